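{
  "level": "regional",
  "totals": {
    "decile1": 11839,
    "decile2": 8471,
    "decile3": 9175,
    "decile4": 14212,
    "decile5": 10379,
    "decile6": 10145,
    "decile7": 17084,
    "decile8": 8604,
    "decile9": 22554,
    "age_le13": 22241,
    "age14": 26685,
    "age15": 26527,
    "age16": 26181,
    "female": 64737,
    "maori": 24393,
    "european": 53889,
    "pacific": 19913,
    "asian": 22358
  }
}
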