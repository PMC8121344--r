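{
  "level": "national",
  "totals": {
    "decile1": 14473,
    "decile2": 12860,
    "decile3": 20131,
    "decile4": 25958,
    "decile5": 21409,
    "decile6": 38793,
    "decile7": 35650,
    "decile8": 33650,
    "decile9": 38736,
    "age_le13": 47361,
    "age14": 56843,
    "age15": 57060,
    "age16": 55744,
    "female": 139694,
    "maori": 58866,
    "european": 145487,
    "pacific": 26826,
    "asian": 32739
  }
}
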