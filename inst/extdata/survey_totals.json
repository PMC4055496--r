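{
  "n_collected": 386,
  "n_analysable": 371,
  "printed_analysable_pct": 97.4,
  "labels": {
    "Cod": 179,
    "Haddock": 155,
    "Alaskan Pollack": 32,
    "Hake (M. capensis)": 4,
    "Whiting": 1
  },
  "cod_by_area": {
    "Atlantic": 57,
    "Pacific": 20,
    "Unspecified": 102
  },
  "processing_levels": {
    "1": 84,
    "2": 84,
    "3": 31,
    "4": 128,
    "5": 44
  }
}
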