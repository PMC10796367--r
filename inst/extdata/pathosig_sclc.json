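{
  "name": "PathoSig (SCLC overall survival, published two-term signature)",
  "M": 50,
  "terms": [
    {"hpc": 39, "beta": 0.2398},
    {"hpc": 19, "beta": -0.3393}
  ],
  "threshold": null,
  "scaling": "identity"
}
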