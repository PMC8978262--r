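# three interstitial point sources; powers in mW
sources:
  - type: point
    position: [30.3, 30.1, 24.2]
    power: 100
  - type: point
    position: [29.8, 29.9, 30.1]
    power: 100
  - type: point
    position: [26.2, 33.1, 33.8]
    power: 100
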