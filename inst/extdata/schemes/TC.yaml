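TC_pair:
  annotation: WC-side
  bonds:
    - "C:N4 > W:O4"
    - "W:N3 > C:N3"
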