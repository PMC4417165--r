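CT_pair:
  annotation: WC-side
  bonds:
    - "W:N4 > C:O4"
    - "C:N3 > W:N3"
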