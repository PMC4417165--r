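TA_wc:
  annotation: WC-side
  bonds:
    - "W:N3 > C:N1"
    - "C:N6 > W:O4"
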