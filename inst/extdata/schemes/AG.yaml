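AG_imino:
  annotation: WC-side
  bonds:
    - "C:N1 > W:N1"
    - "W:N6 > C:O6"
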