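CG_wc:
  annotation: WC-side
  bonds:
    - "W:N4 > C:O6"
    - "C:N1 > W:N3"
    - "C:N2 > W:O2"
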