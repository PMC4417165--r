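GC_wc:
  annotation: WC-side
  bonds:
    - "W:N1 > C:N3"
    - "W:N2 > C:O2"
    - "C:N4 > W:O6"
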