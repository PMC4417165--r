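# C.C pyrimidine transversion: one amino-imino bond, two mirrored dimers.
CC_sym_a:
  annotation: WC-side
  bonds:
    - "W:N4 > C:N3"
CC_sym_b:
  annotation: WC-side
  bonds:
    - "C:N4 > W:N3"
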