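# A.A purine transversion: single amino-N1 bond, two mirrored arrangements.
AA_sym_a:
  annotation: WC-side
  bonds:
    - "W:N6 > C:N1"
AA_sym_b:
  annotation: WC-side
  bonds:
    - "C:N6 > W:N1"
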