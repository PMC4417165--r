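# G.G purine transversion: two symmetry-related imino/amino schemes that the
# pair interchanges between (Watson donating into the Crick minor edge, and
# the strand-mirrored arrangement).
GG_sym_a:
  annotation: WC-side
  bonds:
    - "C:N1 > W:O6"
    - "W:N2 > C:N3"
GG_sym_b:
  annotation: WC-side
  bonds:
    - "W:N1 > C:O6"
    - "C:N2 > W:N3"
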