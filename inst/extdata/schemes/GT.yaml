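# G.T transduction: the wobble (G shifted toward the minor groove) dominates;
# a sugar-contact alternative through the minor groove is listed for
# completeness.
GT_wobble:
  annotation: WC-side
  bonds:
    - "W:N1 > C:O2"
    - "C:N3 > W:O6"
GT_minor_sugar:
  annotation: minor-groove
  bonds:
    - "W:N2 > C:O4'"
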