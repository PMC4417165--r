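TG_wobble:
  annotation: WC-side
  bonds:
    - "W:N3 > C:O6"
    - "C:N1 > W:O2"
TG_minor_sugar:
  annotation: minor-groove
  bonds:
    - "C:N2 > W:O4'"
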