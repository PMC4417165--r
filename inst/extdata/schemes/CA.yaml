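CA_wobble_a:
  annotation: WC-side
  bonds:
    - "C:N6 > W:N3"
CA_wobble_b:
  annotation: WC-side
  bonds:
    - "W:N4 > C:N1"
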