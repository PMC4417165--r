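# T.T wobble-like pairing, two mirrored arrangements.
TT_wobble_a:
  annotation: WC-side
  bonds:
    - "W:N3 > C:O2"
    - "C:N3 > W:O4"
TT_wobble_b:
  annotation: WC-side
  bonds:
    - "C:N3 > W:O2"
    - "W:N3 > C:O4"
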