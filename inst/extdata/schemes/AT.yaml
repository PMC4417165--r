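# Canonical Watson-Crick A:T.
AT_wc:
  annotation: WC-side
  bonds:
    - "W:N6 > C:O4"
    - "C:N3 > W:N1"
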