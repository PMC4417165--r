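# A.C transduction: two schemes related by an in-plane rotation of the pair.
AC_wobble_a:
  annotation: WC-side
  bonds:
    - "W:N6 > C:N3"
AC_wobble_b:
  annotation: WC-side
  bonds:
    - "C:N4 > W:N1"
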