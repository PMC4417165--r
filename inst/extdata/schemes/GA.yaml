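# G.A purine transversion: imino G(N1)-A(N1) arrangement.
GA_imino:
  annotation: WC-side
  bonds:
    - "W:N1 > C:N1"
    - "C:N6 > W:O6"
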