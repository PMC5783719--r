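# The main balancer marker-exchange cross: dpy-25 on the normal
# chromosome II, rol-1 plus the mIs14 GFP insertion on the mIn1 balancer.
markers:
  - name: dpy-25
    dominance: semi_dominant
    haplotype: normal
    side: left
  - name: rol-1
    dominance: recessive
    haplotype: balancer
    side: left
  - name: mIs14
    dominance: semi_dominant
    haplotype: balancer
    side: right
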