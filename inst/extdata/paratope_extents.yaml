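# Enhancing-position extents: framework ranges optionally diversified to
# modulate CDR conformation (chain N-termini and outer loops). Numeric Kabat
# label ranges, inclusive.
H-side:
  - name: vh_nterm
    chain: H
    from: 1
    to: 7
  - name: vh_outer_loop
    chain: H
    from: 71
    to: 78
L-side:
  - name: vk_nterm
    chain: L
    from: 1
    to: 7
  - name: vk_outer_loop
    chain: L
    from: 66
    to: 71
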