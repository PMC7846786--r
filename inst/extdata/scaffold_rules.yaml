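# Scaffold stability and HCDR3-conformation rules for VH3-Vk1 dual-paratope
# Fvs. Allowed sets are strings of one-letter amino-acid codes. Invariant
# interface identities default to the packaged consensus templates; supply a
# project-specific copy of this file to override.
rules:
  - id: invariant_H35
    chain: "H"
    label: 35
    allowed: "S"
    description: invariant VH/VL interface residue VH35
  - id: invariant_H50
    chain: "H"
    label: 50
    allowed: "A"
    description: invariant VH/VL interface residue VH50
  - id: invariant_L34
    chain: "L"
    label: 34
    allowed: "N"
    description: invariant VH/VL interface residue VK34
  - id: invariant_L91
    chain: "L"
    label: 91
    allowed: "Y"
    description: invariant VH/VL interface residue VK91
  - id: hcdr3_basic_94
    chain: "H"
    label: 94
    allowed: "RK"
    description: basic residue at VH94 (kinked HCDR3 base pair)
  - id: hcdr3_D101
    chain: "H"
    label: 101
    allowed: "D"
    description: invariant Asp at VH101 (kinked HCDR3 base pair)
  - id: hcdr3_aromatic_99
    chain: "H"
    label: 99
    allowed: "YF"
    description: Tyr/Phe at VH99 (aromatic pair stabilising HCDR3)
  - id: lcdr2_flank_49
    chain: "L"
    label: 49
    allowed: "YF"
    description: Tyr/Phe at VK49, directly ahead of LCDR2 (aromatic pair partner)
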