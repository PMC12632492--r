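# Bead-selection config for a Martini-style coarse-grained system.
# protein_selection may list bead names, or {resnames: [...]} to select
# protein particles by residue name.
protein_selection:
  resnames: [PROT]
species:
  - name: DPOCL          # di-16:0-18:1 cardiolipin
    anchor_bead: LNK     # central linker bead joining the phosphatidyls
    headgroup_beads: [PO1, PO2]
    tail_beads: [TL1]
  - name: POPC
    anchor_bead: LNK
    headgroup_beads: [PO1, PO2]
    tail_beads: [TL1]
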