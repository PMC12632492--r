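# Demo pipeline configuration: synthetic membrane with a known-affinity
# pentameric site, analysed end to end.
output_dir: lipiddta_demo_out
seed: 5
input:
  type: synthetic
  spec:
    box: [14, 14]
    n_lipids_per_leaflet: 150
    composition: {POPC: 0.8, DPOCL: 0.2}
    protein_radius: 2.5
    n_frames: 60
    n_replicas: 2
    bead_set: full
    pentamer: {dG_true: -2.5, center_radius: 3.3, site_radius: 0.3}
lattice: {r_max: 5, n_radial: 10, n_azimuthal: 90}
enrichment: {species: DPOCL, leaflet: outer, bead_role: anchor}
site:
  disk: {center: [3.3, 0], radius: 0.3}
dta: {n_probes: 200, xB_grid: [0.05, 0.2, 1.0]}
clustering: {pose_beads: [LNK, PO1, PO2]}
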