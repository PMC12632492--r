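# lipidDTA

Lipid–protein interaction analysis for coarse-grained membrane
simulations, built around the density-threshold binding affinity.

Membrane proteins such as pentameric ligand-gated ion channels (pLGICs)
are modulated by specific lipids — cardiolipin, PE, PG — that bind at
shallow grooves on the transmembrane domain. Coarse-grained MD of a
protein embedded in a mixed bilayer shows these sites as regions where a
lipid species' time-averaged density exceeds its bulk density, but
turning such enrichment into a binding free energy, a predicted occupancy
at physiological lipid fractions, and a set of dominant binding poses
requires a pipeline of fairly delicate bookkeeping (leaflets, periodic
boxes, symmetry copies, reference systems). `lipidDTA` packages that
pipeline for R, together with a synthetic membrane-ensemble generator
with *analytically known* ground truth, so every estimator in the package
is validated by parameter recovery rather than by eyeballing.

It is aimed at computational membrane biophysicists who have
coarse-grained trajectories (Martini-style) of a membrane protein and
want leaflet-resolved enrichment maps, site affinities with honest
uncertainties, occupancy-vs-composition curves, and binding-mode
clustering — and at method developers who need a controlled testbed for
density-based affinity estimators.

## The method

**Enrichment maps.** After discarding equilibration frames, centering
each frame on the protein (translation only; the protein backbone is
restrained in these simulations) and assigning each lipid to a leaflet by
the median anchor-bead height, bead densities are accumulated on a polar
lattice around the protein axis — by default 10 radial × 90 azimuthal
bins out to 5 nm. Enrichment is density over bulk density (outermost
ring, or a protein-free companion system); contiguous enriched bins are
candidate binding sites.

**Density-threshold affinity.** A site of accessible area *A* (measured
against the same protein in a single-species reference membrane) is
*occupied* in a frame when at least `n_thresh` anchor beads of the
species lie inside it. With P_occ the site's occupancy probability and
P_ref the occupancy of an equal-area probe placed at random in a
protein-free bulk membrane of the same composition,

ΔG_bind = −RT · ln[ (P_occ/(1−P_occ)) / (P_ref/(1−P_ref)) ]

one value per (replica × symmetry subunit) sample — for a C5 pentamer,
4 replicas give n = 20 samples, whose mean and standard error are
reported. The affinity predicts site occupancy at any mole fraction x_B
through the Langmuir-type relation

P_occ(x_B) = x_B / (e^{ΔG/RT} + x_B),

so affinities measured around two protein conformations translate into
state-dependent occupancy curves.

**Pose clustering.** Every frame in which a lipid's anchor (for
cardiolipin, its central linker bead) sits in the site contributes a
pose; poses are grouped by quality-threshold clustering under a
max-per-bead displacement metric (default 8 clusters, 0.6 nm cutoff),
then near-duplicate modes whose anchor centroids fall within 0.4 nm are
merged. Mode frequencies are fractions of all captured poses.

**Synthetic ground truth.** The generator draws ideal (non-interacting)
lipid anchors from the Boltzmann density of flat disk wells of prescribed
depth ΔG_true inside a protein-excluded box, so the expected site
enrichment is exactly exp(−ΔG_true/RT) and occupancy statistics are
Poissonian — closed-form oracles for every stage, including full
parameter recovery of ΔG_true by the estimator above.

## Worked example

A protein of radius 2.5 nm in a 20 × 20 nm two-leaflet box, 150 lipids
per leaflet at 4:1 POPC:DPOCL, with five C5-symmetric outer-leaflet sites
of true affinity −2.0 kcal/mol; two replicas of 400 frames:

```r
library(lipidDTA)

spec <- synthetic_spec(
  box = c(20, 20), n_lipids_per_leaflet = 150,
  composition = c(POPC = 0.8, DPOCL = 0.2), protein_radius = 2.5,
  sites = pentameric_sites(-2.0, center_radius = 3.3, site_radius = 0.06),
  n_frames = 400, n_replicas = 2, seed = 42)

ens  <- assign_leaflets(center_on_protein(generate_ensemble(spec)$ensemble))
bulk <- assign_leaflets(generate_reference_ensembles(spec)$bulk)

site <- site_from_disk(c(3.3, 0), 0.06, leaflet = "outer", species = "DPOCL")
traces <- list()
for (ri in 1:2) for (su in 0:4)
  traces[[length(traces) + 1]] <-
    occupancy_trace(ens, site, "DPOCL", replica = ri, subunit = su)

p_ref <- reference_occupancy(bulk, site$accessible_area, "DPOCL",
                             n_probes = 500, seed = 43)
est <- delta_g_bind(traces, p_ref)
est
#> dG_bind = -1.899 +/- 0.116 kcal/mol (n = 10 samples, T = 320 K)
#>   mean site occupancy 0.0190 vs reference 0.0008

pocc_curve(est, c(0.01, 0.05, 0.2, 1))
#>     xB  mean ci_low ci_high
#> 1 0.01 0.179  0.119   0.238
#> 2 0.05 0.497  0.398   0.596
#> 3 0.20 0.785  0.720   0.850
#> 4 1.00 0.946  0.927   0.965
```

The estimate recovers the planted −2.0 kcal/mol within its standard
error (10 samples = 2 replicas × 5 subunits). The curve says a site of
this affinity would be occupied about half the time at 5 mol% of the
lipid — the shaded-band analogue of comparing two protein states is
available through `compare_states()`.

Real trajectories enter through `load_ensemble()` (GRO/PDB topology,
DCD / multi-model PDB / multi-frame GRO trajectories, or the package's
CSV frame format) with a YAML bead-selection config; see
`inst/extdata/demo_selection.yaml`. The whole pipeline — enrichment map,
site detection, affinity, occupancy curves, pose clusters, provenance —
runs from one config via `run_pipeline()`
(`inst/extdata/demo_run.yaml`).

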