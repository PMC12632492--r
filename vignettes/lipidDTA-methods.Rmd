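---
title: "Methods: density-threshold lipid affinities and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: density-threshold lipid affinities and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, which
choices were open when it was designed, and what its validation does and
does not demonstrate.

## The frame model

All analyses operate on a normalized frame representation: one row per
bead per frame with a species label, a bead role (`anchor`, `headgroup`,
`tail`, `other`), a parent-lipid id, and nm coordinates. Three
assumptions are baked in:

* **Planar bilayer, fixed normal.** The membrane normal is the z-like
  box axis, as produced by a semi-isotropic barostat. Curved or
  vesicular membranes are out of scope, and so is flip-flop detection.
* **Translation-only centering.** Frames are shifted (with minimum-image
  wrapping in the membrane plane only) so the protein's in-plane center
  of mass sits at the origin. No rotational fitting is applied, because
  the simulations this targets restrain the protein backbone — the lab
  frame *is* the protein frame. Centering is idempotent, and pairwise
  minimum-image distances are invariants checked by tests.
* **Leaflet assignment by the median.** A lipid is `outer` when its
  anchor bead's normal coordinate exceeds the per-frame median anchor
  coordinate. No rule is canonical here; the median is deterministic,
  parameter-free and robust to whole-bilayer drift, and it partitions
  lipids into halves differing by at most one when heights are distinct.
  Frames with fewer than two lipids, or with all anchors at one height,
  are rejected as degenerate rather than guessed at.

Equilibration handling is structural: every analysis pulls its input
through the discard filter, so frames with `time_ns < discard_ns` cannot
leak into any result. For production Martini runs the conventional
discard is the first 5 &mu;s; synthetic ensembles default to zero.

## Enrichment on the polar lattice

Densities are accumulated on a polar lattice of 10 evenly spaced radial
rings to `r_max = 5` nm and 90 azimuthal bins — fine enough azimuthally
(4&deg;, ~0.3 nm arc at the protein edge) to separate sites between
adjacent transmembrane helices of a pentamer, and coarse enough radially
(0.5 nm, about half a lipid diameter) that bins fill at practical frame
counts. Bead-to-bin assignment uses half-open intervals `[r_in, r_out)`
and `[theta_lo, theta_hi)`; a bead at exactly `r_max` is outside the
lattice. Two exact invariants are asserted in the tests: summed
`density x bin_area` equals the mean in-range bead count per frame, and
the area-weighted mean enrichment of the outermost ring equals 1 when
that ring is the bulk reference.

The bulk normalization is not uniquely defined by the enrichment idea,
so both options are provided: the outermost ring of the same map
(default — local, protein-distal, needs no extra system) or the
leaflet-wide mean density of a protein-free companion ensemble. Maps are
pooled over frames of all replicas; per-replica maps differ only at
second order, and `n_frames_used` is recorded.

Sites are maximal 4-connected components (with azimuthal wrap-around) of
bins at enrichment &ge; `threshold`, kept when at least `min_bins` bins.
The defaults `threshold = 1.5`, `min_bins = 3` are exposed rather than
claimed optimal; sites may also be declared geometrically as disks
(e.g. matched to a lipid density in a cryo-EM map), which bypasses
detection entirely. No C5 symmetrization of maps is applied by default —
per-subunit structure is real signal; symmetry enters later, through
subunit-resolved occupancy sampling.

**Accessible area.** A site's geometric area overestimates the area
available to lipids wherever the protein intrudes. The package measures
accessibility from a companion simulation of the same protein in a
single-species membrane: each member bin contributes
`bin_area * min(1, density/bulk_density)`. The saturation at 1 makes the
estimator one-sided on purpose — accessible area is an upper-bounded
geometric quantity, and thermal density fluctuations above bulk must not
inflate it. When two protein states are compared, the area measured on
one designated reference state can be imposed on both
(`set_accessible_area()`), so occupancy odds are compared over identical
probe areas.

## The density-threshold affinity

The occupancy criterion and reference construction are fixed as a
concrete, testable contract:

* a frame is **occupied** when at least `n_thresh` (default 1) anchor
  beads of the species lie in the (subunit-rotated) site region of the
  site's leaflet;
* the **reference** occupancy is measured by placing `n_probes` disks of
  area equal to the site's accessible area uniformly at random per frame
  of a protein-free bulk membrane of the same composition, with periodic
  distances;
* the **free energy** is the occupancy odds ratio,
  &Delta;G = &minus;RT ln[(P/(1&minus;P))/(P_ref/(1&minus;P_ref))], with
  R = 1.98720425&times;10&minus;3 kcal/(mol K) and T defaulting to 320 K
  (the thermostat setting of the simulations this targets).

The sample unit is one (replica &times; symmetry subunit) pair — the
only grouping that reproduces the published sample counts for this class
of system (4 replicas of a pentamer &rarr; n = 20; 3 replicas &rarr;
n = 15). Each sample's occupied/unoccupied counts receive a Jeffreys
0.5 pseudo-count on both outcomes before odds are formed, so a finite
trace can never return an infinite affinity; the correction vanishes as
traces grow, and samples still degenerate at exactly 0 or 1 raise an
error advising longer sampling instead of returning a number. The
reported uncertainty is the Student-t standard error over samples; the
95% bands on occupancy curves are t-intervals of the per-sample curve
values, clipped to [0, 1]. A bootstrap was considered and rejected for
the default because with n = 10–20 approximately normal per-sample
values the t-interval is both cheaper and better calibrated.

Because the estimator is an odds ratio, it converges to the true well
depth only in the **dilute-occupancy regime**: for a Poisson site count
with mean &lambda;, the occupancy odds are e^&lambda;&minus;1, which
exceeds &lambda; by a factor growing with &lambda;, so near-saturated
sites read out too strong. The package does not correct for this — the
published protocol doesn't either — but the validation is designed so
the regime is explicit (below), and `p_occ_site` is reported so users
can see how close to saturation their site runs.

Predicted occupancy uses
P_occ(x_B) = x_B/(e^{&Delta;G/RT} + x_B), evaluated per sample and
averaged; monotonicity in x_B and in &Delta;G are asserted properties.
`compare_states()` tabulates two or more states on a common x_B grid and
reports the sign of the mean difference at every grid point. When
"same uncertainty structure" is wanted analytically (e.g. to illustrate
a state comparison without simulation), inject a common spread shape
shifted between states: then per-sample monotonicity makes the ordering
of the mean curves a theorem, not a hope. Independent wide spreads do
not guarantee that ordering — P_occ is convex in &Delta;G at small x_B,
so a high-variance weak state can overtake a low-variance strong one.

## Pose clustering

Bound poses (one per frame per lipid whose anchor is in the site) are
clustered by a deterministic quality-threshold algorithm on the
configured pose beads with a max-per-bead displacement metric:
repeatedly, each unassigned pose's candidate cluster is every unassigned
pose within `cutoff`; the largest candidate is committed, ties resolved
toward the earliest pose index; after `n_clusters` commits the remainder
is reported as a noise fraction, never silently dropped. Committed
clusters whose anchor-bead centroids lie within `merge_cutoff` are then
combined, closest pair first, recomputing centroids after each merge —
the fixed point has no surviving pair within the cutoff, so re-running
the pass is a no-op. Defaults: 8 clusters, cutoff 0.6 nm, merge 0.4 nm;
the cutoff is interpreted in length units (the tool this mirrors takes
&Aring;ngstr&ouml;ms, hence 6 &Aring; &rarr; 0.6 nm) — if a unitless
quality parameter was intended instead, the number would not transfer,
which is flagged here rather than hidden. Clustering is per-frame, so a
long-resident lipid weights its mode by residence time; per-event
clustering (one pose per visit) can be had by deduplicating
`meta$lipid_id` runs before clustering. The implementation is validated
against an independent brute-force enumeration on all pose sets up to
size 60 across 50 seeds, and is O(n&sup2;) in pose count.

## The synthetic generator: what it emulates, and what it does not

The generator produces a two-leaflet point field of **ideal,
non-interacting lipids**: anchors are drawn from the exact Boltzmann
density of flat disk wells (depth `dG_true`, per species and leaflet)
over the box minus a protein-excluded disk; species have fixed
per-leaflet counts; headgroup/tail beads ride at fixed offsets plus
0.1 nm isotropic jitter. Ideality is the point: expected site enrichment
is exactly e^{&minus;dG_true/RT}, site counts are Poisson-thinned, and
the probe reference has the closed form 1&minus;e^{&minus;&rho;A}, so
every estimator can be scored against truth. Frame-to-frame correlation
is available as a mixture kernel — with probability &rho; a lipid takes
a 0.3 nm random-walk Metropolis step (rejecting protein overlap,
accepting on the Boltzmann ratio), otherwise it resamples independently
— both components preserve the stationary marginal exactly, which the
tests verify by comparing thinned correlated chains against independent
ones.

Two deliberate departures from naive choices:

* **Fixed species counts, not multinomial.** Assigning species i.i.d.
  per lipid would make the minority-species count fluctuate between
  replicas by sd/mean &asymp; 14% at 5 mol% of 1,000 lipids. That noise
  enters the single bulk reference as a common error of roughly
  RT &times; 14% &asymp; 0.09 kcal/mol that the per-sample standard
  error cannot represent, destroying CI calibration at any trace length.
  Real coarse-grained membranes are built with exact per-species counts,
  so the generator apportions counts exactly (largest remainder) and
  permutes them among lipids.
* **Bulk reference at count/box-area density.** The protein-embedded
  box holds its lipids in the box minus the protein disk, so its ambient
  density exceeds the protein-free reference's by A_box/(A_box −
  &pi;R_p&sup2;), and the affinity inherits a
  &minus;RT ln(A_box/A_allowed) offset (&asymp; &minus;0.04 kcal/mol at
  the default geometry). This mirrors the area-per-lipid bookkeeping
  mismatch the real protocol carries between its protein and bulk
  systems and is left in place, budgeted inside the recovery tolerance.

What the generator does **not** emulate: excluded volume between lipids,
lipid shape and tilt, electrostatics, correlated collective motion, and
curvature. Passing recovery tests therefore demonstrate estimator
correctness on the stated statistical model — unbiasedness of the
density machinery, correct odds bookkeeping, honest uncertainty under
independent or AR-mixing frames — not fidelity of any force field, nor
robustness to density correlations that real lipids induce at contact
range.

## Validation scales and numerical choices

The validation study mirrors the scale of the real systems where that is
cheap: 25 &times; 25 nm box, 1,000 lipids per leaflet, 5 mol% target
species, protein radius 3.5 nm (a pLGIC transmembrane footprint), T =
320 K, five site copies at 72&deg; spacing and 4.2 nm radius. Full-scale
recovery (4 replicas &times; 2,000 frames, n = 20 samples) runs once per
well depth in the acceptance suite. The repeated-seed CI-coverage
property runs at reduced trace lengths (2 replicas; 300 frames at
&minus;2 kcal/mol, 100 at &minus;3), chosen so that statistical error
dominates the estimator's known dilute-limit bias and t-coverage is the
quantity actually probed. Validation wells have radius 0.05 nm — sized,
from the closed-form bias analysis above, to keep expected occupancy
below ~8% even at &minus;3 kcal/mol. These wells are statistical
devices, not physical pockets; with point lipids only the product
&rho;&middot;A&middot;e^{&minus;&Delta;G/RT} matters.

Smaller numerical decisions, recorded so they are not rediscovered the
hard way: minimum-image wrapping maps displacements to [&minus;L/2,
L/2); the innermost lattice ring includes r = 0; bin-site rotation by
subunit requires the azimuthal bin count to be divisible by the symmetry
order (90/5 = 18 bins — exact, no interpolation) and errors otherwise;
probe-disk counting uses a periodic cell list, so reference cost is
linear in probes; `which.max` tie-breaking makes clustering reproducible
under permutation up to genuine ties; all JSON is written with full
numeric precision so identical seeds give byte-identical artifacts.

## Known limitations

Besides the generator's idealizations: XTC trajectories are not readable
from R (convert to DCD, multi-model PDB, or the CSV frame format);
protein centering assumes the protein is whole across the periodic
boundary; enrichment pools frames without an autocorrelation correction,
so its error bars (unlike the affinity's replicate-based ones) are
optimistic for strongly correlated trajectories; and the affinity's
standard error does not propagate reference-occupancy uncertainty — keep
`n_probes` high enough that P_ref's relative error is small against
RT-scaled differences you care about (the acceptance setup uses ~10^6
probes for ~3%).
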