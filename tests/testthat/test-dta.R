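test_that("occupancy traces count anchors in the (rotated) site region", {
  # 10 frames; a DPOCL anchor sits in the site only in frames 2, 5, 6
  site <- site_from_disk(c(4, 0), 0.3, "outer", "DPOCL")
  in_x <- c(NA, 4.0, NA, NA, 4.1, 3.9, NA, NA, NA, NA)
  rows <- list()
  for (f in 1:10) {
    # a far-away lipid keeps every frame populated
    rows[[length(rows) + 1]] <- data.frame(
      time_ns = f - 1, lipid_id = 1, species = "DPOCL", bead = "LNK",
      role = "anchor", x = -8, y = -8, z = 2, leaflet = "outer")
    if (!is.na(in_x[f]))
      rows[[length(rows) + 1]] <- data.frame(
        time_ns = f - 1, lipid_id = 2, species = "DPOCL", bead = "LNK",
        role = "anchor", x = in_x[f], y = 0, z = 2, leaflet = "outer")
  }
  ens <- manual_ensemble(data.table::rbindlist(rows))
  tr <- occupancy_trace(ens, site, "DPOCL")
  expect_equal(mean(tr$occupied), 0.3)
  expect_equal(length(tr$occupied), 10)

  # n_thresh = 2 needs two anchors at once
  tr2 <- occupancy_trace(ens, site, "DPOCL", n_thresh = 2)
  expect_equal(sum(tr2$occupied), 0)

  # subunit 1 sees the site rotated by 72 degrees: nothing there
  tr_rot <- occupancy_trace(ens, site, "DPOCL", subunit = 1)
  expect_equal(sum(tr_rot$occupied), 0)
  # ... unless the bead is placed at the rotated position
  rot <- rotate_xy(4.05, 0, 2 * pi / 5)
  extra <- data.frame(time_ns = 0, lipid_id = 3, species = "DPOCL",
                      bead = "LNK", role = "anchor", x = rot$x, y = rot$y,
                      z = 2, leaflet = "outer")
  ens2 <- manual_ensemble(data.table::rbindlist(c(rows, list(extra))))
  expect_equal(sum(occupancy_trace(ens2, site, "DPOCL",
                                   subunit = 1)$occupied), 1)

  expect_error(occupancy_trace(ens, site, "CHOL"),
               class = "lipiddta_input_error")
})

test_that("bin sites rotate by whole azimuthal bins for a pentamer", {
  lat <- polar_lattice()  # 90 bins: 5-fold rotation = 18 bins
  site <- site_from_bins(cbind(3, c(1, 2)), lat, "outer", "DPOCL")
  rot <- lipidDTA:::rotate_site(site, 1L, 5L)
  expect_setequal(rot$region$bins[, "theta_idx"], c(19, 20))
  lat7 <- polar_lattice(n_azimuthal = 7)
  site7 <- site_from_bins(cbind(3, 1), lat7, "outer", "DPOCL")
  expect_error(lipidDTA:::rotate_site(site7, 1L, 5L),
               class = "lipiddta_input_error")
})

test_that("the odds-ratio free energy reproduces hand arithmetic", {
  # single sample: P = 0.8 against p_ref = 0.5 at 320 K
  est <- delta_g_bind(0.8, p_ref = 0.5, temperature = 320)
  expect_equal(est$dG, -rt_kcal(320) * log(4), tolerance = 1e-12)
  expect_equal(round(est$dG, 3), -0.882)

  # equal odds in every sample: dG = 0 with zero spread
  est0 <- delta_g_bind(c(0.5, 0.5, 0.5), p_ref = 0.5)
  expect_equal(est0$dG, 0)
  expect_equal(est0$se, 0)

  # anti-symmetry: swapping site and reference odds negates dG exactly
  a <- delta_g_bind(0.7, p_ref = 0.2)
  b <- delta_g_bind(0.2, p_ref = 0.7)
  expect_equal(a$dG, -b$dG, tolerance = 1e-12)

  # degenerate inputs
  expect_error(delta_g_bind(c(0.5, 1), p_ref = 0.5),
               class = "lipiddta_estimation_error")
  expect_error(delta_g_bind(0.5, p_ref = 0),
               class = "lipiddta_estimation_error")
})

test_that("replica x subunit grouping yields the printed sample counts", {
  spec <- small_spec(n_frames = 15L, n_replicas = 4L,
                     sites = pentameric_sites(-2, center_radius = 3.2,
                                              site_radius = 0.3))
  ens <- assign_leaflets(center_on_protein(generate_ensemble(spec)$ensemble))
  site <- site_from_disk(spec$sites[[1]]$center, 0.3, "outer", "DPOCL")
  traces <- list()
  for (ri in 1:4) for (su in 0:4)
    traces[[length(traces) + 1]] <- occupancy_trace(ens, site, "DPOCL",
                                                    replica = ri,
                                                    subunit = su)
  est <- delta_g_bind(traces, p_ref = 0.1)
  expect_equal(est$n_samples, 20)   # 4 replicas x 5 subunits
  expect_equal(length(est$per_sample_dG), 20)
  expect_equal(est$dG, mean(est$per_sample_dG))
  expect_equal(est$se, sd(est$per_sample_dG) / sqrt(20))
  # 3 replicas x 5 subunits gives n = 15
  expect_equal(delta_g_bind(traces[1:15], p_ref = 0.1)$n_samples, 15)
})

test_that("occupancy probability follows the closed form and its limits", {
  expect_identical(pocc(0, 1), 0.5)
  expect_equal(pocc(-2.1, 0.05, 320), 0.576, tolerance = 1e-3)
  expect_lt(pocc(-5, 1e-9), 1e-5)
  expect_error(pocc(-1, 0), class = "lipiddta_input_error")

  # strictly increasing in xB, strictly decreasing in dG
  xg <- seq(0.01, 1, length.out = 50)
  for (dg in c(-3, -1, 0, 1))
    expect_true(all(diff(pocc(dg, xg)) > 0))
  dgg <- seq(-4, 2, length.out = 50)
  for (xb in c(0.01, 0.2, 1))
    expect_true(all(diff(vapply(dgg, pocc, 1, xB = xb)) < 0))
})

test_that("occupancy curves carry valid, monotone confidence bands", {
  est <- delta_g_bind(c(0.62, 0.55, 0.70, 0.58), p_ref = 0.2)
  xg <- c(0.01, 0.05, 0.1, 0.3, 1)
  cv <- pocc_curve(est, xg)
  expect_true(all(cv$ci_low <= cv$mean & cv$mean <= cv$ci_high))
  expect_true(all(cv$ci_low >= 0 & cv$ci_high <= 1))
  expect_true(all(diff(cv$mean) > 0))
  # the band is the Student-t interval of the per-sample curve values
  p <- pocc(est$per_sample_dG, 0.05, est$temperature)
  half <- qt(0.975, 3) * sd(p) / 2
  expect_equal(cv$ci_high[cv$xB == 0.05] - cv$mean[cv$xB == 0.05], half,
               tolerance = 1e-12)
  expect_error(pocc_curve(delta_g_bind(0.5, p_ref = 0.2), xg),
               class = "lipiddta_input_error")
})

test_that("state comparison preserves per-sample ordering at every xB", {
  rt <- rt_kcal(320)
  # inject analytically: common spread shape shifted between states
  spread <- seq(-0.6, 0.6, length.out = 20)
  inject <- function(dg) {
    odds <- exp(-(dg + spread) / rt)
    delta_g_bind(odds / (1 + odds), p_ref = 0.5)
  }
  est_a <- inject(-2.1); est_b <- inject(-1.5)
  expect_equal(est_a$dG, -2.1, tolerance = 1e-9)
  xg <- c(0.001, 0.01, 0.05, 0.1, 0.25, 0.5, 1)
  rpt <- compare_states(list(resting = est_a, class2 = est_b), xg)
  expect_equal(nrow(rpt), 2 * length(xg))
  diffs <- attr(rpt, "differences")
  expect_true(all(diffs$diff > 0))
  expect_true(all(diffs$sign == 1))

  # identical states differ by exactly zero
  same <- compare_states(list(a = est_a, b = est_a), xg)
  expect_true(all(attr(same, "differences")$diff == 0))

  expect_error(compare_states(list(a = est_a), xg),
               class = "lipiddta_input_error")
})

test_that("reference occupancy matches the Poisson closed form", {
  s <- synthetic_spec(box = c(25, 25), n_lipids_per_leaflet = 1000L,
                      composition = c(POPC = 0.95, DPOCL = 0.05),
                      has_protein = FALSE, n_frames = 300L, seed = 31L,
                      bead_set = "anchor")
  bulk <- assign_leaflets(generate_ensemble(s)$ensemble)
  r <- bulk$replicas[[1]][role == "anchor" & leaflet == "outer" &
                            species == "DPOCL"]
  rho_b <- nrow(r) / 300 / 625   # realized species density
  for (a in c(0.05, 0.2, 1.0)) {
    p <- reference_occupancy(bulk, a, "DPOCL", n_probes = 100L, seed = 41L)
    expected <- 1 - exp(-rho_b * a)
    se <- sqrt(max(expected * (1 - expected), 1e-9) / attr(p, "n_probes_total"))
    expect_lt(abs(as.numeric(p) - expected), 3 * se + 2e-4)
  }
  # determinism and limits
  p1 <- reference_occupancy(bulk, 0.2, "DPOCL", n_probes = 50L, seed = 7L)
  p2 <- reference_occupancy(bulk, 0.2, "DPOCL", n_probes = 50L, seed = 7L)
  expect_identical(as.numeric(p1), as.numeric(p2))
  tiny <- reference_occupancy(bulk, 1e-6, "DPOCL", n_probes = 50L, seed = 7L)
  expect_lt(as.numeric(tiny), 1e-3)
  expect_error(reference_occupancy(bulk, 700, "DPOCL"),
               class = "lipiddta_input_error")
  prot <- small_spec(n_frames = 3L)
  expect_error(reference_occupancy(
    assign_leaflets(generate_ensemble(prot)$ensemble), 0.2, "DPOCL"),
    class = "lipiddta_input_error")
})

test_that("periodic cell-list probe counting equals brute-force counting", {
  s <- small_spec(n_frames = 20L, has_protein = FALSE,
                  n_lipids_per_leaflet = 80L)
  bulk <- assign_leaflets(generate_ensemble(s)$ensemble)
  beads <- bulk$replicas[[1]][role == "anchor" & leaflet == "outer" &
                                species == "DPOCL"]
  times <- sort(unique(beads$time_ns))
  set.seed(99)
  probes <- data.table::data.table(
    fi = rep(seq_along(times), each = 40),
    x = runif(20 * 40, 0, 12), y = runif(20 * 40, 0, 12))
  probes[, pid := .I]
  beads[, fi := match(time_ns, times)]
  for (r_probe in c(0.1, 0.56, 2.5)) {
    fast <- lipidDTA:::count_in_disks(data.table::copy(probes),
                                      data.table::copy(beads), r_probe,
                                      c(12, 12))
    wrap <- function(d, L) d - L * round(d / L)
    slow <- vapply(seq_len(nrow(probes)), function(i) {
      b <- beads[fi == probes$fi[i]]
      sum(wrap(b$x - probes$x[i], 12)^2 +
            wrap(b$y - probes$y[i], 12)^2 <= r_probe^2)
    }, integer(1))
    expect_identical(as.integer(fast), slow)
  }
})

test_that("ground-truth affinities are recovered with honest uncertainty", {
  # Scaled-down study: full box/density (25 nm, 1000 lipids/leaflet,
  # 5 mol% target species, five pentameric site copies of radius 0.05 nm),
  # but 2 replicas and shortened traces so that statistical error dominates
  # the estimator's small dilute-limit bias and the t-interval is
  # meaningful. 20 independent seeds per well depth.
  cases <- list(list(dG = -2, n_frames = 300L),
                list(dG = -3, n_frames = 100L))
  a_site <- pi * 0.05^2
  for (case in cases) {
    ok <- 0L
    for (rep_i in 1:20) {
      seed <- 300 + 17 * rep_i
      spec <- synthetic_spec(
        box = c(25, 25), n_lipids_per_leaflet = 1000L,
        composition = c(POPC = 0.95, DPOCL = 0.05), protein_radius = 3.5,
        sites = pentameric_sites(case$dG, center_radius = 4.2,
                                 site_radius = 0.05),
        n_frames = case$n_frames, n_replicas = 2L, seed = seed,
        bead_set = "anchor")
      ens <- assign_leaflets(center_on_protein(
        generate_ensemble(spec)$ensemble))
      bulk_spec <- synthetic_spec(
        box = c(25, 25), n_lipids_per_leaflet = 1000L,
        composition = c(POPC = 0.95, DPOCL = 0.05), has_protein = FALSE,
        n_frames = 300L, seed = seed + 5000L, bead_set = "anchor")
      bulk <- assign_leaflets(generate_ensemble(bulk_spec)$ensemble)
      site <- site_from_disk(spec$sites[[1]]$center, 0.05, "outer", "DPOCL")
      traces <- list()
      for (ri in 1:2) for (su in 0:4)
        traces[[length(traces) + 1]] <- occupancy_trace(
          ens, site, "DPOCL", replica = ri, subunit = su)
      p_ref <- reference_occupancy(bulk, a_site, "DPOCL",
                                   n_probes = 4400L, seed = seed + 9000L)
      est <- delta_g_bind(traces, p_ref)
      expect_equal(est$n_samples, 10)
      err <- est$dG - case$dG
      covered <- abs(err) <= qt(0.975, est$n_samples - 1) * est$se
      if (abs(err) <= 0.25 && covered) ok <- ok + 1L
    }
    expect_gte(ok, 16L)  # >= 80% of 20 seeded repetitions
  }
})
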