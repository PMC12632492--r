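#' Per-frame site occupancy trace
#'
#' A frame is occupied when at least `n_thresh` anchor beads of the species
#' lie inside the site region in the site's leaflet. For a C5-symmetric
#' protein the same site exists once per subunit: `subunit = k` evaluates
#' the site rotated by `2*pi*k/n_symmetry` about the protein axis, so each
#' (replica, subunit) pair yields one independent occupancy sample.
#'
#' @param ensemble Centered, leaflet-assigned [membrane_ensemble()].
#' @param site A `site_definition`.
#' @param species Lipid species counted.
#' @param n_thresh Minimum anchor count for an occupied frame.
#' @param replica Replica index (1-based).
#' @param subunit Symmetry copy index, 0 to `n_symmetry - 1` (0 for
#'   synthetic single-site systems).
#' @param n_symmetry Rotational symmetry order (5 for a pentamer).
#' @return An `occupancy_trace`: logical `occupied` per post-discard frame,
#'   plus the defining metadata.
#' @export
occupancy_trace <- function(ensemble, site, species, n_thresh = 1L,
                            replica = 1L, subunit = 0L, n_symmetry = 5L) {
  stopifnot(inherits(ensemble, "membrane_ensemble"),
            inherits(site, "site_definition"))
  if (!ensemble$centered)
    stop_lipiddta("ensemble must be centered on the protein first", "input")
  ens <- post_discard(ensemble)
  rep_dt <- ens$replicas[[replica]]
  if (!species %in% rep_dt$species)
    stop_lipiddta(sprintf("species %s absent from ensemble", species),
                  "input")
  rsite <- rotate_site(site, as.integer(subunit), n_symmetry)
  sp_want <- species; lf_want <- rsite$leaflet
  anchors <- rep_dt[species == sp_want & role == "anchor" &
                      leaflet == lf_want]
  times <- sort(unique(rep_dt$time_ns))
  if (nrow(anchors)) {
    inside <- in_site_region(rsite, anchors$x, anchors$y)
    cnt <- anchors[, .(n_in = sum(inside[.I])), by = time_ns]
    counts <- cnt$n_in[match(times, cnt$time_ns)]
    counts[is.na(counts)] <- 0L
  } else counts <- rep(0L, length(times))
  structure(list(occupied = counts >= n_thresh,
                 time_ns = times, site = site, species = species,
                 n_thresh = as.integer(n_thresh),
                 replica = as.integer(replica),
                 subunit = as.integer(subunit)),
            class = "occupancy_trace")
}

#' @export
print.occupancy_trace <- function(x, ...) {
  cat(sprintf("occupancy_trace: replica %d subunit %d, %d frames, P_occ = %.4f\n",
              x$replica, x$subunit, length(x$occupied), mean(x$occupied)))
  invisible(x)
}

#' Reference occupancy in a protein-free bulk membrane
#'
#' Measures the probability that a randomly placed probe region of the
#' site's accessible area is occupied (anchor count >= `n_thresh`) in the
#' protein-free bulk system — the ideal-gas reference against which site
#' occupancy odds are compared. `n_probes` probe disks are placed uniformly
#' at random per frame in the requested leaflet; distances honor the
#' periodic box. Deterministic given `seed`.
#'
#' @param bulk_ensemble Protein-free [membrane_ensemble()].
#' @param accessible_area Probe area in nm^2 (the site's accessible area).
#' @param species Lipid species counted.
#' @param n_thresh Occupancy threshold (anchor beads).
#' @param n_probes Probe placements per frame.
#' @param seed RNG seed for probe placement.
#' @param leaflet Leaflet sampled.
#' @return The occupied fraction (a probability), with attributes
#'   `n_probes_total` and `se` (binomial standard error).
#' @export
reference_occupancy <- function(bulk_ensemble, accessible_area, species,
                                n_thresh = 1L, n_probes = 20L, seed = 1L,
                                leaflet = "outer") {
  stopifnot(inherits(bulk_ensemble, "membrane_ensemble"))
  if (bulk_ensemble$has_protein)
    stop_lipiddta("the reference must be a protein-free bulk ensemble",
                  "input")
  if (accessible_area <= 0)
    stop_lipiddta("accessible_area must be positive", "input")
  box <- bulk_ensemble$box
  if (accessible_area > prod(box))
    stop_lipiddta("accessible_area exceeds the leaflet area", "input")
  ens <- post_discard(bulk_ensemble)
  r_probe <- sqrt(accessible_area / pi)

  occupied <- 0L; total <- 0L
  with_seed(seed, {
    sp_want <- species; lf_want <- leaflet
    for (rep_dt in ens$replicas) {
      beads <- rep_dt[species == sp_want & role == "anchor" &
                        leaflet == lf_want, .(time_ns, x, y)]
      times <- sort(unique(rep_dt$time_ns))
      nf <- length(times)
      probes <- data.table::data.table(
        fi = rep(seq_len(nf), each = n_probes),
        x = stats::runif(nf * n_probes, 0, box[1]),
        y = stats::runif(nf * n_probes, 0, box[2]))
      probes[, pid := .I]
      beads[, fi := match(time_ns, times)]
      hits <- count_in_disks(probes, beads, r_probe, box)
      occupied <- occupied + sum(hits >= n_thresh)
      total <- total + nrow(probes)
    }
  })
  p <- occupied / total
  structure(p, n_probes_total = total,
            se = sqrt(p * (1 - p) / total))
}

# Cell-list neighbor count: for each probe, the number of beads of the same
# frame within r_probe (periodic in-plane distances). Probes and beads carry
# a frame index column `fi`.
count_in_disks <- function(probes, beads, r_probe, box) {
  ncx <- max(1L, as.integer(floor(box[1] / r_probe)))
  ncy <- max(1L, as.integer(floor(box[2] / r_probe)))
  ncx <- min(ncx, 512L); ncy <- min(ncy, 512L)
  cw_x <- box[1] / ncx; cw_y <- box[2] / ncy
  probes[, `:=`(cx = pmin(as.integer(x / cw_x), ncx - 1L),
                cy = pmin(as.integer(y / cw_y), ncy - 1L))]
  if (nrow(beads) == 0L) return(rep(0L, nrow(probes)))
  beads[, `:=`(bcx = pmin(as.integer(x / cw_x), ncx - 1L),
               bcy = pmin(as.integer(y / cw_y), ncy - 1L))]
  # replicate beads into the 3x3 neighborhood of their cell (with wrap)
  offs <- data.table::CJ(ox = -1L:1L, oy = -1L:1L)
  beads9 <- beads[rep(seq_len(.N), each = 9L)]
  beads9[, `:=`(cx = (bcx + rep(offs$ox, times = nrow(beads))) %% ncx,
                cy = (bcy + rep(offs$oy, times = nrow(beads))) %% ncy)]
  data.table::setkey(beads9, fi, cx, cy)
  m <- beads9[probes, on = c("fi", "cx", "cy"),
              allow.cartesian = TRUE, nomatch = NULL,
              .(pid, dx = x - i.x, dy = y - i.y)]
  if (nrow(m) == 0L) return(rep(0L, nrow(probes)))
  m[, dx := wrap_minimum_image(dx, box[1])]
  m[, dy := wrap_minimum_image(dy, box[2])]
  m <- m[dx^2 + dy^2 <= r_probe^2, .N, by = pid]
  out <- rep(0L, nrow(probes))
  out[m$pid] <- m$N
  out
}

#' Density-threshold binding affinity
#'
#' Converts per-sample occupancy probabilities into a binding free energy by
#' the occupancy odds ratio against the bulk reference:
#' `dG_i = -RT * ln[ (P_i/(1-P_i)) / (p_ref/(1-p_ref)) ]`,
#' with R = 1.98720425e-3 kcal/(mol K). One sample per (replica, subunit)
#' pair: four replicas of a pentamer give n = 20 samples. The reported `dG`
#' is the sample mean and `se` the sample standard deviation over sqrt(n).
#'
#' Occupied/unoccupied frame counts receive a Jeffreys-style 0.5
#' pseudo-count on both outcomes before odds are formed, so finite traces
#' cannot produce infinite free energies; the correction vanishes as the
#' trace grows.
#'
#' @param traces List of [occupancy_trace()]s (one per replica x subunit
#'   sample), or a bare numeric vector of per-sample occupancy
#'   probabilities (used as-is, no smoothing).
#' @param p_ref Reference occupancy from [reference_occupancy()], in (0,1).
#' @param temperature Temperature in K.
#' @return An `affinity_estimate`: `dG`, `per_sample_dG`, `se`, `n_samples`,
#'   `temperature`, `p_occ_site` (mean per-sample occupancy), `p_occ_ref`.
#' @export
delta_g_bind <- function(traces, p_ref, temperature = 320) {
  if (p_ref <= 0 || p_ref >= 1)
    stop_lipiddta("p_ref must lie strictly inside (0, 1); sample the reference longer",
                  "estimation")
  if (is.numeric(traces)) {
    p <- traces
  } else {
    p <- vapply(traces, function(tr) {
      stopifnot(inherits(tr, "occupancy_trace"))
      k <- sum(tr$occupied); n <- length(tr$occupied)
      if (n == 0L)
        stop_lipiddta("empty occupancy trace", "estimation")
      (k + 0.5) / (n + 1)
    }, numeric(1))
  }
  if (any(p <= 0 | p >= 1))
    stop_lipiddta("a per-sample occupancy of exactly 0 or 1 survived smoothing; sample longer",
                  "estimation")
  rt <- rt_kcal(temperature)
  per <- -rt * (log(p / (1 - p)) - log(p_ref / (1 - p_ref)))
  n <- length(per)
  structure(list(dG = mean(per), per_sample_dG = per,
                 se = if (n > 1) stats::sd(per) / sqrt(n) else NA_real_,
                 n_samples = n, temperature = temperature,
                 p_occ_site = mean(p), p_occ_ref = as.numeric(p_ref)),
            class = "affinity_estimate")
}

#' @export
print.affinity_estimate <- function(x, ...) {
  cat(sprintf("dG_bind = %.3f +/- %.3f kcal/mol (n = %d samples, T = %g K)\n",
              x$dG, x$se, x$n_samples, x$temperature))
  cat(sprintf("  mean site occupancy %.4f vs reference %.4f\n",
              x$p_occ_site, x$p_occ_ref))
  invisible(x)
}

#' Site occupancy probability at a given mole fraction
#'
#' Langmuir-type occupancy implied by a binding free energy:
#' `Pocc = xB / (exp(dG/RT) + xB)`, where `xB` is the mole fraction of the
#' lipid. At `dG = 0` and `xB = 1` the site is occupied half the time.
#'
#' @param dG Binding free energy in kcal/mol.
#' @param xB Mole fraction(s) in (0, 1].
#' @param temperature Temperature in K.
#' @return Occupancy probabilities, same length as `xB`.
#' @examples
#' pocc(-2.1, 0.05, 320) # ~0.576
#' @export
pocc <- function(dG, xB, temperature = 320) {
  if (any(xB <= 0) || any(xB > 1))
    stop_lipiddta("mole fractions must lie in (0, 1]", "input")
  xB / (exp(dG / rt_kcal(temperature)) + xB)
}

#' Predicted occupancy curve with confidence band
#'
#' Evaluates [pocc()] for each per-sample affinity of an estimate over a
#' grid of mole fractions; the band is a Student-t 95% confidence interval
#' of the mean at each grid point, clipped to `[0, 1]`.
#'
#' @param estimate An `affinity_estimate` with at least 2 samples.
#' @param xB_grid Mole fractions in (0, 1].
#' @param level Confidence level.
#' @return A `pocc_curve` data.frame: `xB`, `mean`, `ci_low`, `ci_high`.
#' @export
pocc_curve <- function(estimate, xB_grid, level = 0.95) {
  stopifnot(inherits(estimate, "affinity_estimate"))
  if (estimate$n_samples < 2L)
    stop_lipiddta("confidence band needs at least 2 affinity samples",
                  "input")
  if (any(xB_grid <= 0) || any(xB_grid > 1))
    stop_lipiddta("mole fractions must lie in (0, 1]", "input")
  n <- estimate$n_samples
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  rows <- lapply(xB_grid, function(xb) {
    p <- pocc(estimate$per_sample_dG, xb, estimate$temperature)
    m <- mean(p); half <- tq * stats::sd(p) / sqrt(n)
    data.frame(xB = xb, mean = m,
               ci_low = max(0, m - half), ci_high = min(1, m + half))
  })
  out <- do.call(rbind, rows)
  attr(out, "source") <- estimate
  class(out) <- c("pocc_curve", "data.frame")
  out
}

#' Compare site affinity across protein states
#'
#' Tabulates per-state affinities and predicted occupancy curves for the
#' same site/species measured around different protein conformations, and
#' reports the sign of the mean occupancy difference at each mole fraction
#' (e.g. "cardiolipin occupancy favors the resting state at all
#' concentrations").
#'
#' @param estimates Named list of `affinity_estimate`s (state label ->
#'   estimate); all must share the lipid species context.
#' @param xB_grid Mole fractions in (0, 1].
#' @param species Optional species label recorded per state for a
#'   consistency check (single label or one per state).
#' @return A data.frame with one row per state x mole fraction (`state`,
#'   `dG`, `se`, `xB`, `pocc`, `ci_low`, `ci_high`), with a `differences`
#'   attribute holding pairwise mean differences and their signs.
#' @export
compare_states <- function(estimates, xB_grid, species = NULL) {
  if (length(estimates) < 2L || is.null(names(estimates)))
    stop_lipiddta("need a named list of at least two state estimates",
                  "input")
  if (!is.null(species) && length(unique(species)) != 1L)
    stop_lipiddta("states being compared must concern the same lipid species",
                  "input")
  tabs <- lapply(names(estimates), function(st) {
    est <- estimates[[st]]
    cv <- pocc_curve(est, xB_grid)
    data.frame(state = st, dG = est$dG, se = est$se, xB = cv$xB,
               pocc = cv$mean, ci_low = cv$ci_low, ci_high = cv$ci_high)
  })
  out <- do.call(rbind, tabs)
  states <- names(estimates)
  pairs <- utils::combn(states, 2, simplify = FALSE)
  diffs <- do.call(rbind, lapply(pairs, function(pr) {
    a <- out[out$state == pr[1], ]; b <- out[out$state == pr[2], ]
    data.frame(state_a = pr[1], state_b = pr[2], xB = a$xB,
               diff = a$pocc - b$pocc, sign = sign(a$pocc - b$pocc))
  }))
  attr(out, "differences") <- diffs
  out
}

#' Serialize affinity results
#'
#' `write_affinity_json` stores the full estimate including per-sample
#' values; `write_pocc_csv` stores curve tables (one or more states).
#'
#' @param estimate An `affinity_estimate`, or named list of them.
#' @param curves A `pocc_curve` or named list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_affinity_json <- function(estimate, path) {
  if (inherits(estimate, "affinity_estimate")) estimate <- list(estimate)
  payload <- lapply(estimate, function(e) unclass(e))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affinity_json
#' @export
write_pocc_csv <- function(curves, path) {
  if (inherits(curves, "pocc_curve")) curves <- list(curve = curves)
  flat <- data.table::rbindlist(Map(function(cv, nm) {
    data.table::data.table(state = nm, data.table::as.data.table(cv))
  }, curves, names(curves)))
  data.table::fwrite(flat, path)
  invisible(path)
}
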