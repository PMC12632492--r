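#' Specification for a synthetic membrane ensemble
#'
#' Defines a two-leaflet, multi-species lipid point field with a
#' protein-excluded disk and optional localized binding sites of prescribed
#' true affinity. Lipids are ideal (non-interacting) points whose anchor
#' positions follow the Boltzmann density `exp(-U(x)/RT)` over the box minus
#' the protein disk, where `U(x) = dG_true` inside a site disk targeting the
#' lipid's species and leaflet and 0 elsewhere. This makes the expected site
#' enrichment exactly `exp(-dG_true/RT)` and site occupancy statistics
#' Poissonian, so downstream estimators can be validated against closed
#' forms.
#'
#' The defaults mirror the scale of Martini simulations of a pentameric
#' channel: a 25 x 25 nm box holding ~1,000 lipids per leaflet at 320 K,
#' with a protein footprint of radius 3.5 nm (approximate pLGIC
#' transmembrane-domain cross-section).
#'
#' @param box In-plane box lengths (nm).
#' @param n_lipids_per_leaflet Lipids per leaflet.
#' @param composition Named species mole fractions, summing to 1.
#' @param protein_radius Radius (nm) of the protein-excluded disk.
#' @param sites List of site wells; each a list with `center` (length-2 nm,
#'   relative to the protein center), `radius` (nm), `leaflet`, `species`,
#'   and `dG_true` (kcal/mol). See [pentameric_sites()].
#' @param n_frames Frames per replica.
#' @param n_replicas Number of independent replicas.
#' @param frame_correlation Frame-to-frame persistence rho in `[0, 1)`. At 0
#'   frames are independent; at rho > 0 each lipid keeps (and locally
#'   perturbs) its position with probability rho per frame, via a Metropolis
#'   kernel that preserves the stationary marginal exactly.
#' @param temperature Temperature in K.
#' @param seed Master seed; replica r uses `seed + r`.
#' @param has_protein Embed the protein-excluded disk?
#' @param bead_set `"full"` emits anchor + two headgroup beads + one tail
#'   bead per lipid (pose clustering has structure); `"anchor"` emits only
#'   anchor beads (cheapest for density/affinity work).
#' @param dt_ns Nominal frame spacing in ns.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(box = c(25, 25), n_lipids_per_leaflet = 1000L,
                           composition = c(POPC = 0.95, DPOCL = 0.05),
                           protein_radius = 3.5, sites = list(),
                           n_frames = 500L, n_replicas = 1L,
                           frame_correlation = 0, temperature = 320,
                           seed = 1L, has_protein = TRUE,
                           bead_set = c("full", "anchor"), dt_ns = 1) {
  bead_set <- match.arg(bead_set)
  if (abs(sum(composition) - 1) > 1e-9)
    stop_lipiddta("composition must sum to 1", "config")
  if (is.null(names(composition)) || any(!nzchar(names(composition))))
    stop_lipiddta("composition must be a named vector of species fractions",
                  "config")
  if (frame_correlation < 0 || frame_correlation >= 1)
    stop_lipiddta("frame_correlation must lie in [0, 1)", "config")
  for (s in sites) {
    if (!all(c("center", "radius", "leaflet", "species", "dG_true") %in%
               names(s)))
      stop_lipiddta("each site needs center, radius, leaflet, species, dG_true",
                    "config")
    if (!is.finite(s$dG_true))
      stop_lipiddta("site dG_true must be finite", "config")
    if (!s$species %in% names(composition))
      stop_lipiddta(sprintf("site species %s absent from composition",
                            s$species), "config")
    d <- sqrt(sum(s$center^2))
    if (has_protein && d - s$radius < protein_radius)
      stop_lipiddta("site disk overlaps the protein disk", "config")
    if (d + s$radius > min(box) / 2)
      stop_lipiddta("site disk extends beyond the periodic box", "config")
  }
  structure(list(box = as.numeric(box),
                 n_lipids_per_leaflet = as.integer(n_lipids_per_leaflet),
                 composition = composition,
                 protein_radius = protein_radius,
                 sites = sites,
                 n_frames = as.integer(n_frames),
                 n_replicas = as.integer(n_replicas),
                 frame_correlation = frame_correlation,
                 temperature = temperature,
                 seed = as.integer(seed),
                 has_protein = isTRUE(has_protein),
                 bead_set = bead_set,
                 dt_ns = dt_ns),
            class = "synthetic_spec")
}

#' Five-fold symmetric copies of a binding site well
#'
#' Builds five identical site wells rotated by multiples of 72 degrees, the
#' arrangement of one binding site per subunit of a C5-symmetric pentameric
#' channel. Together with the (replica x subunit) sample-unit rule of
#' [delta_g_bind()], four replicas give the n = 20 affinity samples used for
#' confidence intervals.
#'
#' @param dG_true Well depth in kcal/mol (negative = attractive).
#' @param center_radius Distance (nm) of each site center from the protein
#'   axis.
#' @param site_radius Site disk radius (nm). The density-threshold estimator
#'   is an odds-ratio and is accurate in the dilute-occupancy regime, so for
#'   ideal point lipids the validation wells are kept small enough that the
#'   expected site occupancy stays well below saturation.
#' @param species,leaflet Targeted species and leaflet.
#' @param phase Angular offset (radians) of the first copy.
#' @return A list of five site definitions for [synthetic_spec()].
#' @export
pentameric_sites <- function(dG_true, center_radius = 4.2, site_radius = 0.05,
                             species = "DPOCL", leaflet = "outer", phase = 0) {
  lapply(0:4, function(k) {
    ang <- phase + 2 * pi * k / 5
    list(center = center_radius * c(cos(ang), sin(ang)),
         radius = site_radius, leaflet = leaflet, species = species,
         dG_true = dG_true)
  })
}

#' Generate a synthetic membrane ensemble with known ground truth
#'
#' Draws anchor positions from the Boltzmann density of the spec's site
#' wells (see [synthetic_spec()]), assigns species i.i.d. from the
#' composition (fixed per lipid across frames), places headgroup/tail beads
#' at fixed offsets from the anchor plus isotropic jitter (sigma = 0.1 nm),
#' and populates both leaflets. Output coordinates are in box coordinates
#' with the protein at the box center; run [center_on_protein()] and
#' [assign_leaflets()] as for real data. Deterministic given the spec seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with elements `ensemble` (a [membrane_ensemble()], with
#'   ground-truth leaflet labels filled) and `truth` (a `synthetic_truth`
#'   object carrying the spec and the expected per-site enrichment
#'   `exp(-dG_true/RT)`).
#' @export
generate_ensemble <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  replicas <- vector("list", spec$n_replicas)
  centers <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    replicas[[r]] <- with_seed(spec$seed + r, generate_replica(spec))
    centers[[r]] <- data.table::data.table(
      time_ns = (seq_len(spec$n_frames) - 1) * spec$dt_ns,
      px = spec$box[1] / 2, py = spec$box[2] / 2)
  }
  ens <- membrane_ensemble(replicas, box = spec$box,
                           temperature = spec$temperature,
                           composition = spec$composition,
                           has_protein = spec$has_protein,
                           discard_ns = 0,
                           protein_centers = if (spec$has_protein) centers,
                           centered = FALSE)
  rt <- rt_kcal(spec$temperature)
  enr <- vapply(spec$sites, function(s) exp(-s$dG_true / rt), numeric(1))
  truth <- structure(list(spec = spec,
                          expected_site_enrichment = enr,
                          expected_occupancy_odds = enr),
                     class = "synthetic_truth")
  list(ensemble = ens, truth = truth)
}

# Species labels with exact counts closest to the target fractions.
apportion_species <- function(composition, n) {
  exact <- composition * n
  counts <- floor(exact)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(exact - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  rep(names(composition), counts)
}

# One replica's bead table, in *centered* coordinates, shifted to box
# coordinates at the end. RNG state is managed by the caller.
generate_replica <- function(spec) {
  n <- spec$n_lipids_per_leaflet
  f <- spec$n_frames
  rt <- rt_kcal(spec$temperature)
  # Exact per-leaflet species counts (largest-remainder apportionment),
  # randomly permuted among lipids: membrane builders place fixed lipid
  # counts, so composition does not fluctuate between replicas.
  lip <- data.table::data.table(
    lipid_id = seq_len(2L * n),
    leaflet = rep(c("outer", "inner"), each = n),
    species = c(sample(apportion_species(spec$composition, n)),
                sample(apportion_species(spec$composition, n))))

  X <- matrix(NA_real_, nrow = 2L * n, ncol = f)
  Y <- matrix(NA_real_, nrow = 2L * n, ncol = f)

  for (lf in c("outer", "inner")) {
    for (sp in names(spec$composition)) {
      idx <- which(lip$leaflet == lf & lip$species == sp)
      if (!length(idx)) next
      tsites <- Filter(function(s) s$leaflet == lf && s$species == sp,
                       spec$sites)
      pos <- sample_group_positions(spec, tsites, length(idx), f, rt)
      X[idx, ] <- pos$x
      Y[idx, ] <- pos$y
    }
  }

  times <- (seq_len(f) - 1) * spec$dt_ns
  z_sign <- ifelse(lip$leaflet == "outer", 1, -1)
  anchor <- data.table::data.table(
    time_ns = rep(times, each = 2L * n),
    lipid_id = rep(lip$lipid_id, f),
    species = rep(lip$species, f),
    bead = "LNK", role = "anchor",
    x = as.vector(X), y = as.vector(Y),
    z = rep(2 * z_sign, f) + stats::rnorm(2L * n * f, sd = 0.1),
    leaflet = rep(lip$leaflet, f))

  if (spec$bead_set == "full") {
    offs <- list(PO1 = c(0.15, 0, 0.10, "headgroup"),
                 PO2 = c(-0.15, 0, 0.10, "headgroup"),
                 TL1 = c(0, 0, -0.35, "tail"))
    extras <- lapply(names(offs), function(b) {
      o <- as.numeric(offs[[b]][1:3])
      m <- nrow(anchor)
      data.table::data.table(
        time_ns = anchor$time_ns, lipid_id = anchor$lipid_id,
        species = anchor$species, bead = b, role = offs[[b]][4],
        x = anchor$x + o[1] + stats::rnorm(m, sd = 0.1),
        y = anchor$y + o[2] + stats::rnorm(m, sd = 0.1),
        z = anchor$z + o[3] * rep(z_sign, f) + stats::rnorm(m, sd = 0.1),
        leaflet = anchor$leaflet)
    })
    beads <- data.table::rbindlist(c(list(anchor), extras))
  } else beads <- anchor

  # shift to box coordinates (protein at box center)
  beads[, x := x + spec$box[1] / 2]
  beads[, y := y + spec$box[2] / 2]
  data.table::setkey(beads, time_ns, lipid_id)
  beads
}

# Positions for one (leaflet, species) group: m lipids x f frames, centered
# coordinates. `tsites` are the wells targeting this group.
sample_group_positions <- function(spec, tsites, m, f, rt) {
  rho <- spec$frame_correlation
  if (rho == 0) {
    pos <- sample_marginal(spec, tsites, m * f, rt)
    return(list(x = matrix(pos$x, nrow = m), y = matrix(pos$y, nrow = m)))
  }
  X <- matrix(NA_real_, m, f); Y <- matrix(NA_real_, m, f)
  cur <- sample_marginal(spec, tsites, m, rt)
  X[, 1] <- cur$x; Y[, 1] <- cur$y
  for (fr in seq_len(f)[-1]) {
    resample <- stats::runif(m) < 1 - rho
    if (any(resample)) {
      nw <- sample_marginal(spec, tsites, sum(resample), rt)
      cur$x[resample] <- nw$x; cur$y[resample] <- nw$y
    }
    keep <- which(!resample)
    if (length(keep)) {
      moved <- metropolis_move(spec, tsites, cur$x[keep], cur$y[keep], rt)
      cur$x[keep] <- moved$x; cur$y[keep] <- moved$y
    }
    X[, fr] <- cur$x; Y[, fr] <- cur$y
  }
  list(x = X, y = Y)
}

# i.i.d. draws from the group's Boltzmann marginal (centered coordinates).
sample_marginal <- function(spec, tsites, n_draw, rt) {
  a_box <- prod(spec$box)
  a_prot <- if (spec$has_protein) pi * spec$protein_radius^2 else 0
  w_site <- vapply(tsites, function(s) pi * s$radius^2 * exp(-s$dG_true / rt),
                   numeric(1))
  a_sites <- sum(vapply(tsites, function(s) pi * s$radius^2, numeric(1)))
  w_else <- a_box - a_prot - a_sites
  w <- c(w_else, w_site)
  comp <- sample.int(length(w), n_draw, replace = TRUE, prob = w)
  x <- numeric(n_draw); y <- numeric(n_draw)
  for (k in seq_along(tsites)) {
    sel <- which(comp == k + 1L)
    if (!length(sel)) next
    s <- tsites[[k]]
    rr <- s$radius * sqrt(stats::runif(length(sel)))
    th <- stats::runif(length(sel), 0, 2 * pi)
    x[sel] <- s$center[1] + rr * cos(th)
    y[sel] <- s$center[2] + rr * sin(th)
  }
  sel <- which(comp == 1L)
  if (length(sel)) {
    got <- 0L
    while (got < length(sel)) {
      need <- length(sel) - got
      cx <- stats::runif(ceiling(need * 1.2), -spec$box[1] / 2, spec$box[1] / 2)
      cy <- stats::runif(length(cx), -spec$box[2] / 2, spec$box[2] / 2)
      ok <- rep(TRUE, length(cx))
      if (spec$has_protein)
        ok <- ok & (cx^2 + cy^2 >= spec$protein_radius^2)
      for (s in tsites)
        ok <- ok & ((cx - s$center[1])^2 + (cy - s$center[2])^2 > s$radius^2)
      cx <- cx[ok]; cy <- cy[ok]
      take <- min(length(cx), need)
      if (take > 0) {
        x[sel[(got + 1L):(got + take)]] <- cx[seq_len(take)]
        y[sel[(got + 1L):(got + take)]] <- cy[seq_len(take)]
        got <- got + take
      }
    }
  }
  list(x = x, y = y)
}

# One random-walk Metropolis step per lipid; preserves the Boltzmann
# marginal (proposals into the protein disk are rejected; energy ratio
# otherwise). Step size 0.3 nm.
metropolis_move <- function(spec, tsites, x, y, rt, step = 0.3) {
  m <- length(x)
  px <- wrap_minimum_image(x + stats::rnorm(m, sd = step), spec$box[1])
  py <- wrap_minimum_image(y + stats::rnorm(m, sd = step), spec$box[2])
  u_of <- function(ax, ay) {
    u <- numeric(length(ax))
    for (s in tsites) {
      inside <- (ax - s$center[1])^2 + (ay - s$center[2])^2 <= s$radius^2
      u[inside] <- u[inside] + s$dG_true
    }
    u
  }
  ok <- rep(TRUE, m)
  if (spec$has_protein) ok <- px^2 + py^2 >= spec$protein_radius^2
  acc <- ok & (stats::runif(m) < exp(-(u_of(px, py) - u_of(x, y)) / rt))
  x[acc] <- px[acc]; y[acc] <- py[acc]
  list(x = x, y = y)
}

#' Reference ensembles for the density-threshold affinity
#'
#' The affinity protocol requires two companion systems: an "accessible
#' area" system in which the same protein is embedded in a single-species
#' membrane (used to measure how much of a site's geometric area the protein
#' leaves accessible), and a protein-free "bulk" system of the original
#' composition (the ideal-gas reference for occupancy odds). Both are
#' generated as single replicas from the parent spec with all wells removed.
#'
#' @param spec A [synthetic_spec()].
#' @param area_species Species name for the single-species area system.
#' @return A list with `area` and `bulk` [membrane_ensemble()]s.
#' @export
generate_reference_ensembles <- function(spec, area_species = "DPPC") {
  stopifnot(inherits(spec, "synthetic_spec"))
  area_spec <- spec
  area_spec$composition <- stats::setNames(1, area_species)
  area_spec$sites <- list()
  area_spec$n_replicas <- 1L
  area_spec$seed <- spec$seed + 1000L
  class(area_spec) <- "synthetic_spec"

  bulk_spec <- spec
  bulk_spec$sites <- list()
  bulk_spec$has_protein <- FALSE
  bulk_spec$n_replicas <- 1L
  bulk_spec$seed <- spec$seed + 2000L
  class(bulk_spec) <- "synthetic_spec"

  list(area = generate_ensemble(area_spec)$ensemble,
       bulk = generate_ensemble(bulk_spec)$ensemble)
}
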