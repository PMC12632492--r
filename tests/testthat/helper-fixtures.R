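# Shared fixtures and independent oracles, built in code at test time.

# A minimal hand-built single-replica ensemble. `beads` is a data.frame with
# at least time_ns, lipid_id, species, x, y, z; bead/role/leaflet filled with
# defaults unless given.
manual_ensemble <- function(beads, box = c(25, 25), has_protein = TRUE,
                            centered = TRUE, composition = NULL,
                            discard_ns = 0, protein_centers = NULL) {
  dt <- data.table::as.data.table(beads)
  if (!"bead" %in% names(dt)) dt[, bead := "LNK"]
  if (!"role" %in% names(dt)) dt[, role := "anchor"]
  if (!"leaflet" %in% names(dt)) dt[, leaflet := "outer"]
  membrane_ensemble(list(dt), box = box, has_protein = has_protein,
                    centered = centered, composition = composition,
                    discard_ns = discard_ns,
                    protein_centers = protein_centers)
}

# Small default synthetic spec for cheap tests.
small_spec <- function(...) {
  args <- list(...)
  defaults <- list(box = c(12, 12), n_lipids_per_leaflet = 120L,
                   composition = c(POPC = 0.8, DPOCL = 0.2),
                   protein_radius = 2.5, n_frames = 50L, n_replicas = 1L,
                   seed = 11L, bead_set = "anchor")
  do.call(synthetic_spec, utils::modifyList(defaults, args))
}

# Independent brute-force quality-threshold clustering oracle: exhaustive
# candidate evaluation with plain nested loops (no shared code with the
# implementation). Returns list of member index vectors, in commit order.
bf_qt_clusters <- function(coords, n_clusters, cutoff) {
  n <- dim(coords)[1]
  k <- dim(coords)[2]
  pose_dist <- function(i, j) {
    worst <- 0
    for (b in seq_len(k)) {
      d <- sqrt(sum((coords[i, b, ] - coords[j, b, ])^2))
      if (d > worst) worst <- d
    }
    worst
  }
  assigned <- rep(FALSE, n)
  clusters <- list()
  while (length(clusters) < n_clusters && any(!assigned)) {
    best <- NULL
    best_size <- 0L
    for (i in seq_len(n)) {
      if (assigned[i]) next
      cand <- integer(0)
      for (j in seq_len(n)) {
        if (assigned[j]) next
        if (pose_dist(i, j) <= cutoff) cand <- c(cand, j)
      }
      if (length(cand) > best_size) {  # strict: earliest seed wins ties
        best <- cand
        best_size <- length(cand)
      }
    }
    clusters[[length(clusters) + 1L]] <- best
    assigned[best] <- TRUE
  }
  clusters
}

# Random clustered pose sets for the oracle-equivalence property.
random_pose_coords <- function(n, k = 3L, n_groups = 3L, spread = 0.25,
                               sep = 3) {
  centers <- matrix(stats::runif(n_groups * 3, 0, sep * n_groups),
                    n_groups, 3)
  g <- sample.int(n_groups, n, replace = TRUE)
  coords <- array(0, c(n, k, 3))
  for (i in seq_len(n)) for (b in seq_len(k))
    coords[i, b, ] <- centers[g[i], ] + c(0.3 * b, 0, 0) +
      stats::rnorm(3, sd = spread)
  coords
}

# Tight pose group: identical beads + tiny jitter around an anchor position.
pose_group <- function(n, anchor = c(0, 0, 0), jitter = 0.02, k = 3L) {
  coords <- array(0, c(n, k, 3))
  for (i in seq_len(n)) for (b in seq_len(k))
    coords[i, b, ] <- anchor + c(0.2 * (b - 1), 0, 0) +
      stats::rnorm(3, sd = jitter)
  coords
}

expect_same_clusters <- function(got, want_members) {
  got_sets <- lapply(got$clusters, function(cl) sort(cl$members))
  want_sets <- lapply(want_members, sort)
  # order-free comparison
  key <- function(s) paste(s, collapse = ",")
  expect_setequal(vapply(got_sets, key, ""), vapply(want_sets, key, ""))
}
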