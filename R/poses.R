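#' Capture bound-lipid poses at a site
#'
#' Collects, across all replicas and post-discard frames, every instance of
#' a lipid of the species whose anchor bead lies inside the site region
#' (the anchor entering the site is the binding criterion), and records the
#' positions of the configured pose beads in the protein-centered frame.
#' One pose is captured per (frame, lipid) while the lipid is resident.
#'
#' @param ensemble Centered, leaflet-assigned [membrane_ensemble()].
#' @param site A `site_definition`.
#' @param species Lipid species.
#' @param pose_beads Character vector of bead names to record, in a fixed
#'   order; must include the species' anchor bead.
#' @return A `bound_pose_set`: coordinates array `[n_poses, n_beads, 3]`,
#'   `bead_labels`, `anchor_index`, and a `meta` table (replica, time_ns,
#'   lipid_id).
#' @export
extract_poses <- function(ensemble, site, species,
                          pose_beads = c("LNK", "PO1", "PO2")) {
  stopifnot(inherits(ensemble, "membrane_ensemble"),
            inherits(site, "site_definition"))
  if (!ensemble$centered)
    stop_lipiddta("ensemble must be centered on the protein first", "input")
  ens <- post_discard(ensemble)
  sp_want <- species; lf_want <- site$leaflet
  pose_list <- list(); meta_list <- list()
  anchor_bead <- NULL
  for (ri in seq_along(ens$replicas)) {
    rep_dt <- ens$replicas[[ri]]
    lips <- rep_dt[species == sp_want & leaflet == lf_want &
                     bead %in% pose_beads]
    if (!nrow(lips)) next
    ab <- unique(lips[role == "anchor", bead])
    if (length(ab) != 1L)
      stop_lipiddta(sprintf("species %s must have exactly one anchor bead among pose_beads",
                            species), "config")
    anchor_bead <- ab
    anch <- lips[role == "anchor"]
    bound <- anch[in_site_region(site, anch$x, anch$y),
                  .(time_ns, lipid_id)]
    if (!nrow(bound)) next
    sel <- lips[bound, on = c("time_ns", "lipid_id"), nomatch = NULL]
    sel[, bead_ord := match(bead, pose_beads)]
    if (anyNA(sel$bead_ord))
      stop_lipiddta("pose bead bookkeeping failed", "format")
    data.table::setorder(sel, time_ns, lipid_id, bead_ord)
    n_beads <- length(pose_beads)
    if (nrow(sel) %% n_beads != 0L)
      stop_lipiddta(sprintf("some %s lipids lack one of the pose beads %s",
                            species, paste(pose_beads, collapse = ",")),
                    "config")
    n_poses <- nrow(sel) / n_beads
    arr <- array(NA_real_, c(n_poses, n_beads, 3L))
    arr[, , 1] <- matrix(sel$x, ncol = n_beads, byrow = TRUE)
    arr[, , 2] <- matrix(sel$y, ncol = n_beads, byrow = TRUE)
    arr[, , 3] <- matrix(sel$z, ncol = n_beads, byrow = TRUE)
    pose_list[[length(pose_list) + 1L]] <- arr
    meta_list[[length(meta_list) + 1L]] <-
      data.table::data.table(replica = ri,
                             sel[bead_ord == 1L, .(time_ns, lipid_id)])
  }
  if (!length(pose_list)) {
    return(structure(list(coords = array(numeric(0),
                                         c(0L, length(pose_beads), 3L)),
                          bead_labels = pose_beads,
                          anchor_index = NA_integer_,
                          meta = data.table::data.table(
                            replica = integer(0), time_ns = numeric(0),
                            lipid_id = integer(0))),
                     class = "bound_pose_set"))
  }
  coords <- abind_poses(pose_list)
  structure(list(coords = coords, bead_labels = pose_beads,
                 anchor_index = match(anchor_bead, pose_beads),
                 meta = data.table::rbindlist(meta_list)),
            class = "bound_pose_set")
}

# row-bind pose arrays along the first dimension
abind_poses <- function(arrs) {
  k <- dim(arrs[[1]])[2]
  tot <- sum(vapply(arrs, function(a) dim(a)[1], integer(1)))
  out <- array(NA_real_, c(tot, k, 3L))
  at <- 0L
  for (a in arrs) {
    n <- dim(a)[1]
    if (n) out[(at + 1L):(at + n), , ] <- a
    at <- at + n
  }
  out
}

#' Construct a pose set directly from coordinates
#'
#' Mainly for testing and for clustering poses produced outside
#' [extract_poses()].
#'
#' @param coords Array `[n_poses, n_beads, 3]`.
#' @param bead_labels Bead names (length = n_beads).
#' @param anchor_index Which bead is the anchor (for merge centroids).
#' @return A `bound_pose_set`.
#' @export
pose_set <- function(coords, bead_labels = NULL, anchor_index = 1L) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop_lipiddta("`coords` must be an [n_poses, n_beads, 3] array", "input")
  if (is.null(bead_labels))
    bead_labels <- paste0("B", seq_len(dim(coords)[2]))
  structure(list(coords = coords, bead_labels = bead_labels,
                 anchor_index = as.integer(anchor_index),
                 meta = data.table::data.table(
                   replica = rep(1L, dim(coords)[1]),
                   time_ns = as.numeric(seq_len(dim(coords)[1])),
                   lipid_id = seq_len(dim(coords)[1]))),
            class = "bound_pose_set")
}

#' @export
print.bound_pose_set <- function(x, ...) {
  cat(sprintf("bound_pose_set: %d poses x %d beads (%s)\n",
              dim(x$coords)[1], dim(x$coords)[2],
              paste(x$bead_labels, collapse = ", ")))
  invisible(x)
}

# max-per-bead displacement between every pair of poses
pose_distance_matrix <- function(coords) {
  n <- dim(coords)[1]; k <- dim(coords)[2]
  d2 <- matrix(0, n, n)
  for (b in seq_len(k)) {
    xb <- coords[, b, 1]; yb <- coords[, b, 2]; zb <- coords[, b, 3]
    db <- outer(xb, xb, "-")^2 + outer(yb, yb, "-")^2 + outer(zb, zb, "-")^2
    d2 <- pmax(d2, db)
  }
  sqrt(d2)
}

#' Cluster bound poses into dominant binding modes
#'
#' Quality-threshold clustering on the pose-bead coordinates with a
#' max-per-bead displacement metric: repeatedly, every unassigned pose's
#' candidate cluster is the set of unassigned poses within `cutoff` of it;
#' the largest candidate is committed (ties broken by earliest pose index),
#' until `n_clusters` clusters are committed or poses are exhausted. Poses
#' left unassigned form a reported noise fraction. Committed clusters whose
#' anchor-bead centroids lie within `merge_cutoff` are then merged
#' iteratively, closest pair first, recomputing centroids after each merge —
#' this combines near-duplicate modes whose anchor positions coincide.
#' Cluster frequencies are fractions of all captured poses; clusters are
#' reported in descending frequency.
#'
#' The defaults (8 clusters, 0.6 nm cutoff, 0.4 nm anchor merge distance)
#' correspond to common practice for coarse-grained lipid binding modes.
#'
#' @param poses A `bound_pose_set`.
#' @param n_clusters Maximum number of committed clusters.
#' @param cutoff Max-per-bead displacement defining cluster membership (nm).
#' @param merge_cutoff Anchor-centroid distance below which committed
#'   clusters are combined (nm).
#' @return A `pose_clusters` object: list of clusters (each with `members`,
#'   `centroid` `[n_beads, 3]`, `anchor_centroid` (in-plane), `frequency`,
#'   `n_members`), a `noise_fraction`, and bookkeeping fields.
#' @export
cluster_poses <- function(poses, n_clusters = 8L, cutoff = 0.6,
                          merge_cutoff = 0.4) {
  stopifnot(inherits(poses, "bound_pose_set"))
  n <- dim(poses$coords)[1]
  empty <- structure(list(clusters = list(), noise_fraction = 0,
                          n_poses = n, bead_labels = poses$bead_labels,
                          parameters = list(n_clusters = n_clusters,
                                            cutoff = cutoff,
                                            merge_cutoff = merge_cutoff)),
                     class = "pose_clusters")
  if (n == 0L) return(empty)

  D <- pose_distance_matrix(poses$coords)
  within <- D <= cutoff
  alive <- rep(TRUE, n)
  committed <- list()
  while (length(committed) < n_clusters && any(alive)) {
    cand_size <- rowSums(within[, alive, drop = FALSE])
    cand_size[!alive] <- -1L
    seed_pose <- which.max(cand_size)   # which.max takes the earliest tie
    members <- which(alive & within[seed_pose, ])
    committed[[length(committed) + 1L]] <- members
    alive[members] <- FALSE
  }
  noise <- sum(alive) / n

  centroid_of <- function(members) {
    cs <- apply(poses$coords[members, , , drop = FALSE], c(2, 3), mean)
    matrix(cs, ncol = 3)
  }
  cents <- lapply(committed, centroid_of)
  ai <- poses$anchor_index
  anchor_xy <- function(cent) cent[ai, 1:2]

  # merge committed clusters whose anchor centroids are close, nearest first
  repeat {
    if (length(committed) < 2L) break
    axy <- do.call(rbind, lapply(cents, anchor_xy))
    dm <- as.matrix(stats::dist(axy))
    diag(dm) <- Inf
    mn <- min(dm)
    if (mn > merge_cutoff) break
    pr <- which(dm == mn, arr.ind = TRUE)[1, ]
    i <- min(pr); j <- max(pr)
    committed[[i]] <- sort(c(committed[[i]], committed[[j]]))
    committed[[j]] <- NULL
    cents <- lapply(committed, centroid_of)
  }

  freq <- vapply(committed, length, integer(1)) / n
  ord <- order(freq, decreasing = TRUE)
  clusters <- lapply(ord, function(i) {
    list(members = committed[[i]], centroid = cents[[i]],
         anchor_centroid = anchor_xy(cents[[i]]),
         frequency = freq[i], n_members = length(committed[[i]]))
  })
  out <- empty
  out$clusters <- clusters
  out$noise_fraction <- noise
  out
}

#' @export
print.pose_clusters <- function(x, ...) {
  cat(sprintf("pose_clusters: %d cluster(s) from %d poses (noise %.1f%%)\n",
              length(x$clusters), x$n_poses, 100 * x$noise_fraction))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  mode %d: %.1f%% (%d poses), anchor at (%.2f, %.2f) nm\n",
                i, 100 * cl$frequency, cl$n_members,
                cl$anchor_centroid[1], cl$anchor_centroid[2]))
  }
  invisible(x)
}

#' Serialize pose clusters
#'
#' `write_clusters_json` stores centroids, frequencies and member counts;
#' `write_cluster_centroids_pdb` writes centroid poses as a multi-model PDB
#' (coordinates converted to Angstrom) for visualization against deposited
#' structures.
#'
#' @param clusters A `pose_clusters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clusters_json <- function(clusters, path) {
  payload <- list(
    n_poses = clusters$n_poses,
    noise_fraction = clusters$noise_fraction,
    parameters = clusters$parameters,
    clusters = lapply(clusters$clusters, function(cl) {
      list(frequency = cl$frequency, n_members = cl$n_members,
           anchor_centroid = cl$anchor_centroid,
           centroid = apply(cl$centroid, 1, as.list))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_clusters_json
#' @export
write_cluster_centroids_pdb <- function(clusters, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(clusters$clusters)) {
    cl <- clusters$clusters[[i]]
    writeLines(sprintf("MODEL     %4d", i), con)
    for (b in seq_len(nrow(cl$centroid))) {
      writeLines(sprintf(
        "ATOM  %5d %-4s %-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
        b, substr(clusters$bead_labels[b], 1, 4), "LIP", i,
        10 * cl$centroid[b, 1], 10 * cl$centroid[b, 2],
        10 * cl$centroid[b, 3]), con)
    }
    writeLines("ENDMDL", con)
  }
  invisible(path)
}
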