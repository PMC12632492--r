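#' Density-enrichment map on the polar lattice
#'
#' Computes the time-averaged bead density of one species/role in one
#' leaflet on a polar lattice centered on the protein axis, and divides by a
#' bulk density to obtain enrichment (1 = no preference). Frames from all
#' replicas are pooled after the equilibration discard.
#'
#' Two bulk normalizations are available. `outer_annulus` (default) uses the
#' area-weighted mean density of the outermost radial ring of the same map —
#' a local, protein-distal reference that needs no extra simulation.
#' `bulk_ensemble` uses the leaflet-wide mean density of a protein-free
#' companion system of the same composition.
#'
#' @param ensemble A centered, leaflet-assigned [membrane_ensemble()].
#' @param lattice A [polar_lattice()].
#' @param species Lipid species label.
#' @param leaflet `"outer"` or `"inner"`.
#' @param bead_role Bead role counted: `"anchor"`, `"headgroup"` or
#'   `"tail"`.
#' @param bulk_mode `"outer_annulus"` or `"bulk_ensemble"`.
#' @param bulk_ensemble Protein-free [membrane_ensemble()]; required when
#'   `bulk_mode = "bulk_ensemble"`.
#' @return An `enrichment_map`: list with `density` and `enrichment`
#'   matrices (`n_radial` x `n_azimuthal`, nm^-2 and dimensionless),
#'   `bulk_density`, `n_frames_used`, and the call's labels.
#' @export
compute_enrichment_map <- function(ensemble, lattice = polar_lattice(),
                                   species, leaflet = "outer",
                                   bead_role = "headgroup",
                                   bulk_mode = c("outer_annulus",
                                                 "bulk_ensemble"),
                                   bulk_ensemble = NULL) {
  bulk_mode <- match.arg(bulk_mode)
  stopifnot(inherits(ensemble, "membrane_ensemble"))
  if (!ensemble$centered)
    stop_lipiddta("ensemble must be centered on the protein first", "input")
  ens <- post_discard(ensemble)
  sel <- select_beads(ens, species, leaflet, bead_role)
  n_frames <- sum(vapply(ens$replicas,
                         function(r) length(unique(r$time_ns)), integer(1)))
  if (n_frames == 0L)
    stop_lipiddta("no frames to analyse", "input")

  counts <- matrix(0, lattice$n_radial, lattice$n_azimuthal)
  bi <- lattice_bin_of(lattice, sel$x, sel$y)
  keep <- !is.na(bi$r_idx)
  if (any(keep)) {
    tab <- table(factor(bi$r_idx[keep], levels = seq_len(lattice$n_radial)),
                 factor(bi$theta_idx[keep],
                        levels = seq_len(lattice$n_azimuthal)))
    counts <- counts + unclass(tab)
  }
  area <- matrix(lattice$ring_area, lattice$n_radial, lattice$n_azimuthal)
  density <- counts / n_frames / area

  if (bulk_mode == "outer_annulus") {
    ring <- lattice$n_radial
    ring_counts <- sum(counts[ring, ])
    bulk_density <- ring_counts / n_frames /
      (lattice$ring_area[ring] * lattice$n_azimuthal)
  } else {
    if (is.null(bulk_ensemble) || bulk_ensemble$has_protein)
      stop_lipiddta("bulk_mode = 'bulk_ensemble' needs a protein-free ensemble",
                    "input")
    be <- post_discard(bulk_ensemble)
    bsel <- select_beads(be, species, leaflet, bead_role)
    bframes <- sum(vapply(be$replicas,
                          function(r) length(unique(r$time_ns)), integer(1)))
    bulk_density <- length(bsel$x) / bframes / prod(bulk_ensemble$box)
  }
  if (!is.finite(bulk_density) || bulk_density <= 0)
    stop_lipiddta(sprintf("bulk density of %s %s beads is zero; species absent?",
                          species, bead_role), "estimation")

  structure(list(lattice = lattice, species = species, leaflet = leaflet,
                 bead_role = bead_role, density = density,
                 enrichment = density / bulk_density,
                 bulk_density = bulk_density, n_frames_used = n_frames,
                 bulk_mode = bulk_mode),
            class = "enrichment_map")
}

# leaflet-/species-/role-filtered bead coordinates pooled over replicas
select_beads <- function(ens, sp, lf, role_lab) {
  parts <- lapply(ens$replicas, function(r)
    r[species == sp & leaflet == lf & role == role_lab, .(x, y)])
  flat <- data.table::rbindlist(parts)
  if (anyNA(flat$x))
    stop_lipiddta("leaflet labels missing; run assign_leaflets() first",
                  "input")
  flat
}

#' @export
print.enrichment_map <- function(x, ...) {
  cat(sprintf("enrichment_map: %s %s beads, %s leaflet, %d frames\n",
              x$species, x$bead_role, x$leaflet, x$n_frames_used))
  cat(sprintf("  bulk density %.4g nm^-2 (%s); enrichment range %.3g-%.3g\n",
              x$bulk_density, x$bulk_mode, min(x$enrichment),
              max(x$enrichment)))
  invisible(x)
}

#' Identify candidate binding sites as contiguous enriched bins
#'
#' Finds maximal connected components (4-neighbor adjacency with azimuthal
#' wrap-around) of lattice bins whose enrichment meets `threshold`, keeps
#' components with at least `min_bins` bins, and returns them ordered by
#' descending mean enrichment.
#'
#' @param map An `enrichment_map`.
#' @param threshold Minimum bin enrichment.
#' @param min_bins Minimum component size in bins.
#' @return List of [site_from_bins()] sites (possibly empty), each with a
#'   `mean_enrichment` attribute.
#' @export
identify_sites <- function(map, threshold = 1.5, min_bins = 3L) {
  stopifnot(inherits(map, "enrichment_map"))
  lat <- map$lattice
  hot <- map$enrichment >= threshold
  lab <- matrix(0L, lat$n_radial, lat$n_azimuthal)
  comp <- 0L
  for (ri in seq_len(lat$n_radial)) for (ti in seq_len(lat$n_azimuthal)) {
    if (!hot[ri, ti] || lab[ri, ti] != 0L) next
    comp <- comp + 1L
    queue <- list(c(ri, ti)); lab[ri, ti] <- comp
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      r0 <- cur[1]; t0 <- cur[2]
      nbrs <- list(c(r0 - 1L, t0), c(r0 + 1L, t0),
                   c(r0, (t0 %% lat$n_azimuthal) + 1L),
                   c(r0, ((t0 - 2L) %% lat$n_azimuthal) + 1L))
      for (nb in nbrs) {
        if (nb[1] < 1L || nb[1] > lat$n_radial) next
        if (hot[nb[1], nb[2]] && lab[nb[1], nb[2]] == 0L) {
          lab[nb[1], nb[2]] <- comp
          queue[[length(queue) + 1L]] <- nb
        }
      }
    }
  }
  if (comp == 0L) return(list())
  sites <- list()
  for (k in seq_len(comp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_bins) next
    bins <- cbind(r_idx = idx[, 1], theta_idx = idx[, 2])
    s <- site_from_bins(bins, lat, leaflet = map$leaflet,
                        species = map$species,
                        label = sprintf("site_%d", k))
    attr(s, "mean_enrichment") <-
      mean(map$enrichment[cbind(idx[, 1], idx[, 2])])
    sites[[length(sites) + 1L]] <- s
  }
  ord <- order(vapply(sites, function(s) attr(s, "mean_enrichment"),
                      numeric(1)), decreasing = TRUE)
  sites <- sites[ord]
  for (i in seq_along(sites)) sites[[i]]$label <- sprintf("site_%d", i)
  sites
}

#' Measure a site's protein-accessible area
#'
#' Estimates how much of a site's geometric area is actually available to
#' lipids (i.e. not excluded by protein) from a companion simulation of the
#' same protein in a single-species membrane. Each member bin contributes
#' `bin_area * min(1, density / bulk_density)`; the saturation at 1 keeps
#' thermal density fluctuations above bulk from inflating the area beyond
#' its geometric bound. For disk sites the same ratio is evaluated over the
#' disk as a whole.
#'
#' @param site A `site_definition`.
#' @param area_ensemble Centered, leaflet-assigned single-species
#'   [membrane_ensemble()] containing the protein.
#' @param lattice Lattice used for bin sites and for the bulk reference ring
#'   (defaults to the site's own lattice, or [polar_lattice()]).
#' @param bead_role Bead role whose density probes accessibility.
#' @return The site with `accessible_area` measured.
#' @export
accessible_area <- function(site, area_ensemble, lattice = NULL,
                            bead_role = "anchor") {
  stopifnot(inherits(site, "site_definition"),
            inherits(area_ensemble, "membrane_ensemble"))
  if (length(area_ensemble$composition) != 1L)
    stop_lipiddta("the accessible-area reference must be a single-species membrane",
                  "input")
  if (is.null(lattice)) lattice <- site$lattice %||% polar_lattice()
  sp <- names(area_ensemble$composition)
  map <- compute_enrichment_map(area_ensemble, lattice, species = sp,
                                leaflet = site$leaflet,
                                bead_role = bead_role,
                                bulk_mode = "outer_annulus")
  if (site$region$type == "bins") {
    b <- site$region$bins
    dens <- map$density[b]
    areas <- lattice_bin_area(lattice, b[, "r_idx"])
    acc <- sum(areas * pmin(1, dens / map$bulk_density))
  } else {
    ens <- post_discard(area_ensemble)
    sel <- select_beads(ens, sp, site$leaflet, bead_role)
    n_frames <- sum(vapply(ens$replicas,
                           function(r) length(unique(r$time_ns)),
                           integer(1)))
    inside <- in_site_region(site, sel$x, sel$y)
    dens <- sum(inside) / n_frames / site$geometric_area
    acc <- site$geometric_area * min(1, dens / map$bulk_density)
  }
  site$accessible_area <- acc
  site
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize an enrichment map to long-format CSV
#'
#' Columns: `r_idx, theta_idx, density, enrichment`.
#'
#' @param map An `enrichment_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_csv <- function(map, path) {
  lat <- map$lattice
  grid <- data.table::CJ(r_idx = seq_len(lat$n_radial),
                         theta_idx = seq_len(lat$n_azimuthal))
  grid[, density := map$density[cbind(r_idx, theta_idx)]]
  grid[, enrichment := map$enrichment[cbind(r_idx, theta_idx)]]
  data.table::fwrite(grid, path)
  invisible(path)
}

#' Polar heat map of an enrichment map
#'
#' Renders bin enrichment on the polar lattice (requires ggplot2).
#'
#' @param map An `enrichment_map`.
#' @return A ggplot object.
#' @export
plot_enrichment_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_lipiddta("ggplot2 is required for plotting", "input")
  lat <- map$lattice
  grid <- data.table::CJ(r_idx = seq_len(lat$n_radial),
                         theta_idx = seq_len(lat$n_azimuthal))
  grid[, enrichment := map$enrichment[cbind(r_idx, theta_idx)]]
  grid[, r_mid := (lat$r_edges[r_idx] + lat$r_edges[r_idx + 1L]) / 2]
  grid[, theta_mid := (theta_idx - 0.5) * lat$dtheta]
  ggplot2::ggplot(grid, ggplot2::aes(x = theta_mid, y = r_mid,
                                     fill = enrichment)) +
    ggplot2::geom_tile() +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = "r (nm)",
                  title = sprintf("%s %s enrichment, %s leaflet",
                                  map$species, map$bead_role, map$leaflet))
}
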