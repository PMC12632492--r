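#' Binding-site definitions
#'
#' A site is a region of one leaflet, either a set of contiguous polar
#' lattice bins (the output of [identify_sites()]) or a geometric disk in
#' the protein-centered plane (useful for matching a site seen as a cryo-EM
#' lipid density). Sites carry a geometric area and an accessible area; the
#' latter defaults to the geometric area until measured against a
#' single-species reference membrane with [accessible_area()].
#'
#' @param bins Integer matrix with columns `r_idx`, `theta_idx` (1-based).
#' @param lattice The [polar_lattice()] the bins refer to.
#' @param center,radius Disk center (nm, protein-centered) and radius (nm).
#' @param leaflet `"outer"` or `"inner"`.
#' @param species Lipid species the site is scored for.
#' @param label Free-text label (e.g. `"outer M3-M4"`).
#' @return An object of class `site_definition`.
#' @name site_definition
NULL

#' @rdname site_definition
#' @export
site_from_bins <- function(bins, lattice, leaflet, species, label = "site") {
  bins <- as.matrix(bins)
  if (ncol(bins) != 2L || nrow(bins) == 0L)
    stop_lipiddta("`bins` must be a non-empty two-column (r_idx, theta_idx) matrix",
                  "input")
  colnames(bins) <- c("r_idx", "theta_idx")
  storage.mode(bins) <- "integer"
  area <- sum(lattice_bin_area(lattice, bins[, "r_idx"]))
  structure(list(region = list(type = "bins", bins = bins),
                 lattice = lattice, leaflet = leaflet, species = species,
                 label = label, geometric_area = area,
                 accessible_area = area),
            class = "site_definition")
}

#' @rdname site_definition
#' @export
site_from_disk <- function(center, radius, leaflet, species, label = "site") {
  if (length(center) != 2L || radius <= 0)
    stop_lipiddta("disk site needs a length-2 center and positive radius",
                  "input")
  area <- pi * radius^2
  structure(list(region = list(type = "disk", center = as.numeric(center),
                               radius = radius),
                 lattice = NULL, leaflet = leaflet, species = species,
                 label = label, geometric_area = area,
                 accessible_area = area),
            class = "site_definition")
}

#' @export
print.site_definition <- function(x, ...) {
  desc <- if (x$region$type == "bins")
    sprintf("%d lattice bins", nrow(x$region$bins))
  else sprintf("disk r=%.2g nm at (%.2f, %.2f)", x$region$radius,
               x$region$center[1], x$region$center[2])
  cat(sprintf("site '%s' [%s, %s]: %s; area %.3g nm^2 (accessible %.3g)\n",
              x$label, x$species, x$leaflet, desc, x$geometric_area,
              x$accessible_area))
  invisible(x)
}

#' Override a site's accessible area
#'
#' Used for cross-state standardization: when comparing the same site
#' across two protein conformations, the accessible area measured on one
#' reference state is imposed on both so that occupancy odds are compared
#' over identical reference areas.
#'
#' @param site A `site_definition`.
#' @param value Accessible area in nm^2 (must not exceed geometric area).
#' @return The modified site.
#' @export
set_accessible_area <- function(site, value) {
  stopifnot(inherits(site, "site_definition"))
  if (value < 0 || value > site$geometric_area + 1e-9)
    stop_lipiddta("accessible area must lie in [0, geometric_area]", "input")
  site$accessible_area <- value
  site
}

# Rotate a site by 2*pi*subunit/n_symmetry about the protein axis.
# For bin sites the azimuthal bin count must be divisible by n_symmetry so
# the rotation maps bins onto bins exactly.
rotate_site <- function(site, subunit, n_symmetry = 5L) {
  if (subunit == 0L) return(site)
  if (site$region$type == "disk") {
    ang <- 2 * pi * subunit / n_symmetry
    rc <- rotate_xy(site$region$center[1], site$region$center[2], ang)
    site$region$center <- c(rc$x, rc$y)
    return(site)
  }
  lat <- site$lattice
  if (lat$n_azimuthal %% n_symmetry != 0L)
    stop_lipiddta(sprintf("azimuthal bin count %d is not divisible by the %d-fold symmetry; cannot rotate a bin site exactly",
                          lat$n_azimuthal, n_symmetry), "input")
  shift <- as.integer(subunit * lat$n_azimuthal / n_symmetry)
  b <- site$region$bins
  b[, "theta_idx"] <- ((b[, "theta_idx"] - 1L + shift) %% lat$n_azimuthal) + 1L
  site$region$bins <- b
  site
}

# Logical membership of protein-centered (x, y) points in the site region.
in_site_region <- function(site, x, y) {
  if (site$region$type == "disk") {
    c0 <- site$region$center
    return((x - c0[1])^2 + (y - c0[2])^2 <= site$region$radius^2)
  }
  bi <- lattice_bin_of(site$lattice, x, y)
  key <- paste(bi$r_idx, bi$theta_idx)
  site_keys <- paste(site$region$bins[, "r_idx"],
                     site$region$bins[, "theta_idx"])
  !is.na(bi$r_idx) & key %in% site_keys
}

#' Serialize sites to JSON
#'
#' @param sites A `site_definition` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_json <- function(sites, path) {
  if (inherits(sites, "site_definition")) sites <- list(sites)
  payload <- lapply(sites, function(s) {
    out <- list(label = s$label, species = s$species, leaflet = s$leaflet,
                geometric_area = s$geometric_area,
                accessible_area = s$accessible_area,
                region_type = s$region$type)
    if (s$region$type == "bins") {
      out$bins <- apply(s$region$bins, 1, as.list)
    } else {
      out$center <- s$region$center
      out$radius <- s$region$radius
    }
    out
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
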