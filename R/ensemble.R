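#' Membrane ensemble container
#'
#' A `membrane_ensemble` holds one or more replica trajectories of a
#' coarse-grained membrane (optionally with an embedded protein) in a
#' normalized long format. Each replica is a `data.table` with one row per
#' bead per frame and columns:
#'
#' * `time_ns` — frame time in ns
#' * `lipid_id` — integer identifying the parent lipid molecule
#' * `species` — lipid species label (e.g. `"POPC"`, `"DPOCL"`)
#' * `bead` — bead name within the lipid (e.g. `"LNK"`, `"PO1"`)
#' * `role` — bead role: `"anchor"`, `"headgroup"`, `"tail"` or `"other"`;
#'   every lipid has exactly one anchor bead per frame
#' * `x`, `y`, `z` — coordinates in nm; the membrane normal is z
#' * `leaflet` — `"outer"`, `"inner"` or `NA` before assignment
#'
#' The membrane normal is taken to be the z-like box axis (planar bilayer
#' under a semi-isotropic barostat); periodic wrapping uses the minimum-image
#' convention in the membrane plane only.
#'
#' @param replicas List of per-replica bead tables (coercible to
#'   `data.table`) with the columns above (`leaflet` optional).
#' @param box Numeric length-2, periodic box lengths (nm) in the membrane
#'   plane.
#' @param temperature Simulation temperature in K.
#' @param composition Named numeric vector of species mole fractions summing
#'   to 1. If `NULL`, computed from the mean share of lipids per species.
#' @param has_protein Logical; is a protein embedded?
#' @param discard_ns Initial equilibration segment (ns) excluded from all
#'   analyses; frames with `time_ns < discard_ns` are never consumed.
#' @param protein_centers List (one element per replica) of `data.table`s
#'   with columns `time_ns`, `px`, `py` giving the in-plane protein center of
#'   mass per frame; required when `has_protein` is `TRUE`.
#' @param centered Logical; have frames already been shifted so the protein
#'   center lies at the in-plane origin?
#' @return An object of class `membrane_ensemble`.
#' @seealso [center_on_protein()], [assign_leaflets()], [post_discard()]
#' @export
membrane_ensemble <- function(replicas, box, temperature = 320,
                              composition = NULL, has_protein = TRUE,
                              discard_ns = 0, protein_centers = NULL,
                              centered = FALSE) {
  if (!is.list(replicas) || length(replicas) == 0L)
    stop_lipiddta("`replicas` must be a non-empty list of bead tables", "input")
  need <- c("time_ns", "lipid_id", "species", "bead", "role", "x", "y", "z")
  replicas <- lapply(replicas, function(r) {
    r <- data.table::as.data.table(r)
    missing_cols <- setdiff(need, names(r))
    if (length(missing_cols))
      stop_lipiddta(paste0("replica table lacks column(s): ",
                           paste(missing_cols, collapse = ", ")), "format")
    if (!"leaflet" %in% names(r)) r[, leaflet := NA_character_]
    if (anyNA(r$x) || anyNA(r$y) || anyNA(r$z) ||
        any(!is.finite(r$x)) || any(!is.finite(r$y)) || any(!is.finite(r$z)))
      stop_lipiddta("bead positions must be finite", "format")
    data.table::setkey(r, time_ns, lipid_id)
    r
  })
  if (temperature <= 0)
    stop_lipiddta("temperature must be positive (Kelvin)", "input")
  if (length(box) != 2L || any(box <= 0))
    stop_lipiddta("`box` must be two positive in-plane lengths (nm)", "input")
  if (is.null(composition)) composition <- infer_composition(replicas)
  if (abs(sum(composition) - 1) > 1e-9)
    stop_lipiddta("species mole fractions must sum to 1", "input")
  if (has_protein && !centered) {
    if (is.null(protein_centers) || length(protein_centers) != length(replicas))
      stop_lipiddta("`protein_centers` must be supplied (one table per replica) when a protein is present and frames are not yet centered",
                    "input")
    protein_centers <- lapply(protein_centers, data.table::as.data.table)
  }
  structure(list(replicas = replicas,
                 box = as.numeric(box),
                 temperature = temperature,
                 composition = composition,
                 has_protein = isTRUE(has_protein),
                 discard_ns = discard_ns,
                 protein_centers = protein_centers,
                 centered = isTRUE(centered)),
            class = "membrane_ensemble")
}

# Mole fractions from anchor-bead counts, averaged over frames and replicas.
infer_composition <- function(replicas) {
  counts <- data.table::rbindlist(lapply(replicas, function(r)
    r[role == "anchor", .N, by = species]))
  counts <- counts[, .(N = sum(N)), by = species]
  stats::setNames(counts$N / sum(counts$N), counts$species)
}

#' @export
print.membrane_ensemble <- function(x, ...) {
  nf <- vapply(x$replicas, function(r) length(unique(r$time_ns)), integer(1))
  cat(sprintf("membrane_ensemble: %d replica(s), %s frames each (discard %g ns)\n",
              length(x$replicas), paste(nf, collapse = "/"), x$discard_ns))
  cat(sprintf("  box %g x %g nm, T = %g K, protein: %s, centered: %s\n",
              x$box[1], x$box[2], x$temperature,
              ifelse(x$has_protein, "yes", "no"),
              ifelse(x$centered, "yes", "no")))
  comp <- paste(sprintf("%s %.3f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}

#' Equilibration-filtered view of an ensemble
#'
#' Returns the ensemble with all frames at `time_ns < discard_ns` removed.
#' Every analysis operation in the package consumes its input through this
#' filter, so pre-equilibration frames can never leak into a result.
#'
#' @param ensemble A [membrane_ensemble()].
#' @return A `membrane_ensemble` whose replicas only contain retained frames.
#' @export
post_discard <- function(ensemble) {
  stopifnot(inherits(ensemble, "membrane_ensemble"))
  d <- ensemble$discard_ns
  if (d <= 0) return(ensemble)
  out <- ensemble
  out$replicas <- lapply(ensemble$replicas, function(r) r[time_ns >= d])
  if (!is.null(out$protein_centers))
    out$protein_centers <- lapply(out$protein_centers,
                                  function(p) p[time_ns >= d])
  if (any(vapply(out$replicas, nrow, integer(1)) == 0L))
    stop_lipiddta("no frames remain after the equilibration discard", "input")
  out$discard_ns <- 0
  out
}

#' Assign lipids to leaflets by the median anchor height
#'
#' Each lipid is assigned to the `outer` leaflet if its anchor bead's
#' membrane-normal coordinate exceeds the median anchor coordinate of all
#' lipids in that frame (the instantaneous midplane), otherwise `inner`.
#' The rule is deterministic and robust to drift of the whole bilayer along
#' the normal; it assumes a planar bilayer and does not handle curvature.
#'
#' @param x A [membrane_ensemble()] or a single-frame bead `data.frame`
#'   (columns `lipid_id`, `role`, `z`, plus any others).
#' @return The input with the `leaflet` column filled.
#' @export
assign_leaflets <- function(x) {
  if (inherits(x, "membrane_ensemble")) {
    x$replicas <- lapply(x$replicas, assign_leaflets_table)
    return(x)
  }
  assign_leaflets_table(data.table::as.data.table(x))
}

assign_leaflets_table <- function(dt) {
  anchors <- dt[role == "anchor"]
  if (nrow(anchors) == 0L)
    stop_lipiddta("frame contains no anchor beads", "degenerate")
  per_frame <- anchors[, {
    if (.N < 2L)
      stop_lipiddta("leaflet assignment needs at least 2 lipids per frame",
                    "degenerate")
    if (max(z) - min(z) < .Machine$double.eps^0.5)
      stop_lipiddta("all anchor beads at identical normal coordinate; leaflets are undefined",
                    "degenerate")
    .(lipid_id = lipid_id,
      leaflet = ifelse(z > stats::median(z), "outer", "inner"))
  }, by = time_ns]
  out <- data.table::copy(dt)
  if ("leaflet" %in% names(out)) out[, leaflet := NULL]
  out <- merge(out, per_frame, by = c("time_ns", "lipid_id"), sort = FALSE)
  data.table::setkey(out, time_ns, lipid_id)
  out
}

#' Center frames on the protein
#'
#' Shifts all in-plane coordinates (with minimum-image periodic wrapping) so
#' that the protein's in-plane center of mass lies at the origin in every
#' frame. No rotational fitting is applied: simulations of this kind restrain
#' the protein backbone, so the laboratory frame already is the protein
#' frame. The membrane-normal coordinate is untouched. Centering is
#' idempotent.
#'
#' @param x A [membrane_ensemble()] (with `has_protein = TRUE`) or a
#'   single-frame bead `data.frame` together with `protein_center` and `box`.
#' @param protein_center For the data-frame method: numeric length-2 in-plane
#'   protein center of mass.
#' @param box For the data-frame method: numeric length-2 box lengths (nm).
#' @return The centered input.
#' @export
center_on_protein <- function(x, protein_center = NULL, box = NULL) {
  if (inherits(x, "membrane_ensemble")) {
    if (!x$has_protein)
      stop_lipiddta("ensemble has no protein; centering is undefined",
                    "input")
    if (x$centered) return(x)
    out <- x
    out$replicas <- Map(function(r, pc) {
      r <- merge(r, pc, by = "time_ns", sort = FALSE)
      r[, x := wrap_minimum_image(x - px, out$box[1])]
      r[, y := wrap_minimum_image(y - py, out$box[2])]
      r[, c("px", "py") := NULL]
      data.table::setkey(r, time_ns, lipid_id)
      r
    }, x$replicas, x$protein_centers)
    out$protein_centers <- lapply(x$protein_centers, function(p) {
      p <- data.table::copy(p); p[, `:=`(px = 0, py = 0)]; p
    })
    out$centered <- TRUE
    return(out)
  }
  if (is.null(protein_center) || is.null(box))
    stop_lipiddta("`protein_center` and `box` are required to center a bare frame",
                  "input")
  dt <- data.table::as.data.table(x)
  dt[, x := wrap_minimum_image(x - protein_center[1], box[1])]
  dt[, y := wrap_minimum_image(y - protein_center[2], box[2])]
  dt
}

#' Write / read the normalized frame format
#'
#' The package's portable frame exchange format is a flat CSV with columns
#' `replica, time_ns, lipid_id, species, bead, role, x, y, z, leaflet`, so
#' that consumers without an MD stack can run every downstream module.
#' Ensemble-level metadata (box, temperature, protein flag, discard) travels
#' in a JSON side-car written next to the CSV.
#'
#' @param ensemble A [membrane_ensemble()].
#' @param path Output CSV path; the side-car is `<path>.meta.json`.
#' @return `write_frames_csv` returns `path` invisibly; `read_frames_csv`
#'   returns a `membrane_ensemble`.
#' @export
write_frames_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "membrane_ensemble"))
  tabs <- Map(function(r, i) {
    out <- data.table::copy(r)
    out[, replica := i]
    out
  }, ensemble$replicas, seq_along(ensemble$replicas))
  flat <- data.table::rbindlist(tabs)
  data.table::setcolorder(flat, c("replica", "time_ns", "lipid_id", "species",
                                  "bead", "role", "x", "y", "z", "leaflet"))
  data.table::fwrite(flat, path)
  meta <- list(box = ensemble$box, temperature = ensemble$temperature,
               composition = as.list(ensemble$composition),
               has_protein = ensemble$has_protein,
               discard_ns = ensemble$discard_ns,
               centered = ensemble$centered,
               protein_centers = ensemble$protein_centers)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_frames_csv
#' @export
read_frames_csv <- function(path) {
  flat <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  reps <- split(flat, by = "replica", keep.by = FALSE)
  pc <- NULL
  if (!is.null(meta$protein_centers) && length(meta$protein_centers))
    pc <- lapply(meta$protein_centers, data.table::as.data.table)
  membrane_ensemble(reps, box = meta$box, temperature = meta$temperature,
                    composition = unlist(meta$composition),
                    has_protein = meta$has_protein,
                    discard_ns = meta$discard_ns,
                    protein_centers = pc,
                    centered = meta$centered)
}
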