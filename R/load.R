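#' Read a bead-selection configuration
#'
#' The selection config names the protein and, per lipid species, which bead
#' is the anchor (the single reference bead per lipid, e.g. the central
#' linker bead of a cardiolipin) and which beads belong to the headgroup and
#' tails. YAML layout:
#'
#' ```yaml
#' protein_selection: [BB, SC1, SC2, SC3, SC4]   # protein bead/atom names
#' species:
#'   - name: DPOCL
#'     anchor_bead: LNK
#'     headgroup_beads: [PO1, PO2, GL1, GL2]
#'     tail_beads: [C1A, C2A]
#' ```
#'
#' `protein_selection` may alternatively be given as
#' `{resnames: [...]}` to select protein particles by residue name.
#'
#' @param path Path to a YAML file, or a list with the same structure.
#' @return A validated selection config (class `selection_config`).
#' @export
read_selection_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$species) || !length(cfg$species))
    stop_lipiddta("selection config must name at least one lipid species",
                  "config")
  if (is.null(cfg$protein_selection))
    stop_lipiddta("selection config must include `protein_selection`",
                  "config")
  for (sp in cfg$species) {
    if (is.null(sp$name) || is.null(sp$anchor_bead) ||
        length(sp$anchor_bead) != 1L)
      stop_lipiddta("each species needs `name` and a single `anchor_bead`",
                    "config")
  }
  structure(cfg, class = "selection_config")
}

# role of a bead name within one species' config
bead_role_for <- function(sp, bead_names) {
  role <- rep("other", length(bead_names))
  role[bead_names %in% sp$anchor_bead] <- "anchor"
  role[bead_names %in% unlist(sp$headgroup_beads)] <- "headgroup"
  role[bead_names %in% unlist(sp$tail_beads)] <- "tail"
  role
}

#' Load an MD ensemble from topology + trajectory files
#'
#' Reads a coarse-grained topology (GRO or PDB) and one trajectory file per
#' replica (DCD via bio3d, multi-model PDB, or a concatenated multi-frame
#' GRO), restricts beads to the configured lipid species, and computes the
#' in-plane protein center of mass per frame. Coordinates are converted to
#' nm. Species mole fractions are computed from lipid counts.
#'
#' XTC is not supported (no R reader exists); convert to DCD or to the
#' package's CSV frame format (see [read_frames_csv()]) upstream.
#'
#' @param topology_path GRO or PDB file defining atom names, residues, box.
#' @param trajectory_paths Character vector of trajectory files, one replica
#'   each. If empty, the topology's own coordinates form a single frame.
#' @param selection_config A [read_selection_config()] result (or path/list).
#' @param temperature Simulation temperature in K (thermostat setting).
#' @param discard_ns Equilibration discard in ns; production Martini runs of
#'   this kind discard the first 5 us (`discard_ns = 5000`).
#' @param dt_ns Time between stored frames in ns (trajectory formats carried
#'   here do not store reliable physical time).
#' @return A [membrane_ensemble()] (uncentered, leaflets unassigned).
#' @export
load_ensemble <- function(topology_path, trajectory_paths = character(),
                          selection_config, temperature = 320,
                          discard_ns = 5000, dt_ns = 1) {
  cfg <- read_selection_config(selection_config)
  top <- read_topology(topology_path)
  atoms <- top$atoms

  prot_sel <- cfg$protein_selection
  if (is.list(prot_sel) && !is.null(prot_sel$resnames)) {
    protein_rows <- which(atoms$resname %in% unlist(prot_sel$resnames))
  } else {
    protein_rows <- which(atoms$atom %in% unlist(prot_sel) &
                            !(atoms$resname %in%
                                vapply(cfg$species, `[[`, "", "name")))
  }
  has_protein <- length(protein_rows) > 0L

  # per-species bead rows; error out on config bead names absent from topology
  lip_rows <- integer(0); lip_role <- character(0)
  for (sp in cfg$species) {
    rows <- which(atoms$resname == sp$name)
    if (!length(rows)) next
    present <- unique(atoms$atom[rows])
    wanted <- c(sp$anchor_bead, unlist(sp$headgroup_beads),
                unlist(sp$tail_beads))
    missing_beads <- setdiff(wanted, present)
    if (length(missing_beads))
      stop_lipiddta(sprintf("bead(s) %s configured for species %s not present in topology",
                            paste(missing_beads, collapse = ", "), sp$name),
                    "config")
    lip_rows <- c(lip_rows, rows)
    lip_role <- c(lip_role, bead_role_for(sp, atoms$atom[rows]))
  }
  if (!length(lip_rows))
    stop_lipiddta("no configured lipid species found in topology", "config")

  # stable lipid ids: one per residue in file order
  res_key <- paste(atoms$resno[lip_rows], atoms$resname[lip_rows])
  lipid_id <- as.integer(factor(res_key, levels = unique(res_key)))

  n_anchor <- tapply(lip_role == "anchor", lipid_id, sum)
  if (any(n_anchor != 1L))
    stop_lipiddta("each lipid must carry exactly one anchor bead; check `anchor_bead` entries",
                  "config")

  frames_to_table <- function(xyz_nm) {
    n_atoms <- ncol(xyz_nm) / 3L
    if (n_atoms != nrow(atoms))
      stop_lipiddta(sprintf("trajectory frame has %d atoms but topology has %d",
                            n_atoms, nrow(atoms)), "format")
    n_frames <- nrow(xyz_nm)
    xi <- 3L * (lip_rows - 1L) + 1L
    beads_per_frame <- length(lip_rows)
    dt <- data.table::data.table(
      time_ns = rep((seq_len(n_frames) - 1L) * dt_ns, each = beads_per_frame),
      lipid_id = rep(lipid_id, n_frames),
      species = rep(atoms$resname[lip_rows], n_frames),
      bead = rep(atoms$atom[lip_rows], n_frames),
      role = rep(lip_role, n_frames),
      x = as.vector(t(xyz_nm[, xi, drop = FALSE])),
      y = as.vector(t(xyz_nm[, xi + 1L, drop = FALSE])),
      z = as.vector(t(xyz_nm[, xi + 2L, drop = FALSE])))
    pc <- NULL
    if (has_protein) {
      pxi <- 3L * (protein_rows - 1L) + 1L
      pc <- data.table::data.table(
        time_ns = (seq_len(n_frames) - 1L) * dt_ns,
        px = rowMeans(xyz_nm[, pxi, drop = FALSE]),
        py = rowMeans(xyz_nm[, pxi + 1L, drop = FALSE]))
    }
    list(beads = dt, pc = pc)
  }

  if (!length(trajectory_paths)) {
    xyzs <- list(matrix(t(cbind(top$atoms$x, top$atoms$y, top$atoms$z)),
                        nrow = 1L))
  } else {
    xyzs <- lapply(trajectory_paths, read_trajectory_xyz, top = top)
  }
  parsed <- lapply(xyzs, frames_to_table)

  membrane_ensemble(replicas = lapply(parsed, `[[`, "beads"),
                    box = top$box[1:2],
                    temperature = temperature,
                    has_protein = has_protein,
                    discard_ns = discard_ns,
                    protein_centers = if (has_protein)
                      lapply(parsed, `[[`, "pc") else NULL,
                    centered = FALSE)
}

# --- format readers -------------------------------------------------------

read_topology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    fr <- read_gro_frames(path)
    list(atoms = fr$frames[[1]], box = fr$box)
  } else if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, verbose = FALSE)
    a <- pdb$atom
    box <- pdb_box_nm(path)
    list(atoms = data.table::data.table(resno = a$resno, resname = a$resid,
                                        atom = a$elety,
                                        x = a$x / 10, y = a$y / 10,
                                        z = a$z / 10),
         box = box)
  } else stop_lipiddta(paste("unsupported topology format:", ext), "format")
}

pdb_box_nm <- function(path) {
  lines <- readLines(path, n = 200L)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (!length(cl))
    stop_lipiddta("PDB topology lacks a CRYST1 record; box is required",
                  "format")
  as.numeric(c(substr(cl[1], 7, 15), substr(cl[1], 16, 24),
               substr(cl[1], 25, 33))) / 10
}

# trajectory -> frames x (3*natoms) matrix in nm
read_trajectory_xyz <- function(path, top) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE)
    return(unclass(xyz) / 10)
  }
  if (ext %in% c("pdb", "ent")) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
    return(unclass(xyz) / 10)
  }
  if (ext == "gro") {
    fr <- read_gro_frames(path)
    return(do.call(rbind, lapply(fr$frames, function(f)
      as.vector(t(cbind(f$x, f$y, f$z))))))
  }
  if (ext == "xtc")
    stop_lipiddta("XTC trajectories are not readable from R; convert to DCD or CSV frames first",
                  "format")
  stop_lipiddta(paste("unsupported trajectory format:", ext), "format")
}

# Reads one or more concatenated frames from a GRO file (fixed-width format,
# coordinates already in nm). Returns list(frames = list(data.table), box).
read_gro_frames <- function(path) {
  lines <- readLines(path)
  frames <- list(); box <- NULL; i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n))
      stop_lipiddta("malformed GRO file: expected atom count line", "format")
    at_lines <- lines[(i + 2L):(i + 1L + n)]
    frames[[length(frames) + 1L]] <- data.table::data.table(
      resno = as.integer(substr(at_lines, 1, 5)),
      resname = trimws(substr(at_lines, 6, 10)),
      atom = trimws(substr(at_lines, 11, 15)),
      x = as.numeric(substr(at_lines, 21, 28)),
      y = as.numeric(substr(at_lines, 29, 36)),
      z = as.numeric(substr(at_lines, 37, 44)))
    box <- as.numeric(strsplit(trimws(lines[i + 2L + n]), "\\s+")[[1]])[1:3]
    i <- i + 3L + n
  }
  if (!length(frames))
    stop_lipiddta("GRO file contains no frames", "format")
  list(frames = frames, box = box)
}

# Write a single-frame GRO file from a bead table (nm coordinates).
write_gro_frame <- function(dt, box, path, title = "lipidDTA frame") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(title, con)
  writeLines(sprintf("%5d", nrow(dt)), con)
  writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     dt$lipid_id %% 100000L, substr(dt$species, 1, 5),
                     substr(dt$bead, 1, 5),
                     seq_len(nrow(dt)) %% 100000L,
                     dt$x, dt$y, dt$z), con)
  writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2],
                     if (length(box) > 2) box[3] else 10), con)
  invisible(path)
}
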