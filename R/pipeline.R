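#' Read a pipeline run configuration
#'
#' A run config bundles every stage parameter of the analysis pipeline.
#' Top-level keys: `output_dir`, `seed`, `input` (either
#' `type: synthetic` with a `spec` block mirroring [synthetic_spec()]
#' arguments — site lists may use `pentamer: {dG_true, ...}` shorthand — or
#' `type: files` with `topology`, `trajectories`, `selection`, and
#' optionally `bulk_topology`/`bulk_trajectories` and
#' `area_topology`/`area_trajectories`), plus optional `lattice`,
#' `enrichment`, `site`, `dta`, and `clustering` blocks. Every omitted
#' parameter falls back to the module defaults.
#'
#' @param path YAML file path, or a list with the same structure.
#' @return A validated config (class `run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$output_dir))
    stop_lipiddta("run config must set `output_dir`", "config")
  if (is.null(cfg$input$type) ||
      !cfg$input$type %in% c("synthetic", "files"))
    stop_lipiddta("run config `input.type` must be 'synthetic' or 'files'",
                  "config")
  if (cfg$input$type == "files") {
    for (key in c("topology", "trajectories", "selection"))
      if (is.null(cfg$input[[key]]))
        stop_lipiddta(sprintf("run config input lacks `%s`", key), "config")
    paths <- c(cfg$input$topology, unlist(cfg$input$trajectories))
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files))
      stop_lipiddta(paste("input file(s) not found:",
                          paste(missing_files, collapse = ", ")), "config")
  } else {
    if (is.null(cfg$input$spec))
      stop_lipiddta("synthetic input needs an `input.spec` block", "config")
  }
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "run_config")
}

spec_from_config <- function(blk, seed) {
  sites <- blk$sites %||% list()
  if (!is.null(blk$pentamer))
    sites <- c(sites, do.call(pentameric_sites, blk$pentamer))
  sites <- lapply(sites, function(s) {
    s$center <- as.numeric(unlist(s$center)); s
  })
  synthetic_spec(
    box = as.numeric(unlist(blk$box %||% c(25, 25))),
    n_lipids_per_leaflet = blk$n_lipids_per_leaflet %||% 1000L,
    composition = unlist(blk$composition %||%
                           list(POPC = 0.95, DPOCL = 0.05)),
    protein_radius = blk$protein_radius %||% 3.5,
    sites = sites,
    n_frames = blk$n_frames %||% 500L,
    n_replicas = blk$n_replicas %||% 1L,
    frame_correlation = blk$frame_correlation %||% 0,
    temperature = blk$temperature %||% 320,
    seed = seed,
    bead_set = blk$bead_set %||% "full")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop_lipiddta(sprintf("stage '%s' failed: %s", stage,
                          conditionMessage(e)), "input")
  })
}

#' Run the full analysis pipeline
#'
#' Executes load/center/leaflet assignment, the enrichment map, site
#' identification, the density-threshold affinity with occupancy
#' prediction, and pose clustering, writing all serialized outputs plus a
#' machine-readable provenance record into the config's output directory.
#' Identical config and seed produce byte-identical outputs.
#'
#' Files written: `enrichment.csv`, `sites.json`, `affinity.json`,
#' `pocc.csv`, `clusters.json`, `provenance.json`.
#'
#' @param config A [read_run_config()] result, YAML path, or list.
#' @return (Invisibly) a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)

  truth <- NULL; bulk <- NULL; area <- NULL
  if (cfg$input$type == "synthetic") {
    gen <- run_stage("simulate", {
      spec <- spec_from_config(cfg$input$spec, seed)
      g <- generate_ensemble(spec)
      refs <- generate_reference_ensembles(spec)
      list(ens = g$ensemble, truth = g$truth, refs = refs)
    })
    ens <- gen$ens; truth <- gen$truth
    bulk <- gen$refs$bulk; area <- gen$refs$area
  } else {
    ens <- run_stage("load", load_ensemble(
      cfg$input$topology, unlist(cfg$input$trajectories),
      cfg$input$selection,
      temperature = cfg$input$temperature %||% 320,
      discard_ns = cfg$input$discard_ns %||% 5000,
      dt_ns = cfg$input$dt_ns %||% 1))
    if (!is.null(cfg$input$bulk_topology))
      bulk <- run_stage("load bulk", load_ensemble(
        cfg$input$bulk_topology, unlist(cfg$input$bulk_trajectories),
        cfg$input$selection,
        temperature = cfg$input$temperature %||% 320,
        discard_ns = cfg$input$discard_ns %||% 5000,
        dt_ns = cfg$input$dt_ns %||% 1))
    if (!is.null(cfg$input$area_topology))
      area <- run_stage("load area", load_ensemble(
        cfg$input$area_topology, unlist(cfg$input$area_trajectories),
        cfg$input$selection,
        temperature = cfg$input$temperature %||% 320,
        discard_ns = cfg$input$discard_ns %||% 5000,
        dt_ns = cfg$input$dt_ns %||% 1))
  }

  ens <- run_stage("center", center_on_protein(ens))
  ens <- run_stage("leaflets", assign_leaflets(ens))
  if (!is.null(bulk)) bulk <- run_stage("leaflets", assign_leaflets(bulk))
  if (!is.null(area)) {
    area <- run_stage("center", center_on_protein(area))
    area <- run_stage("leaflets", assign_leaflets(area))
  }

  lat_cfg <- cfg$lattice %||% list()
  lattice <- polar_lattice(r_max = lat_cfg$r_max %||% 5,
                           n_radial = lat_cfg$n_radial %||% 10L,
                           n_azimuthal = lat_cfg$n_azimuthal %||% 90L)

  enr_cfg <- cfg$enrichment %||% list()
  species <- enr_cfg$species %||% names(ens$composition)[
    which.min(ens$composition)]
  leaflet <- enr_cfg$leaflet %||% "outer"
  emap <- run_stage("enrichment", compute_enrichment_map(
    ens, lattice, species = species, leaflet = leaflet,
    bead_role = enr_cfg$bead_role %||% "anchor",
    bulk_mode = enr_cfg$bulk_mode %||% "outer_annulus",
    bulk_ensemble = bulk))
  write_enrichment_csv(emap, file.path(cfg$output_dir, "enrichment.csv"))

  site_cfg <- cfg$site %||% list()
  if (!is.null(site_cfg$disk)) {
    site <- site_from_disk(as.numeric(unlist(site_cfg$disk$center)),
                           site_cfg$disk$radius, leaflet = leaflet,
                           species = species,
                           label = site_cfg$disk$label %||% "config site")
    sites <- list(site)
  } else {
    sites <- run_stage("sites", identify_sites(
      emap, threshold = site_cfg$threshold %||% 1.5,
      min_bins = site_cfg$min_bins %||% 3L))
    site <- if (length(sites)) sites[[1]] else NULL
  }
  if (!is.null(site) && !is.null(area))
    site <- run_stage("accessible area",
                      accessible_area(site, area, lattice))
  write_sites_json(sites, file.path(cfg$output_dir, "sites.json"))

  results <- list(ensemble = ens, truth = truth, map = emap, sites = sites)

  dta_cfg <- cfg$dta %||% list()
  if (!is.null(site) && !is.null(bulk)) {
    est <- run_stage("dta", {
      subunits <- dta_cfg$subunits %||% 0:4
      n_sym <- dta_cfg$n_symmetry %||% 5L
      traces <- list()
      for (ri in seq_along(ens$replicas))
        for (su in subunits)
          traces[[length(traces) + 1L]] <- occupancy_trace(
            ens, site, species, n_thresh = dta_cfg$n_thresh %||% 1L,
            replica = ri, subunit = su, n_symmetry = n_sym)
      p_ref <- reference_occupancy(
        bulk, site$accessible_area, species,
        n_thresh = dta_cfg$n_thresh %||% 1L,
        n_probes = dta_cfg$n_probes %||% 20L,
        seed = seed + 10L, leaflet = leaflet)
      delta_g_bind(traces, p_ref, temperature = ens$temperature)
    })
    write_affinity_json(est, file.path(cfg$output_dir, "affinity.json"))
    xb <- as.numeric(unlist(dta_cfg$xB_grid %||%
                              c(0.01, 0.02, 0.05, 0.1, 0.2, 0.5)))
    curve <- run_stage("pocc", pocc_curve(est, xb))
    write_pocc_csv(curve, file.path(cfg$output_dir, "pocc.csv"))
    results$estimate <- est; results$curve <- curve
  }

  cl_cfg <- cfg$clustering %||% list()
  if (!is.null(site) && !identical(cl_cfg$enabled %||% TRUE, FALSE)) {
    clusters <- run_stage("poses", {
      ps <- extract_poses(ens, site, species,
                          pose_beads = unlist(cl_cfg$pose_beads %||%
                                                c("LNK", "PO1", "PO2")))
      cluster_poses(ps, n_clusters = cl_cfg$n_clusters %||% 8L,
                    cutoff = cl_cfg$cutoff %||% 0.6,
                    merge_cutoff = cl_cfg$merge_cutoff %||% 0.4)
    })
    write_clusters_json(clusters,
                        file.path(cfg$output_dir, "clusters.json"))
    results$clusters <- clusters
  }

  prov <- list(
    config_hash = rlang::hash(unclass(cfg)),
    seed = seed,
    package_version = as.character(utils::packageVersion("lipidDTA")),
    n_replicas = length(ens$replicas),
    n_frames = vapply(ens$replicas,
                      function(r) length(unique(r$time_ns)), integer(1)),
    composition = as.list(ens$composition),
    temperature = ens$temperature)
  jsonlite::write_json(prov, file.path(cfg$output_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}

#' Write a synthetic dataset to disk
#'
#' Generates an ensemble (plus its two reference ensembles) from a spec and
#' serializes everything: frames CSV + metadata side-cars, the ground truth
#' JSON, and optionally a GRO snapshot of the first frame for visual
#' inspection.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param write_gro Also write `frame0.gro`?
#' @return (Invisibly) the output directory.
#' @export
write_synthetic_dataset <- function(spec, dir, write_gro = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- generate_ensemble(spec)
  refs <- generate_reference_ensembles(spec)
  write_frames_csv(gen$ensemble, file.path(dir, "frames.csv"))
  write_frames_csv(refs$area, file.path(dir, "area_frames.csv"))
  write_frames_csv(refs$bulk, file.path(dir, "bulk_frames.csv"))
  rt <- rt_kcal(spec$temperature)
  truth <- list(
    spec = unclass(spec),
    expected_site_enrichment = gen$truth$expected_site_enrichment,
    expected_occupancy_odds = gen$truth$expected_occupancy_odds)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  if (write_gro) {
    fr0 <- gen$ensemble$replicas[[1]][time_ns == min(time_ns)]
    write_gro_frame(fr0, spec$box, file.path(dir, "frame0.gro"))
  }
  invisible(dir)
}
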