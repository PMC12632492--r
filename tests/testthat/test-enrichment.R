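# fabricate an enrichment_map with a given enrichment matrix
fake_map <- function(enr, lattice = polar_lattice()) {
  structure(list(lattice = lattice, species = "DPOCL", leaflet = "outer",
                 bead_role = "anchor", density = enr, enrichment = enr,
                 bulk_density = 1, n_frames_used = 1,
                 bulk_mode = "outer_annulus"),
            class = "enrichment_map")
}

test_that("a hand-placed bead lands in the right bin with density 1/area", {
  lat <- polar_lattice()
  beads <- data.frame(time_ns = 0, lipid_id = 1:2, species = "DPOCL",
                      bead = "LNK", role = "anchor",
                      x = c(0.25 * cos(0.01), 4.75), y = c(0.25 * sin(0.01), 0),
                      z = 2, leaflet = "outer")
  ens <- manual_ensemble(beads, centered = TRUE)
  m <- compute_enrichment_map(ens, lat, species = "DPOCL",
                              leaflet = "outer", bead_role = "anchor")
  expect_equal(m$density[1, 1], 1 / lat$ring_area[1], tolerance = 1e-12)
  expect_equal(sum(m$density > 0), 2)  # only the two occupied bins
})

test_that("count conservation and outer-annulus normalization are exact", {
  spec <- small_spec(n_frames = 40L,
                     sites = pentameric_sites(-2, center_radius = 3.2,
                                              site_radius = 0.2))
  ens <- assign_leaflets(center_on_protein(generate_ensemble(spec)$ensemble))
  lat <- polar_lattice(r_max = 5)
  m <- compute_enrichment_map(ens, lat, species = "DPOCL", leaflet = "outer",
                              bead_role = "anchor")
  # sum(density * area) over bins == mean matching-bead count within r_max
  area <- matrix(lat$ring_area, lat$n_radial, lat$n_azimuthal)
  r <- ens$replicas[[1]][role == "anchor" & leaflet == "outer" &
                           species == "DPOCL"]
  mean_count <- sum(r$x^2 + r$y^2 < 25) / 40
  expect_equal(sum(m$density * area), mean_count, tolerance = 1e-12)
  # area-weighted mean enrichment of the outermost ring is exactly 1
  ring <- lat$n_radial
  w_mean <- sum(m$enrichment[ring, ] * lat$ring_area[ring]) /
    (lat$ring_area[ring] * lat$n_azimuthal)
  expect_equal(w_mean, 1, tolerance = 1e-12)
})

test_that("a uniform protein-free field shows enrichment 1 everywhere", {
  s <- synthetic_spec(box = c(12, 12), n_lipids_per_leaflet = 400L,
                      composition = c(POPC = 1), has_protein = FALSE,
                      n_frames = 400L, seed = 9L, bead_set = "anchor")
  ens <- generate_ensemble(s)$ensemble
  ens$centered <- TRUE  # no protein: recenter on the box middle by hand
  for (i in seq_along(ens$replicas)) {
    ens$replicas[[i]][, x := x - 6]
    ens$replicas[[i]][, y := y - 6]
  }
  lat <- polar_lattice(r_max = 5, n_radial = 5, n_azimuthal = 18)
  m <- compute_enrichment_map(ens, lat, species = "POPC", leaflet = "outer",
                              bead_role = "anchor")
  # per-ring aggregate within 3 SE (Poisson counting)
  dens0 <- 400 / 144
  for (ri in seq_len(lat$n_radial)) {
    ring_counts <- sum(m$density[ri, ]) * lat$ring_area[ri] * 400
    expected <- dens0 * lat$ring_area[ri] * lat$n_azimuthal * 400
    expect_lt(abs(ring_counts - expected), 3 * sqrt(expected))
  }
  # per-bin: allow 4.5 Poisson sd (90 bins tested jointly)
  counts <- m$density * matrix(lat$ring_area, 5, 18) * 400
  expected_bin <- dens0 * matrix(lat$ring_area, 5, 18) * 400
  expect_true(all(abs(counts - expected_bin) <=
                    4.5 * sqrt(expected_bin) + 3))
})

test_that("a -RT ln 3 well produces mean site-bin enrichment 3", {
  rt <- rt_kcal(320)
  lat <- polar_lattice()
  ctr <- c(3.25 * cos(lat$dtheta / 2), 3.25 * sin(lat$dtheta / 2))
  site <- list(center = ctr, radius = 0.45, leaflet = "outer",
               species = "LIPB", dG_true = -rt * log(3))
  s <- synthetic_spec(box = c(25, 25), n_lipids_per_leaflet = 600L,
                      composition = c(LIPA = 0.75, LIPB = 0.25),
                      protein_radius = 2.5, sites = list(site),
                      n_frames = 250L, seed = 13L, bead_set = "anchor")
  ens <- assign_leaflets(center_on_protein(generate_ensemble(s)$ensemble))
  m <- compute_enrichment_map(ens, lat, species = "LIPB", leaflet = "outer",
                              bead_role = "anchor")
  bins <- bins_in_disk(lat, ctr, 0.45)
  expect_gt(nrow(bins), 0)
  enr <- mean(m$enrichment[bins])
  site_counts <- sum(m$density[bins] *
                       lattice_bin_area(lat, bins[, 1])) * m$n_frames_used
  se <- enr * sqrt(1 / site_counts)  # bulk-ring error is far smaller
  expect_lt(abs(enr - 3), 3 * se)
})

test_that("site identification flood-fills contiguous enriched bins", {
  lat <- polar_lattice()
  flat <- matrix(1, 10, 90)
  expect_length(identify_sites(fake_map(flat), threshold = 1.5), 0)

  m1 <- flat
  m1[cbind(c(3, 3, 4), c(11, 12, 11))] <- 4
  sites <- identify_sites(fake_map(m1), threshold = 1.5, min_bins = 2)
  expect_length(sites, 1)
  got <- sites[[1]]$region$bins
  expect_setequal(paste(got[, 1], got[, 2]), c("3 11", "3 12", "4 11"))
  expect_equal(sites[[1]]$geometric_area,
               sum(lattice_bin_area(lat, c(3, 3, 4))), tolerance = 1e-12)
  # min_bins filters small components
  expect_length(identify_sites(fake_map(m1), threshold = 1.5, min_bins = 4), 0)

  # azimuthal wrap-around joins bins 1 and 90
  m2 <- flat
  m2[cbind(c(3, 3), c(1, 90))] <- 4
  wrap_sites <- identify_sites(fake_map(m2), threshold = 1.5, min_bins = 2)
  expect_length(wrap_sites, 1)
  expect_equal(nrow(wrap_sites[[1]]$region$bins), 2)

  # ordering: strongest component first
  m3 <- flat
  m3[cbind(c(2, 2), c(5, 6))] <- 2
  m3[cbind(c(7, 7), c(40, 41))] <- 9
  two <- identify_sites(fake_map(m3), threshold = 1.5, min_bins = 2)
  expect_length(two, 2)
  expect_equal(two[[1]]$region$bins[1, "r_idx"], c(r_idx = 7))
})

test_that("site identification commutes with azimuthal rotation", {
  flat <- matrix(1, 10, 90)
  flat[cbind(c(5, 5, 6, 5), c(20, 21, 20, 22))] <- 3
  base <- identify_sites(fake_map(flat), threshold = 1.5, min_bins = 2)
  for (shift in c(13, 45, 77)) {
    rot <- flat[, c((90 - shift + 1):90, 1:(90 - shift))]
    rsites <- identify_sites(fake_map(rot), threshold = 1.5, min_bins = 2)
    expect_length(rsites, length(base))
    got <- rsites[[1]]$region$bins
    want <- base[[1]]$region$bins
    want[, "theta_idx"] <- ((want[, "theta_idx"] - 1 + shift) %% 90) + 1
    expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  }
})

test_that("accessible area scales with the density ratio and saturates", {
  lat <- polar_lattice(r_max = 4, n_radial = 2, n_azimuthal = 4)
  # one frame: 6 beads per outer-ring bin, 1 bead in site bin (1,1) whose
  # density is then exactly half the bulk ring density
  mk_bead <- function(i, r, th) data.frame(
    time_ns = 0, lipid_id = i, species = "DPPC", bead = "LNK",
    role = "anchor", x = r * cos(th), y = r * sin(th), z = 2,
    leaflet = "outer")
  beads <- list(mk_bead(1, 1.0, 0.4))
  id <- 2
  for (ti in 1:4) for (k in 1:6) {
    beads[[length(beads) + 1]] <- mk_bead(id, 2.5 + 0.15 * k,
                                          (ti - 0.5) * lat$dtheta)
    id <- id + 1
  }
  ens <- manual_ensemble(data.table::rbindlist(beads), box = c(10, 10),
                         centered = TRUE, composition = c(DPPC = 1))
  site <- site_from_bins(cbind(1, 1), lat, "outer", "DPOCL")
  measured <- accessible_area(site, ens, lat)
  # density ratio: (1/A1) / (24/(4*A2)) with A1 = pi*4/4, A2 = pi*12/4
  ratio <- (1 / lat$ring_area[1]) / (24 / (4 * lat$ring_area[2]))
  expect_equal(measured$accessible_area, site$geometric_area * ratio,
               tolerance = 1e-12)
  expect_equal(ratio, 0.5, tolerance = 1e-12)

  # fully occluded bin -> zero accessible area
  empty_site <- site_from_bins(cbind(1, 2), lat, "outer", "DPOCL")
  expect_equal(accessible_area(empty_site, ens, lat)$accessible_area, 0)

  # saturation: density above bulk cannot inflate area beyond geometric
  crowded <- data.table::rbindlist(c(beads,
    lapply(1:30, function(k) mk_bead(100 + k, 1.0, 0.4))))
  ens2 <- manual_ensemble(crowded, box = c(10, 10), centered = TRUE,
                          composition = c(DPPC = 1))
  expect_equal(accessible_area(site, ens2, lat)$accessible_area,
               site$geometric_area, tolerance = 1e-12)

  # two-species reference is rejected
  ens3 <- manual_ensemble(data.table::rbindlist(beads), box = c(10, 10),
                          centered = TRUE,
                          composition = c(DPPC = 0.5, POPC = 0.5))
  expect_error(accessible_area(site, ens3, lat),
               class = "lipiddta_input_error")
})

test_that("an unobstructed synthetic site keeps its geometric area", {
  s <- synthetic_spec(box = c(14, 14), n_lipids_per_leaflet = 1000L,
                      composition = c(DPPC = 1), protein_radius = 2.0,
                      n_frames = 800L, seed = 17L, bead_set = "anchor")
  area_ens <- assign_leaflets(center_on_protein(generate_ensemble(s)$ensemble))
  lat <- polar_lattice(r_max = 5)
  site <- site_from_bins(bins_in_disk(lat, c(3.6, 0), 0.8), lat,
                         "outer", "DPOCL")
  measured <- accessible_area(site, area_ens, lat)
  expect_lt(abs(measured$accessible_area - site$geometric_area) /
              site$geometric_area, 0.05)
})

test_that("cross-state standardization overrides the accessible area", {
  site <- site_from_disk(c(4, 0), 0.5, "outer", "DPOCL")
  site2 <- set_accessible_area(site, 0.3)
  expect_equal(site2$accessible_area, 0.3)
  expect_error(set_accessible_area(site, 2 * site$geometric_area),
               class = "lipiddta_input_error")
})

test_that("absent species yields an estimation error, not NaN maps", {
  spec <- small_spec(n_frames = 10L)
  ens <- assign_leaflets(center_on_protein(generate_ensemble(spec)$ensemble))
  expect_error(compute_enrichment_map(ens, polar_lattice(),
                                      species = "CHOL", leaflet = "outer",
                                      bead_role = "anchor"),
               class = "lipiddta_estimation_error")
})
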