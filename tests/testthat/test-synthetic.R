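ext <- c(10, 12, 45, 47)

test_that("generators are bit-reproducible and leave the global RNG alone", {
  set.seed(999); rng_before <- .Random.seed
  a <- generate_landscape(ext, 8, 500, "random", seed = 7)
  b <- generate_landscape(ext, 8, 500, "random", seed = 7)
  expect_identical(a, b)
  expect_identical(rng_before, .Random.seed)
  expect_false(identical(a, generate_landscape(ext, 8, 500, "random", seed = 8)))
})

test_that("nested landscapes have exact subset-chain occupancy", {
  occ <- generate_landscape(ext, 10, 2000, "nested", seed = 3)
  cells <- split(paste(floor(occ$lon * 10), floor(occ$lat * 10)), occ$species_id)
  cells <- lapply(cells, unique)
  ids <- names(cells)[order(as.integer(sub("sp", "", names(cells))))]
  for (k in seq_along(ids)[-1]) {
    expect_true(all(cells[[ids[k]]] %in% cells[[ids[k - 1]]]),
                info = sprintf("species %s nested in %s", ids[k], ids[k - 1]))
  }
  # every retained window scores exactly 1
  res <- nos_sweep(occ, origin = c(ext[1], ext[3]), extent = c(ext[2], ext[4]))
  expect_true(nrow(res) > 0)
  expect_true(all(res$nbar == 1))
  expect_true(all(res$modularity == 0))
})

test_that("modular landscapes have zero cross-pool co-occurrence per cell", {
  occ <- generate_landscape(ext, 12, 3000, "modular", n_modules = 4, seed = 5)
  pool <- (as.integer(sub("sp", "", occ$species_id)) - 1L) %% 4L
  cell <- paste(floor(occ$lon * 10), floor(occ$lat * 10))
  pools_per_cell <- tapply(pool, cell, function(p) length(unique(p)))
  expect_true(all(pools_per_cell == 1L))
  expect_error(generate_landscape(ext, 12, 100, "modular", n_modules = 1000,
                                  seed = 1), "modules")
})

test_that("segregated landscapes never share a cell between species", {
  occ <- generate_landscape(ext, 8, 2000, "segregated", seed = 6)
  cell <- paste(floor(occ$lon * 10), floor(occ$lat * 10))
  expect_true(all(tapply(occ$species_id, cell,
                         function(s) length(unique(s))) == 1L))
})

test_that("random landscapes score near zero at moderate occupancy", {
  # the bounded-range standardization makes the null mean fill-dependent
  # (sparse pairs pull negative, saturated pairs positive); at moderate
  # cell occupancy the two cancel and the null centres near 0
  ext3 <- c(0, 3, 40, 43)
  occ <- generate_landscape(ext3, 20, 10000, "random", seed = 21)
  res <- nos_sweep(occ, origin = c(ext3[1], ext3[3]),
                   extent = c(ext3[2], ext3[4]))
  expect_gte(nrow(res), 30L)
  expect_lt(abs(mean(res$nbar)), 0.1)
})

test_that("longitudinal ranges restrict nested occupancy without breaking it", {
  rng <- cbind(c(10, 10.5), c(11, 12))
  occ <- generate_landscape(ext, 5, 1000, "nested",
                            thresholds = c(0, .1, .2, .3, .4),
                            lon_ranges = rbind(rng[1, ], rng[2, ], rng[2, ],
                                               rng[1, ], rng[2, ]),
                            seed = 9)
  expect_true(all(occ$lon[occ$species_id == "sp001"] <= 11))
  expect_true(all(occ$lon[occ$species_id == "sp002"] >= 10.5))
})

test_that("disturbance deletes exactly the requested count and relocates", {
  occ <- generate_landscape(ext, 8, 1000, "random", seed = 2)
  expect_identical(disturb(occ, 0.5, 0.5, intensity = 0, seed = 1), occ)
  half <- disturb(occ, deletion_fraction = 0.5, seed = 1)
  expect_identical(nrow(half), nrow(occ) %/% 2L)
  moved <- disturb(occ, swap_fraction = 0.3, extent = ext, seed = 4)
  expect_identical(nrow(moved), nrow(occ))
  expect_equal(sum(moved$lon != occ$lon | moved$lat != occ$lat),
               round(0.3 * nrow(occ)))
  expect_identical(moved$species_id, occ$species_id)
})

test_that("disturbance degrades nestedness monotonically in intensity", {
  wins <- sapply(c(0, 0.4, 0.8), function(level) {
    mean(sapply(1:5, function(s) {
      occ <- generate_landscape(ext, 10, 4000, "nested", seed = s)
      occ2 <- disturb(occ, deletion_fraction = 0.3, swap_fraction = 0.5,
                      intensity = level, extent = ext, seed = s + 100)
      res <- nos_sweep(occ2, origin = c(ext[1], ext[3]),
                       extent = c(ext[2], ext[4]))
      mean(res$nbar)
    }))
  })
  expect_true(all(diff(wins) < 0))
})

test_that("region tiling partitions the extent with the requested intact share", {
  reg <- generate_regions(c(0, 2, 0, 2), 4, intact_fraction = 0.5, seed = 3)
  expect_length(reg$ecoregions, 4L)
  expect_length(reg$intact, 2L)
  # four 1x1 rectangles
  areas <- sapply(reg$ecoregions, function(f) {
    r <- f$rings[[1]]
    diff(range(r[, 1])) * diff(range(r[, 2]))
  })
  expect_equal(areas, rep(1, 4))
  # every window centroid falls in exactly one region (boundary -> first)
  cx <- rep(seq(0.5, 1.5, 0.1), 11)
  cy <- rep(seq(0.5, 1.5, 0.1), each = 11)
  expect_false(anyNA(locate_points(cx, cy, reg$ecoregions)))
  expect_length(generate_regions(c(0, 2, 0, 2), 4, 0, seed = 1)$intact, 0L)
})

test_that("nested PNV maps project into subset-chain matrices", {
  pnv <- generate_pnv_map(c(0, 2, 0, 2), 3, "nested", n_species = 8)
  sizes <- sapply(pnv, function(f) length(f$properties$species))
  expect_true(all(diff(sizes) <= 0))   # richest band first (south)
  for (b in 2:3)
    expect_true(all(pnv[[b]]$properties$species %in%
                      pnv[[b - 1]]$properties$species))
  set.seed(31)
  loc <- data.frame(lon = runif(3000, 0, 2), lat = runif(3000, 0, 2))
  occ <- pnv_project(loc, pnv)
  res <- nos_sweep(occ, origin = c(0, 0), extent = c(2, 2))
  expect_true(all(res$nbar == 1))
  # disjoint pools give modular projected matrices instead
  pnv2 <- generate_pnv_map(c(0, 2, 0, 2), 3, "disjoint", n_species = 9)
  occ2 <- pnv_project(loc, pnv2)
  res2 <- nos_sweep(occ2, origin = c(0, 0), extent = c(2, 2))
  expect_gt(mean(res2$modularity), mean(res$modularity))
})

test_that("modular landscapes are more modular than random ones", {
  diffs <- sapply(1:8, function(s) {
    m <- generate_landscape(ext, 12, 6000, "modular", n_modules = 4, seed = s)
    r <- generate_landscape(ext, 12, 6000, "random", seed = s + 500)
    rm_ <- nos_sweep(m, origin = c(ext[1], ext[3]), extent = c(ext[2], ext[4]))
    rr <- nos_sweep(r, origin = c(ext[1], ext[3]), extent = c(ext[2], ext[4]))
    mean(rm_$modularity) - mean(rr$modularity)
  })
  expect_gte(sum(diffs > 0), 7L)
})
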