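occ_df <- function(species, lon, lat)
  data.frame(species_id = species, lon = lon, lat = lat)

test_that("window binning is half-open and exhaustive over the 100 cells", {
  # record exactly on a cell's upper edge belongs to the next cell
  occ <- occ_df(c("a", "b"), c(10.0, 10.1), c(50.05, 50.05))
  w <- build_window_matrix(occ, 10, 50, min_rows = 1L, min_cols = 1L)
  expect_true(w$retained)
  expect_identical(dim(w$matrix), c(2L, 2L))  # two distinct cells
  # every in-window record maps to exactly one cell
  set.seed(4)
  occ <- occ_df(sample(letters[1:6], 300, TRUE),
                runif(300, 10, 11), runif(300, 50, 51))
  w <- build_window_matrix(occ, 10, 50, min_rows = 1L, min_cols = 1L)
  expect_identical(sum(w$matrix), nrow(unique(
    data.frame(occ$species_id, floor(occ$lon * 10), floor(occ$lat * 10)))))
  expect_lte(ncol(w$matrix), 100L)
})

test_that("retention rule rejects small matrices with a reason", {
  occ <- occ_df(sprintf("s%d", 1:6), 10 + (0:5) / 10 + 0.05, rep(50.05, 6))
  w <- build_window_matrix(occ, 10, 50)
  expect_true(w$retained)   # 6 species in 6 cells
  occ4 <- occ_df(sprintf("s%d", rep(1:4, each = 10)),
                 rep(10 + (0:9) / 10 + 0.05, 4), rep(50.05, 40))
  w <- build_window_matrix(occ4, 10, 50)
  expect_false(w$retained)
  expect_identical(w$reason, "rows < 5")
  expect_identical(build_window_matrix(occ4[0, ], 10, 50)$reason, "empty window")
})

test_that("window centroid sits half a window from the anchor", {
  occ <- occ_df("a", 10.5, 50.5)
  w <- build_window_matrix(occ, 10, 50, min_rows = 1L, min_cols = 1L)
  expect_equal(c(w$centroid_lon, w$centroid_lat), c(10.5, 50.5))
})

test_that("sweep enumerates the 0.1-degree anchor lattice", {
  # 1.5 x 1.5 degree extent: 6 anchors per axis
  set.seed(9)
  occ <- occ_df(sample(sprintf("s%d", 1:10), 4000, TRUE),
                runif(4000, 20, 21.5), runif(4000, 40, 41.5))
  res <- nos_sweep(occ, origin = c(20, 40), extent = c(21.5, 41.5))
  expect_identical(attr(res, "n_anchors"), 36L)
  expect_identical(nrow(res), 36L)  # dense data: every window retained
  # adjacent centroids differ by exactly 0.1 degree
  lon_steps <- diff(sort(unique(res$centroid_lon)))
  expect_equal(lon_steps, rep(0.1, 5))
  # deterministic row-major order, south-west to north-east
  expect_true(!is.unsorted(res$centroid_lat))
})

test_that("sweep is invariant to record order and to coordinate translation", {
  set.seed(10)
  occ <- occ_df(sample(sprintf("s%d", 1:8), 2500, TRUE),
                runif(2500, 0, 1.3), runif(2500, 0, 1.3))
  a <- nos_sweep(occ, origin = c(0, 0), extent = c(1.3, 1.3))
  b <- nos_sweep(occ[sample(nrow(occ)), ], origin = c(0, 0), extent = c(1.3, 1.3))
  expect_identical(a, b)
  shifted <- occ
  shifted$lon <- occ$lon + 3.2; shifted$lat <- occ$lat - 1.4
  c_ <- nos_sweep(shifted, origin = c(3.2, -1.4), extent = c(4.5, -0.1))
  expect_equal(c_$centroid_lon, a$centroid_lon + 3.2)
  expect_equal(c_$centroid_lat, a$centroid_lat - 1.4)
  expect_equal(c_$nbar, a$nbar)
  expect_equal(c_$modularity, a$modularity)
})

test_that("sweep agrees with the single-window builder at every anchor", {
  set.seed(11)
  occ <- occ_df(sample(sprintf("s%d", 1:8), 1500, TRUE),
                runif(1500, 5, 6.2), runif(1500, 5, 6.2))
  res <- nos_sweep(occ, origin = c(5, 5), extent = c(6.2, 6.2))
  for (i in seq_len(nrow(res))) {
    w <- build_window_matrix(occ, res$centroid_lon[i] - 0.5,
                             res$centroid_lat[i] - 0.5)
    st <- nos_structure(w$matrix)
    expect_equal(res$nbar[i], st$nbar)
    expect_equal(res$modularity[i], st$modularity)
    expect_identical(res$n_species[i], nrow(w$matrix))
  }
})

test_that("empty occurrence sets yield an empty sweep with a warning", {
  occ <- occ_df(character(0), numeric(0), numeric(0))
  expect_warning(
    res <- nos_sweep(occ, origin = c(0, 0), extent = c(1.5, 1.5)),
    "no window")
  expect_identical(nrow(res), 0L)
})

test_that("habitat mask keeps allowed classes only, first feature wins", {
  mask <- list(rect_feature(0, 1, 0, 1, properties = list(class = "forest")),
               rect_feature(1, 2, 0, 1, properties = list(class = "urban")))
  occ <- occ_df(sprintf("s%d", 1:10),
                c(0.2, 0.4, 0.6, 0.8, 0.5, 1.2, 1.5, 1.9, 5, 6),
                rep(0.5, 10))
  kept <- mask_filter(occ, mask, "forest")
  expect_identical(nrow(kept), 5L)
  expect_identical(attr(kept, "n_dropped"), 5L)
  # all classes allowed: identity on in-mask points
  all_in <- mask_filter(occ, mask, c("forest", "urban"))
  expect_identical(nrow(all_in), 8L)
  # shared boundary: the point belongs to the first polygon in file order
  edge <- occ_df("s1", 1, 0.5)
  expect_identical(nrow(mask_filter(edge, mask, "forest")), 1L)
  expect_identical(nrow(mask_filter(edge, rev(mask), "forest")), 0L)
  expect_error(mask_filter(occ, list(), "forest"), "no polygons")
})

test_that("PNV projection emits one record per listed species", {
  pnv <- list(
    rect_feature(0, 1, 0, 1, properties = list(
      unit = "u1", species = c("a", "b", "c"))),
    rect_feature(1, 2, 0, 1, properties = list(unit = "u2", species = "d")))
  loc <- data.frame(lon = c(0.5, 1.5, 9), lat = c(0.5, 0.5, 0.5))
  out <- pnv_project(loc, pnv)
  expect_identical(nrow(out), 4L)
  expect_setequal(out$species_id[out$lon == 0.5], c("a", "b", "c"))
  expect_identical(out$species_id[out$lon == 1.5], "d")
  # overlapping polygons: first containing polygon wins
  over <- list(
    rect_feature(0, 2, 0, 1, properties = list(unit = "w", species = "x")),
    rect_feature(0, 1, 0, 1, properties = list(unit = "v", species = "y")))
  expect_identical(pnv_project(data.frame(lon = 0.5, lat = 0.5), over)$species_id,
                   "x")
  empty <- list(rect_feature(0, 1, 0, 1,
                             properties = list(unit = "e", species = character(0))))
  expect_warning(out <- pnv_project(loc, empty), "empty species list")
  expect_identical(nrow(out), 0L)
})

test_that("occurrence files round-trip and malformed rows are named", {
  occ <- occ_df(c("a", "b"), c(1.25, 2.5), c(3.5, 4.75))
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write_occurrences(occ, path, meta = c(seed = 42))
  expect_identical(readLines(path, n = 1L), "# seed: 42")
  back <- read_occurrences(path)
  expect_equal(back, occ)
  writeLines(c("species_id,lon,lat", "a,1,2", ",3,4"), path)
  expect_error(read_occurrences(path), "row 2")
})
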