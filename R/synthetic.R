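#' Synthetic landscapes with controllable spatial structure
#'
#' Generates point occurrence datasets whose presence-absence matrices have
#' known structure, so every stage of the pipeline can be exercised and
#' validated without external data:
#'
#' * `"nested"` — one shared latent suitability field (a south-to-north
#'   gradient); species `k` is present wherever suitability exceeds its
#'   threshold, thresholds strictly ordered, so species' occupied-cell sets
#'   form exact subset chains and every retained window scores `nbar = 1`.
#' * `"modular"` — the extent is cut into longitudinal blocks aligned to
#'   the 0.1-degree cell lattice, each populated only from its own disjoint
#'   species pool: no cross-pool co-occurrence in any cell.
#' * `"segregated"` — every 0.1-degree cell is owned by a single species,
#'   so no two species ever share a cell.
#' * `"random"` — species and locations drawn independently and uniformly.
#'
#' @param extent bounding box `c(lon_min, lon_max, lat_min, lat_max)` in
#'   decimal degrees; at least 1 x 1 degree.
#' @param n_species number of species (>= 5).
#' @param n_points number of sampled plot locations (`"nested"`) or
#'   occurrence records (other modes).
#' @param structure one of `"nested"`, `"modular"`, `"segregated"`,
#'   `"random"`.
#' @param n_modules number of longitudinal blocks in `"modular"` mode.
#' @param thresholds optional strictly increasing suitability thresholds in
#'   `[0, 1)`, one per species, for `"nested"` mode; default
#'   `(k - 1) / n_species`.
#' @param lon_ranges optional `n_species` x 2 matrix of longitudinal range
#'   limits for `"nested"` mode: species `k` occurs only at longitudes
#'   within `lon_ranges[k, ]`. Default: every range spans the whole extent,
#'   preserving exact subset chains everywhere. Bounded staggered ranges
#'   (see [sample_lon_ranges]) add spatial species turnover, so windows
#'   differ in how much their resident ranges overlap and `nbar` varies
#'   smoothly across the landscape while staying deterministic at cell
#'   level — the structure is then carried by dense range blocks rather
#'   than by individual records.
#' @param seed integer seed (mandatory; generation is bit-reproducible).
#' @return Occurrence data frame (`species_id`, `lon`, `lat`, `source`).
#' @export
generate_landscape <- function(extent, n_species, n_points,
                               structure = c("nested", "modular",
                                             "segregated", "random"),
                               n_modules = 4L, thresholds = NULL,
                               lon_ranges = NULL, seed) {
  structure <- match.arg(structure)
  stopifnot(length(extent) == 4L, extent[2] > extent[1], extent[4] > extent[3])
  if (extent[2] - extent[1] < 1 || extent[4] - extent[3] < 1)
    stop("extent must span at least 1 x 1 degree", call. = FALSE)
  if (n_species < 5L) stop("n_species must be at least 5", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  sp_ids <- sprintf("sp%03d", seq_len(n_species))
  with_seed(seed, {
    lon <- stats::runif(n_points, extent[1], extent[2])
    lat <- stats::runif(n_points, extent[3], extent[4])
    occ <- switch(structure,
      nested = {
        thr <- thresholds %||% ((seq_len(n_species) - 1) / n_species)
        if (length(thr) != n_species || any(diff(thr) <= 0))
          stop("thresholds must be strictly increasing, one per species",
               call. = FALSE)
        if (is.null(lon_ranges))
          lon_ranges <- cbind(rep(extent[1], n_species), extent[2])
        lon_ranges <- as.matrix(lon_ranges)
        stopifnot(nrow(lon_ranges) == n_species, ncol(lon_ranges) == 2L)
        u <- (lat - extent[3]) / (extent[4] - extent[3])
        pres <- outer(u, thr, ">") &
          outer(lon, lon_ranges[, 1L], ">=") & outer(lon, lon_ranges[, 2L], "<=")
        hit <- which(pres, arr.ind = TRUE)
        data.frame(species_id = sp_ids[hit[, 2L]],
                   lon = lon[hit[, 1L]], lat = lat[hit[, 1L]])
      },
      modular = {
        wt <- to_tenths(extent[2]) - to_tenths(extent[1])  # width in cells
        if (n_modules > wt || n_modules > n_species)
          stop("more modules than cells or species", call. = FALSE)
        pool <- rep(seq_len(n_modules), length.out = n_species) # disjoint pools
        edges <- to_tenths(extent[1]) +
          round(seq(0, wt, length.out = n_modules + 1L))        # lattice-aligned
        block <- findInterval(to_tenths(lon), edges[-1L]) + 1L
        block[block > n_modules] <- n_modules
        sp <- vapply(block, function(b) {
          cand <- which(pool == b)
          cand[sample.int(length(cand), 1L)]
        }, integer(1))
        data.frame(species_id = sp_ids[sp], lon = lon, lat = lat)
      },
      segregated = {
        cx <- to_tenths(extent[1]):(to_tenths(extent[2]) - 1L)
        cy <- to_tenths(extent[3]):(to_tenths(extent[4]) - 1L)
        cells <- expand.grid(cx = cx, cy = cy)
        owner <- sample(rep(seq_len(n_species),
                            length.out = nrow(cells)))   # each cell one species
        pick <- sample.int(nrow(cells), n_points, replace = TRUE)
        data.frame(
          species_id = sp_ids[owner[pick]],
          lon = (cells$cx[pick] + stats::runif(n_points)) / 10,
          lat = (cells$cy[pick] + stats::runif(n_points)) / 10)
      },
      random = data.frame(
        species_id = sp_ids[sample.int(n_species, n_points, replace = TRUE)],
        lon = lon, lat = lat)
    )
    occ$source <- structure
    occ
  })
}

#' Random staggered longitudinal ranges
#'
#' Draws one bounded longitudinal range per species: the left edge uniform
#' over the extent (wrapped so every range fits) and the width uniform
#' between `min_width` and `max_width` degrees. Used with
#' [generate_landscape]'s nested mode to create species turnover along the
#' east-west axis.
#'
#' @inheritParams generate_landscape
#' @param min_width,max_width range width bounds in degrees.
#' @return `n_species` x 2 matrix of range limits.
#' @export
sample_lon_ranges <- function(extent, n_species, min_width = 1,
                              max_width = 3, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  span <- extent[2] - extent[1]
  stopifnot(min_width <= max_width, max_width <= span)
  with_seed(seed, {
    w <- stats::runif(n_species, min_width, max_width)
    a <- extent[1] + stats::runif(n_species) * (span - w)
    cbind(a, a + w)
  })
}

#' Synthetic potential-vegetation polygon map
#'
#' Tiles the extent into latitudinal-band polygons, each carrying a species
#' list, standing in for an expert potential-natural-vegetation map. With
#' `pools = "nested"` the band species lists form a subset chain (richest
#' in the south), so projected matrices are perfectly nested; with
#' `"disjoint"` each band has its own pool, producing modular projected
#' matrices. An explicit list of character vectors (south to north) may be
#' given instead.
#'
#' @inheritParams generate_landscape
#' @param n_units number of latitudinal bands.
#' @param pools `"nested"`, `"disjoint"`, or a list of species-id vectors.
#' @param n_species pool size used by the named schemes.
#' @return List of polygon features with properties `unit` and `species`.
#' @export
generate_pnv_map <- function(extent, n_units, pools = "nested",
                             n_species = 20L, seed = 1L) {
  stopifnot(n_units >= 1L)
  sp_ids <- sprintf("sp%03d", seq_len(n_species))
  pool_list <- if (is.list(pools)) {
    if (length(pools) != n_units) stop("one pool per band", call. = FALSE)
    pools
  } else if (pools == "nested") {
    sizes <- round(seq(n_species, max(5, ceiling(n_species / 2)),
                       length.out = n_units))
    lapply(sizes, function(s) sp_ids[seq_len(s)])
  } else if (pools == "disjoint") {
    split(sp_ids, rep(seq_len(n_units), length.out = n_species))
  } else stop("pools must be 'nested', 'disjoint' or a list", call. = FALSE)
  if (any(vapply(pool_list, length, integer(1)) == 0L))
    stop("pools must be non-empty", call. = FALSE)
  edges <- seq(extent[3], extent[4], length.out = n_units + 1L)
  lapply(seq_len(n_units), function(b)
    rect_feature(extent[1], extent[2], edges[b], edges[b + 1L],
                 properties = list(unit = sprintf("band%02d", b),
                                   species = pool_list[[b]])))
}

#' Degrade a landscape with deletion and relocation noise
#'
#' Two orthogonal disturbance channels: a fraction of records is deleted
#' outright (exactly `round(n * intensity * deletion_fraction)` records),
#' and a fraction of the survivors is relocated to uniform random positions
#' in the extent. Deletion mimics loss of occurrences; relocation mixes
#' species across the landscape, destroying both nestedness and modular
#' block structure. `intensity` scales both channels, so `intensity = 0`
#' is the identity.
#'
#' @param occ occurrence data frame.
#' @param deletion_fraction,swap_fraction per-channel fractions in `[0, 1]`.
#' @param intensity overall multiplier in `[0, 1]`.
#' @param extent relocation bounding box; default the data bounding box.
#' @param seed integer seed (mandatory).
#' @return Disturbed occurrence data frame.
#' @export
disturb <- function(occ, deletion_fraction = 0, swap_fraction = 0,
                    intensity = 1, extent = NULL, seed) {
  stopifnot(deletion_fraction >= 0, deletion_fraction <= 1,
            swap_fraction >= 0, swap_fraction <= 1,
            intensity >= 0, intensity <= 1)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  if (intensity == 0 || nrow(occ) == 0L) return(occ)
  if (is.null(extent))
    extent <- c(min(occ$lon), max(occ$lon), min(occ$lat), max(occ$lat))
  with_seed(seed, {
    n <- nrow(occ)
    n_del <- round(n * intensity * deletion_fraction)
    if (n_del > 0L) occ <- occ[-sample.int(n, n_del), , drop = FALSE]
    n2 <- nrow(occ)
    n_swap <- round(n2 * intensity * swap_fraction)
    if (n_swap > 0L) {
      at <- sample.int(n2, n_swap)
      occ$lon[at] <- stats::runif(n_swap, extent[1], extent[2])
      occ$lat[at] <- stats::runif(n_swap, extent[3], extent[4])
    }
    rownames(occ) <- NULL
    occ
  })
}

#' Spatially graded disturbance
#'
#' Applies [disturb] with intensity increasing linearly from 0 at the
#' western edge to `max_intensity` at the eastern edge, over `n_strips`
#' longitudinal strips — emulating a landscape where disturbance pressure
#' varies in space, which yields a realistic spread of structure values
#' across windows. Relocation is confined to each record's own strip
#' (disturbance mixes assemblages locally), so lightly disturbed strips
#' are not contaminated by heavily disturbed ones.
#'
#' @inheritParams disturb
#' @param max_intensity intensity of the easternmost strip.
#' @param n_strips number of longitudinal strips.
#' @export
disturb_gradient <- function(occ, extent, deletion_fraction = 0,
                             swap_fraction = 1, max_intensity = 1,
                             n_strips = 8L, seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  edges <- seq(extent[1], extent[2], length.out = n_strips + 1L)
  strip <- findInterval(occ$lon, edges[-1L]) + 1L
  strip[strip > n_strips] <- n_strips
  lev <- (seq_len(n_strips) - 1) / max(1L, n_strips - 1L) * max_intensity
  out <- lapply(seq_len(n_strips), function(s) {
    part <- occ[strip == s, , drop = FALSE]
    if (!nrow(part)) return(part)
    disturb(part, deletion_fraction, swap_fraction, lev[s],
            extent = c(edges[s], edges[s + 1L], extent[3], extent[4]),
            seed = child_seed(seed, s))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic ecoregions and intact-forest mask
#'
#' Tiles the extent into a rectangular grid of "ecoregions" (the divisor
#' pair of `n_regions` whose shape best matches the extent's aspect ratio)
#' and marks a random fraction of them intact, exporting the intact subset
#' separately as an intact-forest-landscape stand-in.
#'
#' @inheritParams generate_landscape
#' @param n_regions number of regions (>= 1).
#' @param intact_fraction fraction of regions marked intact.
#' @return List with `ecoregions` (polygon features with properties
#'   `region_id`, `intact`) and `intact` (the intact subset).
#' @export
generate_regions <- function(extent, n_regions, intact_fraction = 0, seed = 1L) {
  stopifnot(n_regions >= 1L)
  div <- which(n_regions %% seq_len(n_regions) == 0L)
  aspect <- (extent[2] - extent[1]) / (extent[4] - extent[3])
  nx <- div[which.min(abs(log((div^2 / n_regions)) - log(aspect)))]
  ny <- n_regions %/% nx
  ex <- seq(extent[1], extent[2], length.out = nx + 1L)
  ey <- seq(extent[3], extent[4], length.out = ny + 1L)
  grid <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  intact <- with_seed(seed, {
    flag <- rep(FALSE, n_regions)
    n_int <- round(intact_fraction * n_regions)
    if (n_int > 0L) flag[sample.int(n_regions, n_int)] <- TRUE
    flag
  })
  regions <- lapply(seq_len(n_regions), function(r)
    rect_feature(ex[grid$ix[r]], ex[grid$ix[r] + 1L],
                 ey[grid$iy[r]], ey[grid$iy[r] + 1L],
                 properties = list(region_id = sprintf("eco%02d", r),
                                   intact = intact[r])))
  list(ecoregions = regions, intact = regions[intact])
}
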