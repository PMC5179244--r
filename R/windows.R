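#' Occurrence tables: delimited-text interchange
#'
#' Point occurrence records are plain data frames with columns
#' `species_id`, `lon`, `lat` and optionally `source`. On disk they are
#' comma-separated with that header; lines starting with `#` are metadata
#' (seeds, conventions) and are ignored on read.
#'
#' @param path file path.
#' @return Data frame with validated columns.
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("species_id", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence file must have columns species_id, lon, lat", call. = FALSE)
  bad <- which(!is.finite(df$lon) | !is.finite(df$lat) |
                 df$lon < -180 | df$lon > 180 | df$lat < -90 | df$lat > 90 |
                 is.na(df$species_id) | df$species_id == "")
  if (length(bad))
    stop(sprintf("malformed occurrence rows (first at data row %d)", bad[1L]),
         call. = FALSE)
  df
}

#' @rdname read_occurrences
#' @param occ occurrence data frame.
#' @param meta named character/numeric vector written as `# key: value`
#'   header lines (seeds, generator settings).
#' @export
write_occurrences <- function(occ, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(occ, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter occurrences through a categorical habitat mask
#'
#' Retains only records falling inside a mask polygon whose `class`
#' property is among `allowed_classes` — e.g. keeping plots in forest
#' land-cover classes. Points on a shared boundary belong to the first
#' feature in file order; records outside every mask polygon are dropped.
#'
#' @param occ occurrence data frame (`species_id`, `lon`, `lat`, ...).
#' @param mask polygon feature list; each feature must carry a `class`
#'   property.
#' @param allowed_classes character vector of class labels to retain.
#' @return The retained rows of `occ`, with attribute `n_dropped`.
#' @export
mask_filter <- function(occ, mask, allowed_classes) {
  if (length(mask) == 0L)
    stop("mask contains no polygons", call. = FALSE)
  cls <- vapply(mask, function(f) as.character(f$properties$class %||% NA),
                character(1))
  if (anyNA(cls)) stop("every mask polygon needs a 'class' property", call. = FALSE)
  idx <- locate_points(occ$lon, occ$lat, mask)
  keep <- !is.na(idx) & cls[ifelse(is.na(idx), 1L, idx)] %in% allowed_classes
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Project plot locations onto a potential-vegetation polygon map
#'
#' For each plot location, looks up the containing vegetation-unit polygon
#' and emits one occurrence record per species in that polygon's `species`
#' list — turning an expert map of vegetation units into a potential
#' occurrence dataset comparable with the observed one. Locations outside
#' every polygon, and polygons with empty species lists (warned), emit
#' nothing; overlapping polygons resolve to the first in file order.
#'
#' @param locations data frame with columns `lon`, `lat` (duplicates
#'   allowed; typically the plot locations of the observed dataset).
#' @param pnv polygon feature list, each feature with a `species` property
#'   (character vector).
#' @return Occurrence data frame (`species_id`, `lon`, `lat`,
#'   `source = "pnv"`).
#' @export
pnv_project <- function(locations, pnv) {
  if (length(pnv) == 0L) stop("PNV map contains no polygons", call. = FALSE)
  pools <- lapply(pnv, function(f) as.character(f$properties$species))
  if (any(vapply(pools, length, integer(1)) == 0L))
    warning("PNV polygon(s) with empty species list emit no records")
  idx <- locate_points(locations$lon, locations$lat, pnv)
  keep <- which(!is.na(idx))
  if (!length(keep))
    return(data.frame(species_id = character(0), lon = numeric(0),
                      lat = numeric(0), source = character(0)))
  reps <- vapply(idx[keep], function(i) length(pools[[i]]), integer(1))
  sp <- unlist(pools[idx[keep]], use.names = FALSE)
  data.frame(
    species_id = as.character(sp %||% character(0)),
    lon = rep(locations$lon[keep], reps),
    lat = rep(locations$lat[keep], reps),
    source = rep("pnv", sum(reps))
  )
}

#' Build the presence-absence matrix of one window
#'
#' Bins the records falling in a 1-degree window into its 10 x 10 grid of
#' 0.1-degree cells (half-open intervals `[a, a + 0.1)` on both axes, so a
#' record exactly on a cell's upper edge belongs to the next cell), builds
#' the binary species x cell matrix, prunes empty rows and columns, and
#' applies the retention rule: at least `min_rows` species and `min_cols`
#' occupied cells.
#'
#' @param occ occurrence data frame.
#' @param anchor_lon,anchor_lat window lower-left corner, decimal degrees;
#'   must sit on the 0.1-degree lattice.
#' @param window_size,cell_size window and cell edge in degrees; the ratio
#'   must be a whole number of cells (default 10).
#' @param min_rows,min_cols retention thresholds (default 5 x 5).
#' @return List with `retained` (logical), `matrix` (binary species x site
#'   matrix when retained, else `NULL`), `reason` (rejection reason or
#'   `NA`), and the window `centroid_lon`, `centroid_lat`.
#' @export
build_window_matrix <- function(occ, anchor_lon, anchor_lat,
                                window_size = 1, cell_size = 0.1,
                                min_rows = 5L, min_cols = 5L) {
  ncell <- window_size / cell_size
  if (abs(ncell - round(ncell)) > 1e-9)
    stop("window_size must be a whole multiple of cell_size", call. = FALSE)
  ncell <- as.integer(round(ncell))
  ax <- to_tenths(anchor_lon); ay <- to_tenths(anchor_lat)
  ix <- to_tenths(occ$lon) - ax
  iy <- to_tenths(occ$lat) - ay
  inw <- ix >= 0L & ix < ncell & iy >= 0L & iy < ncell
  centroid <- c(anchor_lon + window_size / 2, anchor_lat + window_size / 2)
  rej <- function(reason) list(retained = FALSE, matrix = NULL, reason = reason,
                               centroid_lon = centroid[1], centroid_lat = centroid[2])
  if (!any(inw)) return(rej("empty window"))
  sp <- as.character(occ$species_id[inw])
  cell <- sprintf("c%02d_%02d", ix[inw], iy[inw])
  keyed <- !duplicated(paste(sp, cell))          # presence-absence: dedup
  m <- table(species = sp[keyed], site = cell[keyed])
  m <- prune_matrix(unclass(m))                  # already non-empty by construction
  if (nrow(m) < min_rows) return(rej(sprintf("rows < %d", min_rows)))
  if (ncol(m) < min_cols) return(rej(sprintf("cols < %d", min_cols)))
  list(retained = TRUE, matrix = m, reason = NA_character_,
       centroid_lon = centroid[1], centroid_lat = centroid[2])
}

#' Sweep a moving window across a landscape
#'
#' Enumerates every anchor position of a `window_size` window on a
#' 0.1-degree lattice (row-major, south-west to north-east), builds the
#' presence-absence matrix at each position ([build_window_matrix]), and
#' for every retained matrix computes [nos_structure], georeferenced at the
#' window centroid. Windows are independent, so the result is invariant to
#' record order and to evaluation order.
#'
#' @inheritParams build_window_matrix
#' @param occ occurrence data frame.
#' @param origin lower-left lattice origin `c(lon, lat)`; default snaps the
#'   data bounding box's south-west corner down to the 0.1-degree lattice.
#' @param extent upper-right limit `c(lon, lat)`; default snaps the data
#'   bounding box's north-east corner up.
#' @param axis_mode passed to [nos_structure].
#' @param dataset_tag label stored in the `dataset` column (e.g. `"ACV"`,
#'   `"PNV"`).
#' @return Data frame with one row per retained window: `dataset`,
#'   `centroid_lon`, `centroid_lat`, `n_species`, `n_sites`, `nbar`, `z`,
#'   `modularity`. Attributes `n_anchors` and `rejections` (table of
#'   rejection reasons) summarize the sweep; an empty sweep warns.
#' @export
nos_sweep <- function(occ, origin = NULL, extent = NULL,
                      window_size = 1, cell_size = 0.1,
                      min_rows = 5L, min_cols = 5L,
                      axis_mode = "both", dataset_tag = "ACV") {
  if (is.null(origin))
    origin <- c(floor(min(occ$lon) * 10) / 10, floor(min(occ$lat) * 10) / 10)
  if (is.null(extent))
    extent <- c(ceiling(max(occ$lon) * 10) / 10, ceiling(max(occ$lat) * 10) / 10)
  ox <- to_tenths(origin[1]); oy <- to_tenths(origin[2])
  w <- as.integer(round(window_size / cell_size))
  nx <- (to_tenths(extent[1]) - ox) - w   # last anchor offset, in tenths
  ny <- (to_tenths(extent[2]) - oy) - w
  if (nx < 0L || ny < 0L)
    stop("extent smaller than one window", call. = FALSE)
  # Presence is per (species, 0.1-degree cell): deduplicate once globally.
  # Anchors sit on the same lattice as the cells, so every window's matrix
  # is a contiguous block of this presence table — identical to calling
  # build_window_matrix() per anchor, but without rescanning the records.
  cx <- to_tenths(occ$lon); cy <- to_tenths(occ$lat)
  sp <- as.character(occ$species_id)
  keep <- !duplicated(paste(sp, cx, cy))
  pres <- data.frame(sp = sp[keep], cx = cx[keep], cy = cy[keep])
  rows <- vector("list", (nx + 1L) * (ny + 1L))
  reasons <- character(0)
  k <- 0L
  for (jy in 0:ny) for (jx in 0:nx) {
    k <- k + 1L
    ax <- ox + jx; ay <- oy + jy
    sel <- pres$cx >= ax & pres$cx < ax + w & pres$cy >= ay & pres$cy < ay + w
    if (!any(sel)) { reasons <- c(reasons, "empty window"); next }
    p <- pres[sel, , drop = FALSE]
    m <- unclass(table(p$sp, paste(p$cx, p$cy)))
    if (nrow(m) < min_rows) { reasons <- c(reasons, sprintf("rows < %d", min_rows)); next }
    if (ncol(m) < min_cols) { reasons <- c(reasons, sprintf("cols < %d", min_cols)); next }
    st <- nos_structure(m, axis_mode)
    rows[[k]] <- data.frame(
      dataset = dataset_tag,
      centroid_lon = (ax + w / 2) / 10, centroid_lat = (ay + w / 2) / 10,
      n_species = nrow(m), n_sites = ncol(m),
      nbar = st$nbar, z = st$z, modularity = st$modularity
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) {
    warning("no window retained over the sweep extent")
    out <- data.frame(dataset = character(0), centroid_lon = numeric(0),
                      centroid_lat = numeric(0), n_species = integer(0),
                      n_sites = integer(0), nbar = numeric(0), z = numeric(0),
                      modularity = numeric(0))
  }
  rownames(out) <- NULL
  attr(out, "n_anchors") <- as.integer((nx + 1) * (ny + 1))
  attr(out, "rejections") <- table(reasons)
  out
}

#' Write window results with a metadata header
#'
#' @param results data frame from [nos_sweep].
#' @param path file path.
#' @param meta named vector written as `# key: value` lines.
#' @export
write_window_results <- function(results, path, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta))
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  utils::write.csv(results, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_window_results
#' @export
read_window_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export window results as GeoJSON points
#'
#' @param results data frame from [nos_sweep].
#' @param path file path.
#' @export
window_results_to_geojson <- function(results, path) {
  feats <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    list(type = "Point", coords = c(r$centroid_lon, r$centroid_lat),
         properties = as.list(r[setdiff(names(r), c("centroid_lon", "centroid_lat"))]))
  })
  write_geojson(feats, path)
}
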