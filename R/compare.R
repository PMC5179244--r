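centroid_key <- function(lon, lat) {
  paste(round(lon * 10), round(lat * 10), sep = "_")  # 0.1-degree lattice key
}

#' Per-centroid difference between two window-result sets
#'
#' Joins actual-vegetation and potential-vegetation window results on their
#' centroid coordinates (exact match on the 0.1-degree lattice) and emits
#' the ACV - PNV difference of `nbar`, `z` and `modularity` at every
#' centroid. Centroids retained on only one side are kept with a
#' `missing_side` flag and `NA` differences rather than silently dropped.
#'
#' @param acv,pnv window-result data frames from [nos_sweep] over the same
#'   lattice.
#' @return Data frame with `centroid_lon`, `centroid_lat`, `d_nbar`, `d_z`,
#'   `d_modularity`, `missing_side` (`""`, `"acv_only"`, `"pnv_only"`).
#' @export
difference_map <- function(acv, pnv) {
  ka <- centroid_key(acv$centroid_lon, acv$centroid_lat)
  kp <- centroid_key(pnv$centroid_lon, pnv$centroid_lat)
  if (nrow(acv) && nrow(pnv) && !length(intersect(ka, kp)))
    stop("window lattices of the two result sets are disjoint", call. = FALSE)
  keys <- union(ka, kp)
  ia <- match(keys, ka); ip <- match(keys, kp)
  lon <- ifelse(is.na(ia), pnv$centroid_lon[ip], acv$centroid_lon[ia])
  lat <- ifelse(is.na(ia), pnv$centroid_lat[ip], acv$centroid_lat[ia])
  out <- data.frame(
    centroid_lon = lon, centroid_lat = lat,
    d_nbar = acv$nbar[ia] - pnv$nbar[ip],
    d_z = acv$z[ia] - pnv$z[ip],
    d_modularity = acv$modularity[ia] - pnv$modularity[ip],
    missing_side = ifelse(is.na(ia), "pnv_only", ifelse(is.na(ip), "acv_only", ""))
  )
  out <- out[order(out$centroid_lat, out$centroid_lon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Average window statistics per ecoregion
#'
#' Each window contributes to the ecoregion containing its centroid
#' (first-matching polygon in file order); per region and dataset tag the
#' unweighted arithmetic means of `nbar`, `z` and `modularity` are
#' reported. Windows whose centroid falls in no region are counted and
#' excluded; regions without windows are omitted with a warning. `NA`
#' Z values (zero-variance windows) are dropped from the Z mean.
#'
#' @param results window-result data frame from [nos_sweep].
#' @param ecoregions polygon feature list with a `region_id` property.
#' @return Data frame `region_id`, `dataset`, `n_windows`, `mean_nbar`,
#'   `mean_z`, `mean_modularity`; attribute `n_unassigned`.
#' @export
ecoregion_aggregate <- function(results, ecoregions) {
  ids <- vapply(ecoregions, function(f) as.character(f$properties$region_id),
                character(1))
  at <- locate_points(results$centroid_lon, results$centroid_lat, ecoregions)
  n_un <- sum(is.na(at))
  if (n_un) message(n_un, " window centroid(s) outside every ecoregion; excluded")
  keep <- !is.na(at)
  res <- results[keep, , drop = FALSE]
  grp <- interaction(ids[at[keep]], res$dataset, drop = TRUE, sep = "\r")
  agg <- function(v, f = mean) as.numeric(tapply(v, grp, f, na.rm = TRUE))
  parts <- strsplit(levels(grp), "\r", fixed = TRUE)
  out <- data.frame(
    region_id = vapply(parts, `[`, character(1), 1L),
    dataset = vapply(parts, `[`, character(1), 2L),
    n_windows = as.integer(tapply(seq_len(nrow(res)), grp, length)),
    mean_nbar = agg(res$nbar), mean_z = agg(res$z),
    mean_modularity = agg(res$modularity)
  )
  missing_regions <- setdiff(ids, out$region_id)
  if (length(missing_regions))
    warning("ecoregion(s) with no windows omitted: ",
            paste(missing_regions, collapse = ", "))
  out <- out[order(out$region_id, out$dataset), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unassigned") <- n_un
  out
}

#' Welch contrast of intact versus non-intact windows
#'
#' Classifies windows by whether their centroid lies in an intact-forest
#' polygon and contrasts the two groups with Welch's unequal-variance
#' t-test (Welch-Satterthwaite degrees of freedom, two-sided p), once for
#' `nbar` (nestedness) and once for modularity. The test statistic is
#' non-intact minus intact, so higher nestedness inside intact areas gives
#' a negative t for `nbar`, and lower modularity inside gives a positive t
#' for modularity.
#'
#' @param results window-result data frame from [nos_sweep].
#' @param intact polygon feature list of intact areas.
#' @return Data frame with one row per statistic: `statistic`, `t`, `df`,
#'   `p`, `n_nonintact`, `n_intact`, `mean_nonintact`, `mean_intact`.
#' @export
intact_contrast <- function(results, intact) {
  inside <- !is.na(locate_points(results$centroid_lon, results$centroid_lat,
                                 intact))
  if (sum(inside) < 2L || sum(!inside) < 2L)
    stop("each group needs at least 2 windows", call. = FALSE)
  one <- function(stat) {
    x <- results[[stat]][!inside]; y <- results[[stat]][inside]
    tt <- tryCatch(stats::t.test(x, y, var.equal = FALSE),
                   error = function(e) NULL)   # constant data
    data.frame(
      statistic = stat,
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      df = if (is.null(tt)) NA_real_ else unname(tt$parameter),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      n_nonintact = length(x), n_intact = length(y),
      mean_nonintact = mean(x), mean_intact = mean(y)
    )
  }
  out <- rbind(one("nbar"), one("modularity"))
  rownames(out) <- NULL
  out
}

#' Record-subsampling sensitivity analysis
#'
#' Reruns the moving-window sweep after removing a random fraction
#' (default half) of the occurrence records, pairs the windows retained in
#' both runs, and regresses the subsample statistic on the full-data
#' statistic (ordinary least squares) for `nbar` and modularity. A robust
#' statistic shows slope near 1, intercept near 0 and high R-squared.
#'
#' @param occ occurrence data frame.
#' @param subsample_fraction fraction of records removed (default 0.5).
#' @param seed integer seed for the subsample (mandatory, recorded in the
#'   report).
#' @param ... passed to [nos_sweep] (window geometry, retention rule...).
#' @return List of class `"sensitivity_report"`: per statistic `slope`,
#'   `intercept`, `r2` (NA with `degenerate = TRUE` when the full-data
#'   values have zero variance), plus `n_windows_paired`, `low_power`
#'   (fewer than 10 paired windows), `subsample_fraction`, `seed`.
#' @export
sensitivity_run <- function(occ, subsample_fraction = 0.5, seed, ...) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  origin <- c(floor(min(occ$lon) * 10) / 10, floor(min(occ$lat) * 10) / 10)
  extent <- c(ceiling(max(occ$lon) * 10) / 10, ceiling(max(occ$lat) * 10) / 10)
  full <- nos_sweep(occ, origin = origin, extent = extent, ...)
  sub_occ <- disturb(occ, deletion_fraction = subsample_fraction,
                     swap_fraction = 0, intensity = 1, seed = seed)
  sub <- nos_sweep(sub_occ, origin = origin, extent = extent, ...)
  kf <- centroid_key(full$centroid_lon, full$centroid_lat)
  ks <- centroid_key(sub$centroid_lon, sub$centroid_lat)
  common <- intersect(kf, ks)
  fi <- match(common, kf); si <- match(common, ks)
  fit_one <- function(stat) {
    x <- full[[stat]][fi]; y <- sub[[stat]][si]
    ok <- is.finite(x) & is.finite(y)   # windows with no scorable pairs are NA
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2L || stats::var(x) == 0)
      return(list(slope = NA_real_, intercept = NA_real_, r2 = NA_real_,
                  degenerate = TRUE))
    fit <- stats::lm(y ~ x)
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r2 = suppressWarnings(summary(fit)$r.squared),  # perfect fits warn
         degenerate = FALSE)
  }
  out <- list(nbar = fit_one("nbar"), modularity = fit_one("modularity"),
              n_windows_paired = length(common),
              low_power = length(common) < 10L,
              subsample_fraction = subsample_fraction, seed = seed)
  class(out) <- "sensitivity_report"
  out
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity analysis: %.0f%% record removal, %d paired windows%s\n",
              100 * x$subsample_fraction, x$n_windows_paired,
              if (x$low_power) " [low power]" else ""))
  for (s in c("nbar", "modularity")) {
    f <- x[[s]]
    if (isTRUE(f$degenerate))
      cat(sprintf("  %-10s regression degenerate (zero variance)\n", s))
    else
      cat(sprintf("  %-10s y = %.3fx + %.3f   R2 = %.3f\n",
                  s, f$slope, f$intercept, f$r2))
  }
  invisible(x)
}

#' Descriptive-statistics summary of window results
#'
#' Min, first quartile, median, mean, third quartile and max of each
#' structure statistic, per dataset tag — the layout of a classic
#' descriptive summary table. Quantiles use linear interpolation
#' (`type = 7`); `NA` Z values are dropped.
#'
#' @param results window-result data frame from [nos_sweep] (one or more
#'   dataset tags row-bound together).
#' @param statistics columns to summarize.
#' @return Data frame: first column `summary` (Min...Max), then one column
#'   per statistic-dataset combination, named `<statistic>_<dataset>`.
#' @export
summary_table <- function(results, statistics = c("nbar", "z", "modularity")) {
  stopifnot(nrow(results) > 0L)
  labels <- c("Min", "1st Qu", "Median", "Mean", "3rd Qu", "Max")
  six <- function(v) {
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0, .25, .5, .75, 1), type = 7, names = FALSE)
    c(q[1:3], mean(v), q[4:5])
  }
  out <- data.frame(summary = labels)
  for (stat in statistics)
    for (tag in unique(results$dataset))
      out[[paste(stat, tag, sep = "_")]] <-
        six(results[[stat]][results$dataset == tag])
  out
}
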