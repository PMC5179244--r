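#' nosweep: spatial structure of species assemblages via node overlap scores
#'
#' Core statistic: the standardized deviation of the shared-neighbour count
#' of two nodes of a bipartite incidence (two species sharing sites, or two
#' sites sharing species) from its expectation under random placement of
#' their degrees. Scores span \[-1, 1\]: +1 is perfect nestedness (one
#' neighbourhood contained in the other), -1 complete segregation
#' (checkerboard). The matrix-level mean is written `nbar`, the population
#' standard deviation of the scores is the matrix's modularity, and a
#' one-sample Z test flags departure of `nbar` from 0.
#'
#' @keywords internal
"_PACKAGE"

# Feasible range of the shared count S given degrees d_i, d_j among n sites.
# The range collapses to a single point iff max(d_i, d_j) == n, in which
# case S is forced and the pair carries no information (degenerate).
shared_bounds <- function(n, d_i, d_j) {
  list(lo = pmax(0, d_i + d_j - n), hi = pmin(d_i, d_j))
}

check_degrees <- function(n, d_i, d_j) {
  if (any(n < 1) || any(d_i < 1) || any(d_j < 1))
    stop("n, d_i and d_j must be positive", call. = FALSE)
  if (any(d_i > n) || any(d_j > n))
    stop("degrees cannot exceed n", call. = FALSE)
}

#' Expected number of shared neighbours under random placement
#'
#' Computes the expectation of the shared-neighbour count `S` of two nodes
#' with degrees `d_i` and `d_j` whose neighbourhoods are placed uniformly at
#' random among `n` available nodes of the opposite class. `S` then follows
#' a hypergeometric law, and the expectation is the probability-weighted sum
#' over all feasible overlaps, evaluated here with log-gamma binomial
#' coefficients so that `n` of a few hundred does not overflow. The sum has
#' the closed form `d_i * d_j / n`, available as `method = "closed"`; both
#' routes agree to near machine precision and the closed form is used
#' internally when scoring whole matrices.
#'
#' @param n number of available neighbours (sites when comparing species,
#'   species when comparing sites).
#' @param d_i,d_j node degrees, in `1..n`.
#' @param method `"sum"` (default) evaluates the full probabilistic sum;
#'   `"closed"` the algebraic closed form.
#' @return Expected shared count, a value in
#'   `[max(0, d_i + d_j - n), min(d_i, d_j)]`.
#' @examples
#' nos_expected_shared(5, 1, 1)    # 0.2
#' nos_expected_shared(10, 4, 5)   # 2
#' @export
nos_expected_shared <- function(n, d_i, d_j, method = c("sum", "closed")) {
  method <- match.arg(method)
  check_degrees(n, d_i, d_j)
  if (method == "closed") return(d_i * d_j / n)
  stopifnot(length(n) == 1L, length(d_i) == 1L, length(d_j) == 1L)
  k <- seq_len(min(d_i, d_j))
  logp <- lchoose(n, k) + lchoose(n - k, d_j - k) + lchoose(n - d_j, d_i - k) -
    lchoose(n, d_j) - lchoose(n, d_i)
  # infeasible k have lchoose = -Inf and contribute 0
  sum(exp(logp) * k)
}

#' Standardization magnitude for a node pair
#'
#' The score of a pair divides the deviation `(S - P) / min(d_i, d_j)` by
#' the largest magnitude that deviation can take in the observed direction,
#' so that maximal sharing maps to +1 and minimal sharing to -1. For
#' positive deviations the bound is `(min(d_i, d_j) - P) / min(d_i, d_j)`;
#' for negative ones `(P - max(0, d_i + d_j - n)) / min(d_i, d_j)`.
#'
#' Pairs in which `S` is forced (which happens exactly when
#' `max(d_i, d_j) == n`) admit no deviation; they return `NA` and are
#' excluded from matrix-level averaging.
#'
#' @inheritParams nos_expected_shared
#' @param sign `"positive"` or `"negative"`: direction of the deviation to
#'   be standardized.
#' @return Positive standardization magnitude, or `NA_real_` for a
#'   degenerate pair.
#' @export
nos_omega <- function(n, d_i, d_j, sign = c("positive", "negative")) {
  sign <- match.arg(sign)
  check_degrees(n, d_i, d_j)
  if (max(d_i, d_j) == n) return(NA_real_)
  p <- d_i * d_j / n
  b <- shared_bounds(n, d_i, d_j)
  dmin <- min(d_i, d_j)
  if (sign == "positive") (b$hi - p) / dmin else (p - b$lo) / dmin
}

#' Node overlap-segregation score of one pair
#'
#' Standardized deviation of the observed shared-neighbour count from its
#' random expectation: `(S - P) / min(d_i, d_j)` divided by the
#' direction-matched standardization magnitude ([nos_omega]). The score is
#' +1 when sharing is maximal (`S = min(d_i, d_j)`), -1 when minimal
#' (`S = max(0, d_i + d_j - n)`), 0 when `S` equals its expectation, and is
#' symmetric in `i` and `j`. Degenerate pairs score `NA`.
#'
#' @param S observed shared-neighbour count; must lie in its feasible range.
#' @inheritParams nos_expected_shared
#' @return Score in `[-1, 1]`, or `NA_real_` for a degenerate pair.
#'   Vectorized over all arguments.
#' @examples
#' nos_pair_score(1, 5, 1, 1)   # +1: perfect nestedness
#' nos_pair_score(0, 5, 1, 1)   # -1: complete segregation
#' @export
nos_pair_score <- function(S, n, d_i, d_j) {
  check_degrees(n, d_i, d_j)
  b <- shared_bounds(n, d_i, d_j)
  if (any(S < b$lo) || any(S > b$hi))
    stop("S outside its feasible range given n and the degrees", call. = FALSE)
  p <- d_i * d_j / n
  # (S-P)/min(d) / omega with min(d) cancelled: exact +/-1 at the bounds
  out <- ifelse(S > p, (S - p) / (b$hi - p),
         ifelse(S < p, (S - p) / (p - b$lo), 0))
  out[pmax(d_i, d_j) == n] <- NA_real_
  out
}

# All pair scores along one axis of a binary matrix (rows: species pairs).
# Returns the vector of scores for the upper triangle, NA for degenerate
# pairs.
axis_pair_scores <- function(m) {
  nr <- nrow(m)
  if (nr < 2L) return(numeric(0))
  n <- ncol(m)
  s <- tcrossprod(m)
  d <- rowSums(m)
  iu <- which(upper.tri(s), arr.ind = TRUE)
  nos_pair_score(s[iu], n, d[iu[, 1L]], d[iu[, 2L]])
}

#' Z test of the mean pair score
#'
#' One-sample Z of the mean score against 0, using the population standard
#' deviation of the scores: `Z = mean / (sd / sqrt(n_pairs))`. Values above
#' 2 indicate significant nestedness at about p < 0.05, values below -2
#' significant segregation. With zero variance the test is not computable
#' and `NA` is returned.
#'
#' @param scores numeric vector of pair scores; `NA` entries (degenerate
#'   pairs) are dropped.
#' @return The Z statistic, or `NA_real_` when the score variance is zero.
#' @export
nos_z <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (length(scores) < 2L)
    stop("at least two scorable pairs are needed for the Z test", call. = FALSE)
  s <- stats::sd(scores) * sqrt((length(scores) - 1) / length(scores))
  if (s == 0) return(NA_real_)
  mean(scores) / (s / sqrt(length(scores)))
}

#' Matrix-level structure: nbar, modularity and Z
#'
#' Scores every pair of rows and/or columns of a binary presence-absence
#' matrix with [nos_pair_score] and summarizes them: `nbar` is the mean
#' score (nestedness when positive, segregation when negative), modularity
#' is the population standard deviation of the scores (high when the matrix
#' splits into internally similar, mutually dissimilar blocks), and `z` is
#' the [nos_z] test of `nbar` against 0. By default row pairs (species
#' overlap) and column pairs (site overlap) are pooled; either axis can be
#' scored alone. Degenerate pairs are excluded throughout.
#'
#' @param m binary matrix, rows = species, columns = sites. Must already be
#'   pruned of empty rows and columns (see [prune_matrix]).
#' @param axis_mode `"both"` (default), `"rows"`, or `"columns"`.
#' @return A list of class `"nos_structure"` with elements `nbar`,
#'   `modularity`, `z`, `n_pairs` (scorable pairs), `axis_mode`, and
#'   `computable` (`FALSE` when fewer than 2 pairs could be scored, in which
#'   case the statistics are `NA`).
#' @examples
#' chain <- outer(1:5, 1:5, ">=") * 1L   # strict subset chain
#' nos_structure(chain)$nbar             # exactly 1
#' nos_structure(diag(5))$nbar           # exactly -1
#' @export
nos_structure <- function(m, axis_mode = c("both", "rows", "columns")) {
  axis_mode <- match.arg(axis_mode)
  m <- as.matrix(m)
  if (!all(m %in% c(0, 1)))
    stop("matrix entries must be 0/1", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("matrix has empty rows or columns; prune_matrix() first", call. = FALSE)
  storage.mode(m) <- "double"
  scores <- c(
    if (axis_mode != "columns") axis_pair_scores(m),
    if (axis_mode != "rows") axis_pair_scores(t(m))
  )
  scores <- scores[!is.na(scores)]
  n_pairs <- length(scores)
  if (n_pairs < 2L) {
    res <- list(nbar = NA_real_, modularity = NA_real_, z = NA_real_,
                n_pairs = n_pairs, axis_mode = axis_mode, computable = FALSE)
  } else {
    sd_pop <- stats::sd(scores) * sqrt((n_pairs - 1) / n_pairs)
    res <- list(
      nbar = mean(scores),
      modularity = sd_pop,
      z = if (sd_pop == 0) NA_real_ else nos_z(scores),
      n_pairs = n_pairs, axis_mode = axis_mode, computable = TRUE
    )
  }
  class(res) <- "nos_structure"
  res
}

#' @export
print.nos_structure <- function(x, ...) {
  if (!x$computable) {
    cat("Node overlap-segregation structure: not computable",
        sprintf("(%d scorable pairs)\n", x$n_pairs))
    return(invisible(x))
  }
  cat(sprintf(
    "Node overlap-segregation structure (%s, %d pairs)\n  nbar = %.4f  modularity = %.4f  Z = %s\n",
    x$axis_mode, x$n_pairs, x$nbar, x$modularity,
    if (is.na(x$z)) "NA (zero variance)" else sprintf("%.3f", x$z)))
  invisible(x)
}

#' Monte-Carlo estimate of the expected shared-neighbour count
#'
#' Brute-force validation oracle for [nos_expected_shared]: places two
#' neighbourhoods of sizes `d_i` and `d_j` uniformly at random among `n`
#' nodes, `n_draws` independent times, and averages the observed overlap.
#'
#' @inheritParams nos_expected_shared
#' @param n_draws number of random placements.
#' @param seed integer seed; the global RNG state is left untouched.
#' @return List with `estimate`, its Monte-Carlo standard error `se`, and
#'   `n_draws`.
#' @export
nos_mc_expected_shared <- function(n, d_i, d_j, n_draws = 1e5, seed = 1L) {
  check_degrees(n, d_i, d_j)
  stopifnot(n_draws >= 1)
  with_seed(seed, {
    shared <- vapply(seq_len(n_draws), function(i) {
      length(intersect(sample.int(n, d_i), sample.int(n, d_j)))
    }, numeric(1))
    list(estimate = mean(shared),
         se = stats::sd(shared) / sqrt(n_draws),
         n_draws = n_draws)
  })
}

#' Drop empty rows and columns from a presence-absence matrix
#'
#' @param m binary matrix.
#' @return The submatrix of non-empty rows and columns (possibly 0-extent).
#' @export
prune_matrix <- function(m) {
  m <- as.matrix(m)
  m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
}

#' Read / write a presence-absence matrix as delimited text
#'
#' Plain-text interchange: comma-separated, first column = species
#' identifiers, header = site identifiers, cells strictly 0/1.
#'
#' @param path file path.
#' @param m binary matrix with row and column names.
#' @return `read_pam` returns a binary integer matrix with dimnames.
#' @export
read_pam <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L))) stop("matrix cells must be 0/1", call. = FALSE)
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
    stop("row and column labels must be unique", call. = FALSE)
  m
}

#' @rdname read_pam
#' @export
write_pam <- function(m, path) {
  df <- data.frame(species = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
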