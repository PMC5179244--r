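# Independent brute-force oracles, kept deliberately naive: direct
# binomial-coefficient evaluation, no log-gamma, no vectorization, and a
# from-scratch score formula. These never call the package's own routines.

oracle_expected <- function(n, d_i, d_j) {
  total <- 0
  for (k in seq_len(min(d_i, d_j))) {
    pr <- choose(n, k) * choose(n - k, d_j - k) * choose(n - d_j, d_i - k) /
      (choose(n, d_j) * choose(n, d_i))
    total <- total + pr * k
  }
  total
}

oracle_score <- function(S, n, d_i, d_j) {
  if (d_i == n || d_j == n) return(NA_real_)  # S is forced
  p <- oracle_expected(n, d_i, d_j)
  lo <- max(0, d_i + d_j - n)
  hi <- min(d_i, d_j)
  dev <- (S - p) / min(d_i, d_j)
  if (dev > 0) dev / ((hi - p) / min(d_i, d_j))
  else if (dev < 0) dev / ((p - lo) / min(d_i, d_j))
  else 0
}

# Mean / population-SD of all pooled pair scores of a pruned binary matrix,
# by direct enumeration of every row pair and column pair.
oracle_structure <- function(m) {
  scores <- c()
  for (ax in 1:2) {
    if (ax == 2) m <- t(m)
    n <- ncol(m)
    d <- rowSums(m)
    if (nrow(m) >= 2) for (i in 1:(nrow(m) - 1)) for (j in (i + 1):nrow(m)) {
      s <- sum(m[i, ] * m[j, ])
      scores <- c(scores, oracle_score(s, n, d[i], d[j]))
    }
  }
  scores <- scores[!is.na(scores)]
  list(nbar = mean(scores),
       modularity = sqrt(mean((scores - mean(scores))^2)),
       n_pairs = length(scores))
}

# Random pruned binary matrix with at least 2 rows and 2 columns.
random_pam <- function(nr, nc, p = 0.4) {
  repeat {
    m <- matrix(rbinom(nr * nc, 1, p), nr, nc)
    m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
    if (nrow(m) >= 2 && ncol(m) >= 2) return(m)
  }
}

# Small fixtures reused across files
chain5 <- outer(1:5, 1:5, ">=") * 1L    # species i occupies sites 1..i
blocks2 <- rbind(cbind(matrix(1, 3, 5), matrix(0, 3, 5)),
                 cbind(matrix(0, 3, 5), matrix(1, 3, 5)))
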