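# Independent brute-force oracles: every H coefficient recomputed by direct
# Guttman-error counting over explicit loops, never touching the package's
# covariance-form implementation.

oracle_pair_FE <- function(X, i, j) {
  n <- nrow(X)
  p <- colMeans(X)
  # harder item: lower popularity, ties to lower column index
  if (p[j] < p[i]) { h <- j; e <- i } else { h <- i; e <- j }
  F_ <- 0L
  for (r in seq_len(n)) if (X[r, h] == 1 && X[r, e] == 0) F_ <- F_ + 1L
  c(F = F_, E = n * p[h] * (1 - p[e]))
}

oracle_pair_H <- function(X, i, j) {
  fe <- oracle_pair_FE(X, i, j)
  1 - fe["F"] / fe["E"]
}

oracle_item_H <- function(X, i) {
  sf <- se_ <- 0
  for (j in seq_len(ncol(X))) {
    if (j == i) next
    fe <- oracle_pair_FE(X, i, j)
    sf <- sf + fe["F"]; se_ <- se_ + fe["E"]
  }
  unname(1 - sf / se_)
}

oracle_scale_H <- function(X) {
  sf <- se_ <- 0
  k <- ncol(X)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    fe <- oracle_pair_FE(X, i, j)
    sf <- sf + fe["F"]; se_ <- se_ + fe["E"]
  }
  unname(1 - sf / se_)
}

oracle_transposed_H <- function(X) {
  Xt <- t(X)
  keep <- colMeans(Xt) > 0 & colMeans(Xt) < 1
  oracle_scale_H(Xt[, keep, drop = FALSE])
}

# random valid response matrix: every column non-constant
rand_binary_matrix <- function(n, k) {
  repeat {
    X <- matrix(rbinom(n * k, 1, runif(k, 0.15, 0.85)[rep(seq_len(k),
                                                          each = n)]),
                n, k)
    p <- colMeans(X)
    if (all(p > 0 & p < 1)) return(X)
  }
}

# quadrature marginal popularity of a 2PL item over a standard-normal trait
pop_quadrature <- function(a, b) {
  stats::integrate(function(t) plogis(a * (t - b)) * dnorm(t),
                   -Inf, Inf)$value
}

# greedy restscore merge, re-implemented straightforwardly for comparison
oracle_group_restscores <- function(R, minsize) {
  vals <- sort(unique(R))
  groups <- list()
  current <- c()
  cur_n <- 0
  for (v in vals) {
    current <- c(current, v)
    cur_n <- cur_n + sum(R == v)
    if (cur_n >= minsize) {
      groups[[length(groups) + 1]] <- current
      current <- c(); cur_n <- 0
    }
  }
  if (cur_n > 0) {
    if (cur_n >= minsize || length(groups) == 0) {
      groups[[length(groups) + 1]] <- current
    } else {
      groups[[length(groups)]] <- c(groups[[length(groups)]], current)
    }
  }
  out <- integer(length(R))
  for (g in seq_along(groups)) out[R %in% groups[[g]]] <- g
  out
}
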