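# Loevinger scalability coefficients for dichotomous items.
#
# For an item pair, let the "harder" item h be the less popular one (tie:
# lower column index) and e the other. A Guttman error is a household owning
# the harder item but not the easier one. With F = observed error count and
# E = n * p_h * (1 - p_e) the count expected under independence,
#   H_ij = 1 - F/E,
# which is algebraically identical to cov(X_i, X_j) / (p_h (1 - p_e)) with
# the n-denominator covariance. The covariance form is the canonical
# computation here (unaffected by the tie designation); item and scale
# coefficients are ratio aggregates: H_i = 1 - sum_j F_ij / sum_j E_ij and
# H = 1 - sum_{i<j} F_ij / sum_{i<j} E_ij.

# cov/covmax building blocks shared by every H computation
.h_parts <- function(X) {
  X <- unclass(X)
  n <- nrow(X)
  p <- colMeans(X)
  p11 <- crossprod(X) / n
  covm <- p11 - tcrossprod(p)
  pmin_ <- outer(p, p, pmin)
  pmax_ <- outer(p, p, pmax)
  covmax <- pmin_ * (1 - pmax_)
  diag(covm) <- diag(covmax) <- NA_real_
  list(n = n, p = p, cov = covm, covmax = covmax)
}

.scale_H_from_parts <- function(parts) {
  cm <- parts$cov; cx <- parts$covmax
  ut <- upper.tri(cm)
  1 - (sum(cx[ut]) - sum(cm[ut])) / sum(cx[ut])
}

.item_H_from_parts <- function(parts) {
  num <- rowSums(parts$covmax - parts$cov, na.rm = TRUE)
  den <- rowSums(parts$covmax, na.rm = TRUE)
  1 - num / den
}

# internal fast H for a plain 0/1 matrix (no class ceremony)
.scale_H <- function(X) .scale_H_from_parts(.h_parts(X))
.item_H <- function(X) .item_H_from_parts(.h_parts(X))

#' Strength label for a scalability coefficient
#'
#' Conventional interpretation bands: below .3 unscalable, .3-.4 weak,
#' .4-.5 medium, above .5 strong.
#'
#' @param H numeric vector of H coefficients.
#' @return character vector of labels.
#' @export
scalability_strength <- function(H) {
  cut(H, breaks = c(-Inf, 0.3, 0.4, 0.5, Inf), right = FALSE,
      labels = c("unscalable", "weak", "medium", "strong")) |> as.character()
}

#' Loevinger scalability coefficients H_ij, H_i, H and H^T
#'
#' Computes the full pairwise table of Loevinger coefficients, per-item
#' coefficients, the scale coefficient, and (optionally) the coefficient of
#' the transposed matrix, which summarises how accurately the item ordering
#' holds across households. Standard errors of the item coefficients come
#' from a seeded nonparametric bootstrap over households.
#'
#' @param x a [as_response_matrix()] input.
#' @param se logical; bootstrap standard errors for the `H_i`?
#' @param n_boot bootstrap replicates (>= 200) when `se = TRUE`.
#' @param seed integer seed for the bootstrap.
#' @param transpose logical; also compute `H^T` via [transposed_H()]?
#' @return an object of class `scalability_report`: list with `pairs`
#'   (data frame `item_i`, `item_j`, `harder`, `F`, `E`, `H_ij`), `item`
#'   (data frame `item`, `popularity`, `H_i`, `se`, `strength`), `scale_H`,
#'   `scale_strength`, `transposed_H`, `n`, `k`.
#' @examples
#' x <- make_guttman(c(-1, 0, 1, 2), c(-0.5, 0.5, 1.5))
#' compute_scalability(x)$scale_H  # 1: a Guttman pattern has no errors
#' @export
compute_scalability <- function(x, se = FALSE, n_boot = 1000, seed = 1,
                                transpose = TRUE) {
  x <- as_response_matrix(x)
  parts <- .h_parts(x)
  n <- parts$n
  k <- ncol(x)
  labels <- colnames(x)
  p <- parts$p

  ij <- which(upper.tri(parts$cov), arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  # harder item: lower popularity, ties to the lower index
  harder <- ifelse(p[j] < p[i], j, i)
  easier <- ifelse(harder == i, j, i)
  E <- n * parts$covmax[ij]
  F_ <- E - n * parts$cov[ij]
  pairs <- data.frame(
    item_i = labels[i], item_j = labels[j], harder = labels[harder],
    F = F_, E = E, H_ij = parts$cov[ij] / parts$covmax[ij],
    row.names = NULL)

  item_H <- .item_H_from_parts(parts)
  ses <- rep(NA_real_, k)
  if (se) ses <- se_item_H(x, n_boot = n_boot, seed = seed)$se

  rep_ <- list(
    pairs = pairs,
    item = data.frame(item = labels, popularity = unname(p),
                      H_i = unname(item_H), se = ses,
                      strength = scalability_strength(item_H),
                      row.names = NULL),
    scale_H = .scale_H_from_parts(parts),
    transposed_H = if (transpose) {
      tryCatch(transposed_H(x), error = function(e) {
        message("H^T unavailable: ", conditionMessage(e))
        NA_real_
      })
    } else NA_real_,
    n = n, k = k)
  rep_$scale_strength <- scalability_strength(rep_$scale_H)
  class(rep_) <- "scalability_report"
  rep_
}

#' @export
print.scalability_report <- function(x, ...) {
  cat(sprintf("Scalability of %d items on %d households\n", x$k, x$n))
  cat(sprintf("  scale H = %.3f (%s),  H^T = %s\n", x$scale_H,
              x$scale_strength,
              ifelse(is.na(x$transposed_H), "not computed",
                     sprintf("%.3f", x$transposed_H))))
  print(x$item, digits = 3)
  invisible(x)
}

#' Bootstrap standard errors of the item scalability coefficients
#'
#' Households are resampled with replacement and the `H_i` recomputed; the
#' standard error is the standard deviation across replicates. Replicates in
#' which an item becomes constant leave every `H` undefined and are dropped
#' (with a message); more than 10% dropped raises a warning, all dropped an
#' error.
#'
#' @param x a [as_response_matrix()] input.
#' @param n_boot number of bootstrap replicates, at least 200.
#' @param seed integer seed; results are reproducible given the seed.
#' @return list with `se` (numeric per item), `n_boot_used`, `n_dropped`.
#' @export
se_item_H <- function(x, n_boot = 1000, seed = 1) {
  x <- as_response_matrix(x)
  if (n_boot < 200) stop("n_boot must be at least 200")
  X <- unclass(x)
  n <- nrow(X)
  set.seed(as.integer(seed))
  out <- matrix(NA_real_, n_boot, ncol(X))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    Xb <- X[sample.int(n, n, replace = TRUE), , drop = FALSE]
    pb <- colMeans(Xb)
    if (any(pb == 0 | pb == 1)) {
      dropped <- dropped + 1L
      next
    }
    out[b, ] <- .item_H(Xb)
  }
  used <- n_boot - dropped
  if (used == 0L) {
    stop("all bootstrap replicates degenerate (constant item in every resample)")
  }
  if (dropped > 0L) {
    message(dropped, " bootstrap replicate(s) dropped for constant items")
    if (dropped > 0.1 * n_boot) {
      warning("more than 10% of bootstrap replicates dropped; ",
              "standard errors may be unreliable")
    }
  }
  list(se = apply(out, 2, stats::sd, na.rm = TRUE),
       n_boot_used = used, n_dropped = dropped)
}

#' Scalability of the transposed response matrix
#'
#' Treating households as "items", the scale coefficient of the transposed
#' matrix summarises the accuracy of the item (asset) ordering across
#' households. Households with constant response patterns (owning everything
#' or nothing) become constant columns after transposition and are dropped
#' with a message.
#'
#' @param x a [as_response_matrix()] input.
#' @return the scalar `H^T`.
#' @export
transposed_H <- function(x) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  q <- rowMeans(X)
  keep <- q > 0 & q < 1
  if (sum(!keep) > 0) {
    message(sum(!keep), " constant household row(s) dropped for H^T")
  }
  if (sum(keep) < 2L) stop("fewer than 2 non-constant households; H^T undefined")
  X <- X[keep, , drop = FALSE]
  q <- q[keep]
  k <- ncol(X)
  n <- nrow(X)
  # O(n k + n log n): sum over household pairs of cov and covmax without
  # materialising the n x n matrices.
  # sum of pairwise inner products of rows = (sum_i c_i^2 - sum_h r_h) / 2
  cs <- colSums(X)
  rs <- rowSums(X)
  sum_inner <- (sum(cs^2) - sum(rs)) / 2
  sum_qq <- (sum(q)^2 - sum(q^2)) / 2
  sum_cov <- sum_inner / k - sum_qq
  # covmax for a pair = q_(h) * (1 - q_(h')) with q_(h) <= q_(h'); sort and
  # use suffix sums of (1 - q)
  qs <- sort(q)
  suffix <- rev(cumsum(rev(1 - qs)))
  # pair (i, j>i): q_i * (1 - q_j)
  sum_covmax <- sum(qs[-n] * (suffix[-1]))
  sum_cov / sum_covmax
}
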