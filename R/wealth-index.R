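# Household SEP scores: the Mokken unweighted sum with wealth quintiles,
# and the contrasting principal-component index built on the tetrachoric
# (polychoric for 2x2 tables) correlation matrix.

#' Assign wealth quintiles to scores
#'
#' Boundary for quintile `q` (q = 1..4) is the smallest score whose
#' empirical CDF reaches `q/5`; every household sharing a score shares a
#' quintile, so with heavily tied discrete sum scores the fifths are only
#' approximate — by design, ties are never split.
#'
#' @param scores numeric vector (at least 5 values, at least 2 distinct).
#' @return integer labels 1 (poorest fifth) to 5 (wealthiest), with the four
#'   boundary scores in attribute `boundaries`.
#' @examples
#' quintile_assign(c(0, 0, 0, 0, 0, 0, 1, 2, 3, 4))  # six zeros share q1
#' @export
quintile_assign <- function(scores) {
  if (length(scores) < 5L) stop("need at least 5 scores for quintiles")
  if (length(unique(scores)) < 2L) {
    stop("scores are constant; quintiles are undefined")
  }
  svals <- sort(unique(scores))
  cdf <- stats::ecdf(scores)(svals)
  bounds <- vapply(1:4, function(q) svals[which(cdf >= q / 5)[1L]], numeric(1))
  labels <- rep(5L, length(scores))
  for (q in 4:1) labels[scores <= bounds[q]] <- q
  structure(labels, boundaries = bounds)
}

.new_wealth_index <- function(method, score, items, household_ids) {
  q <- quintile_assign(score)
  structure(list(method = method, score = as.numeric(score),
                 quintile = as.integer(q),
                 boundaries = attr(q, "boundaries"),
                 items = items, household_ids = household_ids),
            class = "wealth_index")
}

#' @export
print.wealth_index <- function(x, ...) {
  cat("Wealth index (", x$method, "), ", length(x$score), " households, ",
      length(x$items), " items\n", sep = "")
  cat("quintile sizes:", paste(tabulate(x$quintile, 5), collapse = " "), "\n")
  invisible(x)
}

#' Mokken SEP score: unweighted sum over scale items
#'
#' Under the monotone homogeneity model the simple count of owned scale
#' assets orders households on the latent trait, which is the whole point of
#' the Mokken approach: no weights to estimate.
#'
#' @param x a [as_response_matrix()] input.
#' @param items scale columns (indices or labels); default all.
#' @return a `wealth_index` with integer scores in `[0, length(items)]` and
#'   quintile labels.
#' @export
mokken_score <- function(x, items = NULL) {
  x <- as_response_matrix(x)
  if (is.null(items)) items <- seq_len(ncol(x))
  items <- .resolve_items(x, items)
  if (length(items) == 0L) stop("empty item set")
  score <- rowSums(unclass(x)[, items, drop = FALSE])
  .new_wealth_index("mokken_sum", score, colnames(x)[items], rownames(x))
}

#' Tetrachoric correlation from a 2x2 table
#'
#' Two-step maximum likelihood under a latent bivariate normal: thresholds
#' from the inverse-normal of the margins, then the correlation maximising
#' the multinomial likelihood of the four orthant probabilities. A table
#' with a zero cell gets 0.5 added to all four cells (logged via message).
#'
#' @param tab 2x2 numeric matrix of counts, rows = first item (1 then 0),
#'   columns = second item (1 then 0).
#' @param correct continuity correction added to all cells when any cell is
#'   zero.
#' @return object of class `tetrachoric_estimate`: list with `rho`,
#'   `thresholds` (tau_i, tau_j), `converged`, `loglik`, `corrected`,
#'   `clipped`.
#' @examples
#' tetrachoric_rho(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))$rho  # ~0.809
#' @export
tetrachoric_rho <- function(tab, correct = 0.5) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2L), all(tab >= 0))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("zero margin: tetrachoric correlation undefined")
  }
  corrected <- FALSE
  if (any(tab == 0)) {
    tab <- tab + correct
    corrected <- TRUE
    message("zero cell: continuity correction +", correct,
            " applied to all cells")
  }
  n <- sum(tab)
  p1 <- sum(tab[1, ]) / n   # P(first item = 1)
  p2 <- sum(tab[, 1]) / n
  tau1 <- stats::qnorm(1 - p1)
  tau2 <- stats::qnorm(1 - p2)
  lim <- 1 - 1e-6
  negll <- function(rho) {
    p11 <- mvtnorm::pmvnorm(lower = c(tau1, tau2), upper = c(Inf, Inf),
                            corr = matrix(c(1, rho, rho, 1), 2))[1]
    p10 <- (1 - stats::pnorm(tau1)) - p11
    p01 <- (1 - stats::pnorm(tau2)) - p11
    p00 <- 1 - p11 - p10 - p01
    probs <- pmax(c(p11, p10, p01, p00), 1e-12)
    -sum(c(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]) * log(probs))
  }
  opt <- stats::optimize(negll, c(-lim, lim), tol = 1e-9)
  rho <- opt$minimum
  clipped <- abs(rho) >= lim - 1e-5
  structure(list(rho = rho, thresholds = c(tau1, tau2),
                 converged = !clipped, loglik = -opt$objective,
                 corrected = corrected, clipped = clipped),
            class = "tetrachoric_estimate")
}

#' Pairwise tetrachoric correlation matrix of binary items
#'
#' The polychoric correlation matrix for dichotomous data: each off-diagonal
#' entry is the [tetrachoric_rho()] of the pair's cross-table. If the
#' assembled matrix is not positive semi-definite it is repaired by clipping
#' negative eigenvalues and rescaling to unit diagonal (logged).
#'
#' @param x a [as_response_matrix()] input.
#' @return a k x k correlation matrix with item labels.
#' @export
polychoric_matrix <- function(x) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  k <- ncol(X)
  n <- nrow(X)
  p11 <- crossprod(X)
  cs <- colSums(X)
  R <- diag(k)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      n11 <- p11[i, j]
      tab <- matrix(c(n11, cs[i] - n11, cs[j] - n11, n - cs[i] - cs[j] + n11),
                    2, 2, byrow = TRUE)
      R[i, j] <- R[j, i] <- tetrachoric_rho(tab)$rho
    }
  }
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-8) {
    message("polychoric matrix not PSD (min eigenvalue ",
            format(min(ev$values), digits = 3), "); repaired by clipping")
    vals <- pmax(ev$values, 1e-8)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    R <- stats::cov2cor(R)
  }
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}

#' First principal component of a correlation matrix
#'
#' Eigendecomposition with components ordered by descending eigenvalue;
#' variance proportions are eigenvalue/k (the trace of a correlation matrix
#' is k). First-component loadings are sign-normalised so their sum is
#' positive, making "higher score = wealthier" the convention.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @return object of class `pca_result`: list with `loadings` (first
#'   eigenvector, sign-normalised), `eigenvalues` (descending),
#'   `variance_proportions`, `k`.
#' @export
pca_first_component <- function(corr) {
  corr <- as.matrix(corr)
  if (!isSymmetric(corr, tol = 1e-8)) stop("correlation matrix not symmetric")
  k <- ncol(corr)
  ev <- eigen(corr, symmetric = TRUE)
  loadings <- ev$vectors[, 1]
  if (sum(loadings) < 0) loadings <- -loadings
  names(loadings) <- colnames(corr)
  structure(list(loadings = loadings, eigenvalues = ev$values,
                 variance_proportions = ev$values / k, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA of a", x$k, "x", x$k, "correlation matrix\n")
  cat("variance proportions:",
      paste(sprintf("%.3f", utils::head(x$variance_proportions, 4)),
            collapse = " "), "...\n")
  invisible(x)
}

#' PCA-based SEP score for each household
#'
#' Filmer-Pritchett style scoring: each item is centred by its popularity
#' and scaled by its Bernoulli standard deviation, then combined with the
#' first-component loadings. A hypothetical household sitting at every item
#' mean scores exactly zero.
#'
#' @param x a [as_response_matrix()] input whose columns match the loadings.
#' @param pca a [pca_first_component()] result.
#' @return a `wealth_index` with continuous scores and quintile labels.
#' @export
pca_scores <- function(x, pca) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  if (length(pca$loadings) != ncol(X)) {
    stop("loadings length (", length(pca$loadings),
         ") does not match item count (", ncol(X), ")")
  }
  p <- colMeans(X)
  Z <- sweep(sweep(X, 2, p), 2, sqrt(p * (1 - p)), "/")
  score <- drop(Z %*% pca$loadings)
  .new_wealth_index("pca", score, colnames(X), rownames(X))
}
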