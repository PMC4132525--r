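# Reliability and the three-way comparison of SEP measures against log
# household expenditure.

#' Weighted Cronbach's alpha with a Feldt confidence interval
#'
#' Items are rescaled as `y_i = w_i * x_i` before the usual alpha formula
#' `k/(k-1) * (1 - sum(var(y_i)) / var(sum(y_i)))` with `n - 1` denominator
#' variances. Unit weights give the plain alpha of a sum scale; first
#' principal-component loadings give the reliability of the corresponding
#' weighted index. The confidence interval uses Feldt's F-distribution
#' method with `n - 1` and `(n - 1)(k - 1)` degrees of freedom. Alpha is
#' invariant to rescaling all weights by a common positive factor.
#'
#' @param x a [as_response_matrix()] input (or any numeric items matrix).
#' @param weights numeric vector, one finite weight per item (default unit).
#' @param conf_level confidence level, default 0.95.
#' @return object of class `reliability_result`: list with `alpha`,
#'   `ci_low`, `ci_high`, `conf_level`, `weights`, `n`, `k`, `ci_method`.
#' @export
weighted_alpha <- function(x, weights = NULL, conf_level = 0.95) {
  X <- if (inherits(x, "response_matrix")) unclass(x) else as.matrix(x)
  n <- nrow(X)
  k <- ncol(X)
  if (k < 2L) stop("alpha needs at least 2 items")
  if (is.null(weights)) weights <- rep(1, k)
  if (length(weights) != k || !all(is.finite(weights))) {
    stop("weights must be ", k, " finite values")
  }
  Y <- sweep(X, 2, weights, "*")
  item_vars <- apply(Y, 2, stats::var)
  total_var <- stats::var(rowSums(Y))
  if (total_var == 0) stop("total score has zero variance; alpha undefined")
  alpha <- k / (k - 1) * (1 - sum(item_vars) / total_var)
  gamma <- 1 - conf_level
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  ci_low <- 1 - (1 - alpha) * stats::qf(1 - gamma / 2, df1, df2)
  ci_high <- 1 - (1 - alpha) * stats::qf(gamma / 2, df1, df2)
  structure(list(alpha = alpha, ci_low = ci_low, ci_high = ci_high,
                 conf_level = conf_level, weights = weights, n = n, k = k,
                 ci_method = "Feldt"),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d%% CI %.3f-%.3f, Feldt), n = %d, k = %d\n",
              x$alpha, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n, x$k))
  invisible(x)
}

.check_variance <- function(v, name) {
  if (stats::sd(v) == 0) stop("zero variance in ", name)
}

#' Compare SEP indices with each other and with household expenditure
#'
#' Expenditure is natural-log transformed (expenditure distributions are
#' long-tailed). Continuous scores are compared by Pearson correlation,
#' quintile labels by Spearman rank correlation with average ranks for the
#' (heavily tied) labels; each index also gets a per-quintile expenditure
#' summary (n, quartiles, median) matching what a quintile boxplot would
#' display.
#'
#' @param mokken,pca_full,pca_reduced `wealth_index` objects on the same
#'   households.
#' @param expenditure strictly positive expenditure vector, same length.
#' @return object of class `comparison_report`: list with
#'   `pearson` (correlation matrix of the three continuous scores and log
#'   expenditure), `spearman` (quintiles and log expenditure),
#'   `quintile_summary` (data frame: index, quintile, n, q1, median, q3),
#'   `log_base` ("natural").
#' @export
compare_indices <- function(mokken, pca_full, pca_reduced, expenditure) {
  idx <- list(mokken = mokken, pca_full = pca_full, pca_reduced = pca_reduced)
  stopifnot(all(vapply(idx, inherits, logical(1), "wealth_index")))
  n <- length(expenditure)
  if (any(vapply(idx, function(i) length(i$score), integer(1)) != n)) {
    stop("all indices and expenditure must cover the same households")
  }
  if (any(expenditure <= 0)) stop("expenditure must be strictly positive")
  for (nm in names(idx)) .check_variance(idx[[nm]]$score, nm)
  .check_variance(expenditure, "expenditure")
  log_exp <- log(expenditure)

  cont <- cbind(vapply(idx, function(i) i$score, numeric(n)),
                log_expenditure = log_exp)
  pearson <- stats::cor(cont, method = "pearson")
  quin <- cbind(vapply(idx, function(i) as.numeric(i$quintile), numeric(n)),
                log_expenditure = log_exp)
  spearman <- stats::cor(quin, method = "spearman")

  qs <- do.call(rbind, lapply(names(idx), function(nm) {
    do.call(rbind, lapply(1:5, function(q) {
      e <- log_exp[idx[[nm]]$quintile == q]
      qq <- if (length(e)) stats::quantile(e, c(.25, .5, .75), names = FALSE)
            else rep(NA_real_, 3)
      data.frame(index = nm, quintile = q, n = length(e),
                 q1 = qq[1], median = qq[2], q3 = qq[3])
    }))
  }))
  structure(list(pearson = pearson, spearman = spearman,
                 quintile_summary = qs, log_base = "natural", n = n),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Comparison of SEP indices on", x$n, "households\n")
  cat("Pearson (continuous scores, log expenditure):\n")
  print(round(x$pearson, 3))
  cat("Spearman (quintiles, log expenditure):\n")
  print(round(x$spearman, 3))
  invisible(x)
}
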