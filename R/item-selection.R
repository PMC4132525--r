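# Automated item selection procedure: sequential bottom-up partitioning of
# an item pool into Mokken scales under Loevinger-H constraints.

#' Configuration for the automated item selection procedure
#'
#' @param c lower-bound scalability threshold in `[0, 1)`; items enter a
#'   scale only while their within-scale `H_i` stays at or above `c`. The
#'   conventional default is 0.3.
#' @param alpha one-sided significance level for the `H_ij > 0` tests.
#' @param n_boot bootstrap replicates for the significance test.
#' @param seed integer base seed; each pair's test derives its own stream.
#' @return a list of class `selection_config`.
#' @export
selection_config <- function(c = 0.3, alpha = 0.05, n_boot = 500, seed = 1) {
  stopifnot(c >= 0, c < 1, alpha > 0, alpha < 1, n_boot >= 100)
  structure(list(c = c, alpha = alpha, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "selection_config")
}

#' One-sided bootstrap test of a positive pairwise scalability coefficient
#'
#' `H_ij` depends on the pair's responses only through the 2x2 cross-table,
#' so the household bootstrap reduces exactly to resampling the four cell
#' counts from a multinomial. The pair is declared significantly positive
#' when the `alpha` percentile of the bootstrap distribution of `H_ij`
#' exceeds zero. Replicates in which either item becomes constant leave
#' `H_ij` undefined and are dropped; a fully degenerate bootstrap is treated
#' as non-significant (with a message).
#'
#' @param x a [as_response_matrix()] input.
#' @param i,j item column indices.
#' @param config a [selection_config()].
#' @return list with `significant` (logical), `p_value` (bootstrap fraction
#'   of replicates with `H_ij <= 0`), `H_ij`, `n_dropped`.
#' @export
significance_positive_Hij <- function(x, i, j, config = selection_config()) {
  x <- as_response_matrix(x)
  X <- unclass(x)[, c(i, j), drop = FALSE]
  n <- nrow(X)
  n11 <- sum(X[, 1] == 1L & X[, 2] == 1L)
  n10 <- sum(X[, 1] == 1L & X[, 2] == 0L)
  n01 <- sum(X[, 1] == 0L & X[, 2] == 1L)
  n00 <- n - n11 - n10 - n01
  # deterministic per-pair stream derived from the base seed
  set.seed((config$seed + 7919L * min(i, j) + 104729L * max(i, j)) %% .Machine$integer.max)
  cells <- stats::rmultinom(config$n_boot, n, c(n11, n10, n01, n00) / n)
  p1 <- (cells[1, ] + cells[2, ]) / n
  p2 <- (cells[1, ] + cells[3, ]) / n
  ok <- p1 > 0 & p1 < 1 & p2 > 0 & p2 < 1
  hstar <- (cells[1, ok] / n - p1[ok] * p2[ok]) /
    (pmin(p1[ok], p2[ok]) * (1 - pmax(p1[ok], p2[ok])))
  h_obs <- (n11 / n - (n11 + n10) / n * (n11 + n01) / n) /
    (min(n11 + n10, n11 + n01) / n * (1 - max(n11 + n10, n11 + n01) / n))
  n_dropped <- sum(!ok)
  if (length(hstar) == 0L) {
    message("degenerate bootstrap for pair (", i, ",", j,
            "); treated as non-significant")
    return(list(significant = FALSE, p_value = 1, H_ij = h_obs,
                n_dropped = n_dropped))
  }
  sig <- unname(stats::quantile(hstar, config$alpha, names = FALSE) > 0)
  list(significant = sig, p_value = mean(hstar <= 0), H_ij = h_obs,
       n_dropped = n_dropped)
}

#' Automated item selection procedure (AISP)
#'
#' Partitions the item pool into zero or more Mokken scales bottom-up:
#' \enumerate{
#'   \item among unassigned items, seed a new scale with the pair maximising
#'     `H_ij` among pairs that are significantly positive and have
#'     `H_ij >= c`;
#'   \item repeatedly add the unassigned item that is significantly
#'     positively related to every current member, whose within-scale `H_i`
#'     (computed on the augmented scale) is at least `c`, and that maximises
#'     the augmented scale's `H`; ties go to the higher `H_i`, then the
#'     lower column index;
#'   \item when no item qualifies, close the scale and restart on the
#'     remainder.
#' }
#' Items never seeded or added are unscalable. The full decision trail is
#' kept in `selection_log`.
#'
#' @param x a [as_response_matrix()] input.
#' @param config a [selection_config()].
#' @return object of class `scale_partition`: list with `scales` (list of
#'   integer index vectors in formation order), `unscalable` (integer
#'   vector), `reports` (per-scale [compute_scalability()] output),
#'   `selection_log` (data frame of decisions), `n_sig_tests`, `item_labels`.
#' @examples
#' x <- make_guttman(rnorm(100), c(-1, 0, 1))
#' aisp(x)$scales  # one scale holding all three items
#' @export
aisp <- function(x, config = selection_config()) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  k <- ncol(X)
  labels <- colnames(X)
  parts <- .h_parts(X)
  Hij <- parts$cov / parts$covmax

  # all pairwise significance decisions up front (cached, deterministic)
  sig <- matrix(NA, k, k)
  n_tests <- 0L
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      res <- significance_positive_Hij(x, i, j, config)
      sig[i, j] <- sig[j, i] <- res$significant
      n_tests <- n_tests + 1L
    }
  }

  unassigned <- seq_len(k)
  scales <- list()
  log_rows <- list()
  log_add <- function(action, scale, item, value) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      step = length(log_rows) + 1L, action = action, scale = scale,
      item = item, value = value)
  }

  repeat {
    if (length(unassigned) < 2L) break
    # (1) seed: best significantly-positive pair with H_ij >= c
    cand <- expand.grid(i = unassigned, j = unassigned)
    cand <- cand[cand$i < cand$j, ]
    ok <- sig[cbind(cand$i, cand$j)] & Hij[cbind(cand$i, cand$j)] >= config$c
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0L) break
    h <- Hij[cbind(cand$i, cand$j)]
    pick <- order(-h, cand$i, cand$j)[1L]
    scale <- c(cand$i[pick], cand$j[pick])
    sid <- length(scales) + 1L
    log_add("seed", sid, paste(labels[scale], collapse = "+"), h[pick])
    unassigned <- setdiff(unassigned, scale)

    # (2) grow
    repeat {
      pool <- unassigned[vapply(unassigned, function(it)
        all(sig[it, scale]), logical(1))]
      if (length(pool) == 0L) break
      stats_ <- vapply(pool, function(it) {
        aug <- c(scale, it)
        ph <- .h_parts(X[, aug, drop = FALSE])
        hi <- unname(.item_H_from_parts(ph)[length(aug)])
        c(H = .scale_H_from_parts(ph), Hi = hi)
      }, numeric(2))
      keep <- stats_["Hi", ] >= config$c
      if (!any(keep)) break
      pool <- pool[keep]
      stats_ <- stats_[, keep, drop = FALSE]
      o <- order(-stats_["H", ], -stats_["Hi", ], pool)[1L]
      add <- pool[o]
      scale <- c(scale, add)
      unassigned <- setdiff(unassigned, add)
      log_add("add", sid, labels[add], stats_["H", o])
    }
    scales[[sid]] <- sort(scale)
    log_add("close", sid, "", .scale_H(X[, scale, drop = FALSE]))
  }

  part <- structure(list(
    scales = scales,
    unscalable = unassigned,
    reports = lapply(scales, function(s)
      compute_scalability(as_response_matrix(X[, s, drop = FALSE]),
                          transpose = FALSE)),
    selection_log = if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(step = integer(), action = character(), scale = integer(),
                 item = character(), value = numeric()),
    n_sig_tests = n_tests,
    item_labels = labels), class = "scale_partition")
  # partition invariant: disjoint and exhaustive
  stopifnot(!anyDuplicated(c(unlist(part$scales), part$unscalable)),
            setequal(c(unlist(part$scales), part$unscalable), seq_len(k)))
  part
}

#' @export
print.scale_partition <- function(x, ...) {
  cat("AISP partition:", length(x$scales), "scale(s),",
      length(x$unscalable), "unscalable item(s)\n")
  for (s in seq_along(x$scales)) {
    cat(sprintf("  scale %d (H = %.3f): %s\n", s, x$reports[[s]]$scale_H,
                paste(x$item_labels[x$scales[[s]]], collapse = ", ")))
  }
  if (length(x$unscalable)) {
    cat("  unscalable:", paste(x$item_labels[x$unscalable], collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Table-1-style item report for a partition
#'
#' One row per item in original pool order: label, popularity, the scale it
#' was assigned to (`NA` when unscalable), and its within-scale `H_i` with
#' bootstrap standard error.
#'
#' @param x a `scale_partition`.
#' @param matrix the response matrix the partition was computed on.
#' @param n_boot,seed bootstrap settings for the per-scale standard errors.
#' @return a data frame.
#' @export
partition_item_table <- function(x, matrix, n_boot = 1000, seed = 1) {
  matrix <- as_response_matrix(matrix)
  p <- colMeans(matrix)
  k <- ncol(matrix)
  out <- data.frame(item = colnames(matrix), popularity = unname(p),
                    scale = NA_integer_, H_i = NA_real_, se = NA_real_)
  for (s in seq_along(x$scales)) {
    idx <- x$scales[[s]]
    sub <- as_response_matrix(unclass(matrix)[, idx, drop = FALSE])
    hi <- .item_H(sub)
    se <- tryCatch(se_item_H(sub, n_boot = n_boot, seed = seed)$se,
                   error = function(e) rep(NA_real_, length(idx)))
    out$scale[idx] <- s
    out$H_i[idx] <- hi
    out$se[idx] <- se
  }
  out
}
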