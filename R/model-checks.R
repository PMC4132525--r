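# Restscore checks of the monotone homogeneity and double monotonicity
# assumptions: item response proportions are examined across groups of
# households with similar rest scores (sum over the other scale items).

#' Configuration for the restscore model checks
#'
#' @param minvi minimum violation magnitude: a proportion reversal smaller
#'   than this is treated as noise. Default 0.03.
#' @param minsize minimum households per restscore group. Default
#'   `floor(n/10)` when `n >= 500`, else `max(50, floor(n/5))`, resolved
#'   when the data are seen (`NULL` here).
#' @param alpha significance level: a violation is *critical* when it
#'   exceeds `minvi` **and** its one-sided test has `p < alpha`.
#' @return list of class `check_config`.
#' @export
check_config <- function(minvi = 0.03, minsize = NULL, alpha = 0.05) {
  stopifnot(minvi >= 0, alpha > 0, alpha < 1,
            is.null(minsize) || minsize >= 2)
  structure(list(minvi = minvi, minsize = minsize, alpha = alpha),
            class = "check_config")
}

.resolve_minsize <- function(config, n) {
  if (!is.null(config$minsize)) return(as.integer(config$minsize))
  if (n >= 500) as.integer(floor(n / 10)) else
    as.integer(max(50, floor(n / 5)))
}

# greedy left-to-right merge of adjacent restscore values into groups of at
# least `minsize` households; an undersized final remainder joins the last
# closed group
.group_restscores <- function(R, minsize) {
  vals <- sort(unique(R))
  counts <- vapply(vals, function(v) sum(R == v), integer(1))
  grp_of_val <- integer(length(vals))
  g <- 1L
  acc <- 0L
  for (v in seq_along(vals)) {
    grp_of_val[v] <- g
    acc <- acc + counts[v]
    if (acc >= minsize && v < length(vals)) {
      g <- g + 1L
      acc <- 0L
    }
  }
  # remainder undersized: merge into previous group
  if (acc < minsize && acc > 0L && g > 1L) {
    grp_of_val[grp_of_val == g] <- g - 1L
  }
  grp <- grp_of_val[match(R, vals)]
  grp
}

#' Restscore grouping for a set of scale items
#'
#' Computes each household's rest score (sum over the scale items minus any
#' excluded ones) and merges adjacent rest-score values left-to-right until
#' every group holds at least `minsize` households.
#'
#' @param x a [as_response_matrix()] input.
#' @param scale_items columns forming the scale (indices or labels);
#'   defaults to all.
#' @param excluded_items items removed from the rest score (the item or pair
#'   under examination).
#' @param config a [check_config()].
#' @return object of class `restscore_table`: list with `group` (integer per
#'   household), `table` (data frame `group`, `r_min`, `r_max`, `n`),
#'   `minsize`.
#' @export
restscore_groups <- function(x, scale_items = NULL, excluded_items = integer(0),
                             config = check_config()) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  if (is.null(scale_items)) scale_items <- seq_len(ncol(X))
  scale_items <- .resolve_items(x, scale_items)
  excluded_items <- .resolve_items(x, excluded_items)
  rest <- setdiff(scale_items, excluded_items)
  if (length(rest) < 2L) stop("need at least 2 items in the rest score")
  R <- rowSums(X[, rest, drop = FALSE])
  n <- length(R)
  minsize <- .resolve_minsize(config, n)
  if (n < 2L * minsize) {
    warning("sample smaller than two restscore groups; using a single group")
    grp <- rep(1L, n)
  } else {
    grp <- .group_restscores(R, minsize)
  }
  tab <- do.call(rbind, lapply(sort(unique(grp)), function(g) {
    data.frame(group = g, r_min = min(R[grp == g]), r_max = max(R[grp == g]),
               n = sum(grp == g))
  }))
  structure(list(group = grp, rest_score = R, table = tab, minsize = minsize),
            class = "restscore_table")
}

# items given as labels or indices -> integer indices
.resolve_items <- function(x, items) {
  if (length(items) == 0L) return(integer(0))
  if (is.character(items)) {
    idx <- match(items, colnames(x))
    if (anyNA(idx)) stop("unknown item(s): ",
                         paste(items[is.na(idx)], collapse = ", "))
    idx
  } else {
    as.integer(items)
  }
}

.new_violation_report <- function(items, labels, comparisons, violations,
                                  critical, max_viol, z_max, check) {
  ord <- order(-critical, -max_viol, items)
  structure(list(
    items = data.frame(item = labels, comparisons = comparisons,
                       violations = violations, critical = critical,
                       max_violation = max_viol, z_max = z_max,
                       row.names = NULL),
    worst = if (sum(critical) > 0 || sum(violations) > 0) labels[ord[1L]]
            else NA_character_,
    check = check), class = "violation_report")
}

#' @export
print.violation_report <- function(x, ...) {
  cat("Restscore", x$check, "check\n")
  print(x$items, digits = 3)
  if (!is.na(x$worst)) cat("worst offender:", x$worst, "\n")
  invisible(x)
}

#' Check monotonicity of item response functions (MMH)
#'
#' For each scale item, households are grouped by the rest score over the
#' remaining items, and the item's positive-response proportion is compared
#' across every ordered group pair. A later group falling below an earlier
#' one by more than `minvi` is a violation; it is *critical* when the
#' one-sided two-proportion z-test is also significant at `alpha`.
#'
#' @param x a [as_response_matrix()] input.
#' @param scale_items scale columns (indices or labels); default all.
#' @param config a [check_config()].
#' @return a `violation_report`: per item the number of group-pair
#'   comparisons, violations, critical violations, maximum violation
#'   magnitude, and maximum z statistic.
#' @export
check_monotonicity <- function(x, scale_items = NULL, config = check_config()) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  if (is.null(scale_items)) scale_items <- seq_len(ncol(X))
  scale_items <- .resolve_items(x, scale_items)
  if (length(scale_items) < 3L) stop("monotonicity check needs >= 3 items")
  labels <- colnames(X)[scale_items]
  k <- length(scale_items)
  comparisons <- violations <- critical <- integer(k)
  max_viol <- z_max <- numeric(k)
  for (ii in seq_len(k)) {
    it <- scale_items[ii]
    rg <- restscore_groups(x, scale_items, excluded_items = it, config)
    gs <- sort(unique(rg$group))
    ng <- vapply(gs, function(g) sum(rg$group == g), integer(1))
    pg <- vapply(gs, function(g) mean(X[rg$group == g, it]), numeric(1))
    G <- length(gs)
    if (G < 2L) next
    prs <- utils::combn(G, 2)
    comparisons[ii] <- ncol(prs)
    for (cc in seq_len(ncol(prs))) {
      g1 <- prs[1, cc]; g2 <- prs[2, cc]
      vi <- pg[g1] - pg[g2]      # positive = later group lower = reversal
      if (vi > config$minvi) {
        violations[ii] <- violations[ii] + 1L
        pbar <- (pg[g1] * ng[g1] + pg[g2] * ng[g2]) / (ng[g1] + ng[g2])
        se <- sqrt(pbar * (1 - pbar) * (1 / ng[g1] + 1 / ng[g2]))
        z <- if (se > 0) vi / se else Inf
        max_viol[ii] <- max(max_viol[ii], vi)
        z_max[ii] <- max(z_max[ii], z)
        if (stats::pnorm(z, lower.tail = FALSE) < config$alpha) {
          critical[ii] <- critical[ii] + 1L
        }
      }
    }
  }
  .new_violation_report(scale_items, labels, comparisons, violations,
                        critical, max_viol, z_max, "monotonicity")
}

#' Check invariant item ordering via the restscore method (DMM)
#'
#' For every item pair (the harder item being the overall less popular one),
#' households are grouped by the rest score excluding both items. A group in
#' which the harder item is *more* popular than the easier one by more than
#' `minvi` violates non-intersection; the violation is *critical* when a
#' one-sided sign test on the group's discordant households (those owning
#' exactly one of the two) is significant at `alpha`. Tallies are aggregated
#' per item over all pairs containing it.
#'
#' @inheritParams check_monotonicity
#' @return a `violation_report`; also carries a `pairs` data frame of
#'   pair-level results.
#' @export
check_iio_restscore <- function(x, scale_items = NULL,
                                config = check_config()) {
  x <- as_response_matrix(x)
  X <- unclass(x)
  if (is.null(scale_items)) scale_items <- seq_len(ncol(X))
  scale_items <- .resolve_items(x, scale_items)
  if (length(scale_items) < 3L) stop("IIO check needs >= 3 items")
  labels <- colnames(X)[scale_items]
  k <- length(scale_items)
  p <- colMeans(X[, scale_items, drop = FALSE])
  comparisons <- violations <- critical <- integer(k)
  max_viol <- z_max <- numeric(k)
  pair_rows <- list()
  for (a in seq_len(k - 1)) {
    for (b in seq((a + 1), k)) {
      # harder = lower overall popularity (tie: lower index)
      if (p[b] < p[a]) { hh <- b; ee <- a } else { hh <- a; ee <- b }
      ih <- scale_items[hh]; ie <- scale_items[ee]
      rg <- restscore_groups(x, scale_items, excluded_items = c(ih, ie),
                             config)
      gs <- sort(unique(rg$group))
      vio <- 0L; crit <- 0L; mv <- 0; zm <- 0
      for (g in gs) {
        sel <- rg$group == g
        ph <- mean(X[sel, ih]); pe <- mean(X[sel, ie])
        vi <- ph - pe
        comparisons[hh] <- comparisons[hh] + 1L
        comparisons[ee] <- comparisons[ee] + 1L
        if (vi > config$minvi) {
          vio <- vio + 1L
          # discordant households within the group: harder-only vs easier-only
          n10 <- sum(X[sel, ih] == 1L & X[sel, ie] == 0L)
          n01 <- sum(X[sel, ih] == 0L & X[sel, ie] == 1L)
          pval <- if (n10 + n01 > 0) {
            stats::pbinom(n10 - 1L, n10 + n01, 0.5, lower.tail = FALSE)
          } else 1
          z <- stats::qnorm(pval, lower.tail = FALSE)
          mv <- max(mv, vi)
          zm <- max(zm, z)
          if (pval < config$alpha) crit <- crit + 1L
        }
      }
      violations[hh] <- violations[hh] + vio
      violations[ee] <- violations[ee] + vio
      critical[hh] <- critical[hh] + crit
      critical[ee] <- critical[ee] + crit
      max_viol[hh] <- max(max_viol[hh], mv)
      max_viol[ee] <- max(max_viol[ee], mv)
      z_max[hh] <- max(z_max[hh], zm)
      z_max[ee] <- max(z_max[ee], zm)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        harder = labels[hh], easier = labels[ee], groups = length(gs),
        violations = vio, critical = crit, max_violation = mv)
    }
  }
  rep_ <- .new_violation_report(scale_items, labels, comparisons, violations,
                                critical, max_viol, z_max, "IIO")
  rep_$pairs <- do.call(rbind, pair_rows)
  rep_
}

#' Iteratively remove items violating invariant item ordering
#'
#' Runs [check_iio_restscore()]; while any critical violations remain, the
#' item with the most critical violations is removed (ties: larger maximum
#' violation, then lower within-scale `H_i`, then lower column index) and
#' the check repeated. Stops when no critical violations remain or the
#' scale would shrink below 3 items.
#'
#' @inheritParams check_monotonicity
#' @return list with `retained` (item indices), `removal_log` (data frame
#'   `step`, `item`, `critical`, `max_violation`), `final_report`.
#' @export
iterative_iio_removal <- function(x, scale_items = NULL,
                                  config = check_config()) {
  x <- as_response_matrix(x)
  if (is.null(scale_items)) scale_items <- seq_len(ncol(x))
  scale_items <- .resolve_items(x, scale_items)
  current <- scale_items
  log_rows <- list()
  rep_ <- NULL
  step <- 0L
  repeat {
    if (length(current) < 3L) {
      warning("scale shrank below 3 items; stopping IIO removal")
      break
    }
    rep_ <- check_iio_restscore(x, current, config)
    tab <- rep_$items
    if (sum(tab$critical) == 0L) break
    hi <- .item_H(unclass(x)[, current, drop = FALSE])
    ord <- order(-tab$critical, -tab$max_violation, hi, current)
    drop_ii <- ord[1L]
    step <- step + 1L
    log_rows[[step]] <- data.frame(
      step = step, item = tab$item[drop_ii], critical = tab$critical[drop_ii],
      max_violation = tab$max_violation[drop_ii])
    message("IIO removal step ", step, ": dropping ", tab$item[drop_ii],
            " (", tab$critical[drop_ii], " critical violation(s))")
    current <- current[-drop_ii]
  }
  list(retained = current,
       removal_log = if (step > 0L) do.call(rbind, log_rows) else
         data.frame(step = integer(), item = character(),
                    critical = integer(), max_violation = numeric()),
       final_report = rep_)
}
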