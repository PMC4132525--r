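# Synthetic household asset/expenditure data with the statistical structure
# the scaling analysis assumes: a dominant monotone latent trait driving
# 2PL logistic item responses, a long-tailed log-normal expenditure
# moderately correlated with the trait, plus controlled violations
# (non-monotone and intersecting items) for power and specificity tests.

#' Configuration of the latent-trait response model
#'
#' Households carry a standard-normal latent socioeconomic trait `theta`.
#' Item `i` is owned with probability `plogis(a_i * (theta - b_i))`: `a_i`
#' is the discrimination (equal discriminations give non-intersecting,
#' Rasch-like response functions), `b_i` the difficulty (the trait level at
#' which ownership probability is 1/2). Four-weekly household expenditure is
#' `exp(mu + lambda * theta + sigma * eps)`: with `lambda = 0.75 * sigma`,
#' `cor(log expenditure, theta) = 0.6`.
#'
#' @param n_households positive integer.
#' @param items data frame with numeric columns `a` (> 0) and `b`, optional
#'   `label`.
#' @param expenditure list with `mu` (log-scale mean), `lambda` (trait
#'   loading, >= 0) and `sigma` (log-scale noise SD, > 0).
#' @param seed integer seed; the dataset is bit-reproducible from it.
#' @return list of class `latent_config`.
#' @export
latent_config <- function(n_households, items,
                          expenditure = list(mu = 7, lambda = 0.525,
                                             sigma = 0.7),
                          seed = 1) {
  items <- as.data.frame(items)
  if (nrow(items) == 0L) stop("item_params must be non-empty")
  if (!all(c("a", "b") %in% names(items))) stop("items need columns a and b")
  if (any(items$a <= 0)) stop("discriminations a must be positive")
  if (is.null(items$label)) items$label <- paste0("item", seq_len(nrow(items)))
  stopifnot(n_households >= 1, expenditure$sigma > 0, expenditure$lambda >= 0)
  structure(list(n_households = as.integer(n_households), items = items,
                 expenditure = expenditure, seed = as.integer(seed)),
            class = "latent_config")
}

#' Simulate household responses and expenditure from a latent trait
#'
#' Draws `theta` standard normal, item responses Bernoulli with 2PL
#' probabilities, and expenditure log-normal with loading `lambda` on the
#' trait; a single seeded RNG stream makes the dataset bit-reproducible.
#'
#' @param config a [latent_config()].
#' @return object of class `synthetic_dataset`: list with `responses` (a
#'   `response_matrix`), `theta`, `expenditure` (strictly positive), and
#'   `generating_config`.
#' @export
simulate_responses <- function(config) {
  stopifnot(inherits(config, "latent_config"))
  set.seed(config$seed)
  n <- config$n_households
  a <- config$items$a
  b <- config$items$b
  theta <- stats::rnorm(n)
  pr <- stats::plogis(outer(theta, b, "-") * rep(a, each = n))
  X <- matrix((stats::runif(n * length(a)) < pr) * 1L, n, length(a))
  colnames(X) <- config$items$label
  eps <- stats::rnorm(n)
  expenditure <- exp(config$expenditure$mu +
                       config$expenditure$lambda * theta +
                       config$expenditure$sigma * eps)
  structure(list(responses = as_response_matrix(X), theta = theta,
                 expenditure = expenditure, generating_config = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset:", length(x$theta), "households,",
      ncol(x$responses), "items\n")
  invisible(x)
}

#' Deterministic Guttman response matrix
#'
#' The error-free limit of the response model: household `h` owns item `i`
#' exactly when `theta[h] > difficulties[i]`. Every Loevinger coefficient of
#' such a matrix is 1, which makes it the canonical positive control.
#' Degenerate outputs (e.g. all-zero columns when every `theta` is below the
#' difficulties) are left to the downstream popularity check.
#'
#' @param theta numeric vector of trait values.
#' @param difficulties numeric vector of distinct item difficulties.
#' @return a plain 0/1 integer matrix (households x items).
#' @export
make_guttman <- function(theta, difficulties) {
  if (anyDuplicated(difficulties)) stop("difficulties must be distinct")
  X <- outer(theta, difficulties, ">") * 1L
  colnames(X) <- paste0("g", seq_along(difficulties))
  X
}

#' Append an item with a non-monotone (unimodal) response function
#'
#' The new item's ownership probability is `0.9 * exp(-(theta - peak)^2 /
#' (2 width^2))`: low- and high-trait households rarely own it, mid-trait
#' households often do — the canonical monotonicity violation. Original
#' items are untouched.
#'
#' @param data a `synthetic_dataset`.
#' @param peak trait level of maximum ownership probability.
#' @param width spread of the bump (> 0).
#' @param seed integer seed for the new item's draws (independent of the
#'   base data).
#' @return the dataset with one extra response column `nonmono*`.
#' @export
inject_nonmonotone_item <- function(data, peak = 0, width = 0.5, seed = 1) {
  stopifnot(inherits(data, "synthetic_dataset"), width > 0)
  set.seed(as.integer(seed))
  pr <- 0.9 * exp(-(data$theta - peak)^2 / (2 * width^2))
  newcol <- (stats::runif(length(pr)) < pr) * 1L
  X <- cbind(unclass(data$responses), newcol)
  colnames(X)[ncol(X)] <- paste0("nonmono", 1L + sum(grepl("^nonmono",
                                                      colnames(X))))
  data$responses <- as_response_matrix(X)
  data
}

#' Append a monotone item whose response function crosses the others
#'
#' Adds a 2PL item with discrimination `a_new` and difficulty `b_new`. Two
#' 2PL response functions with different discriminations cross at
#' `theta = (a_new * b_new - a * b) / (a_new - a)`; a discrimination far
#' from the pool's (at least 3x larger or smaller than the median, enforced
#' unless `require_contrast = FALSE`) puts crossings inside the observed
#' trait range and so violates invariant item ordering.
#'
#' @param data a `synthetic_dataset`.
#' @param a_new,b_new 2PL parameters of the injected item.
#' @param seed integer seed for the new item's draws.
#' @param require_contrast enforce the 3x discrimination-contrast
#'   precondition (set `FALSE` to study the parallel limit).
#' @return the dataset with one extra response column `crossing*`.
#' @export
inject_intersecting_item <- function(data, a_new = 6, b_new = 0, seed = 1,
                                     require_contrast = TRUE) {
  stopifnot(inherits(data, "synthetic_dataset"), a_new > 0)
  a_base <- stats::median(data$generating_config$items$a)
  if (require_contrast && a_new < 3 * a_base && a_new > a_base / 3) {
    stop("a_new (", a_new, ") must differ from the pool's discrimination (",
         a_base, ") by at least 3x to guarantee a crossing")
  }
  set.seed(as.integer(seed))
  pr <- stats::plogis(a_new * (data$theta - b_new))
  newcol <- (stats::runif(length(pr)) < pr) * 1L
  X <- cbind(unclass(data$responses), newcol)
  colnames(X)[ncol(X)] <- paste0("crossing", 1L + sum(grepl("^crossing",
                                                       colnames(X))))
  data$responses <- as_response_matrix(X)
  data
}

#' Simulate multiple independent trait blocks plus noise items
#'
#' Each block rides its own independent standard-normal trait; the first
#' block's trait is the `theta` driving expenditure. Noise items are
#' independent Bernoulli draws at fixed popularities. This is the generator
#' behind multi-scale structure-recovery tests and the default
#' survey-shaped fixture.
#'
#' @param n households.
#' @param blocks list of data frames with columns `a`, `b`, optional
#'   `label` (one data frame per latent trait).
#' @param noise_p popularities of trait-free noise items (possibly empty).
#' @param noise_labels optional labels for the noise items.
#' @param expenditure as in [latent_config()].
#' @param seed integer seed.
#' @return a `synthetic_dataset`; attribute `item_block` gives each item's
#'   block id (0 for noise items), in response-column order.
#' @export
simulate_blocks <- function(n, blocks, noise_p = numeric(0),
                            noise_labels = NULL,
                            expenditure = list(mu = 7, lambda = 0.525,
                                               sigma = 0.7),
                            seed = 1) {
  stopifnot(length(blocks) >= 1)
  set.seed(as.integer(seed))
  cols <- list()
  block_id <- integer(0)
  labels <- character(0)
  theta1 <- NULL
  for (bidx in seq_along(blocks)) {
    bl <- as.data.frame(blocks[[bidx]])
    th <- stats::rnorm(n)
    if (bidx == 1L) theta1 <- th
    pr <- stats::plogis(outer(th, bl$b, "-") * rep(bl$a, each = n))
    cols[[bidx]] <- matrix((stats::runif(n * nrow(bl)) < pr) * 1L, n)
    block_id <- c(block_id, rep(bidx, nrow(bl)))
    labels <- c(labels, if (!is.null(bl$label)) bl$label else
      paste0("b", bidx, "_item", seq_len(nrow(bl))))
  }
  if (length(noise_p)) {
    noise <- vapply(noise_p, function(p) (stats::runif(n) < p) * 1L,
                    integer(n))
    cols[[length(cols) + 1L]] <- noise
    block_id <- c(block_id, rep(0L, length(noise_p)))
    labels <- c(labels, if (!is.null(noise_labels)) noise_labels else
      paste0("noise", seq_along(noise_p)))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- labels
  eps <- stats::rnorm(n)
  exp_ <- exp(expenditure$mu + expenditure$lambda * theta1 +
                expenditure$sigma * eps)
  cfg <- latent_config(n, data.frame(a = unlist(lapply(blocks, function(b)
    as.data.frame(b)$a)), b = unlist(lapply(blocks, function(b)
      as.data.frame(b)$b))), expenditure, seed)
  out <- structure(list(responses = as_response_matrix(X), theta = theta1,
                        expenditure = exp_, generating_config = cfg),
                   class = "synthetic_dataset")
  attr(out, "item_block") <- block_id
  out
}

#' Default survey-shaped synthetic fixture
#'
#' Seventeen items emulating a national household asset module: twelve
#' items on the dominant wealth trait with 2PL difficulties spanning
#' popularities from roughly 90% (clock, electricity) down to 0.3%
#' (dishwasher); two items (bucket, agricultural machine) riding a second,
#' independent trait; and three trait-free noise items (bicycle, second
#' house, cars). Difficulties were chosen by inverting the quadrature
#' marginal `P(own) = E[plogis(a (theta - b))]` at the target popularity.
#'
#' @param n households (default 3810, a complete-case national sample size).
#' @param seed integer seed.
#' @return a `synthetic_dataset` (see [simulate_blocks()]).
#' @export
simulate_whs_like <- function(n = 3810, seed = 1) {
  main <- data.frame(
    label = c("clock", "electricity", "television", "motorbike", "video_dvd",
              "telephone", "refrigerator", "magazine", "washing_machine",
              "computer", "mobile_phone", "dishwasher"),
    a = c(2.0, 1.8, 2.6, 2.4, 2.3, 2.4, 2.4, 1.7, 2.1, 2.0, 2.2, 2.0),
    b = c(-1.746, -1.826, -0.953, 0.006, 0.601, 1.196, 1.269, 2.077, 2.123,
          2.206, 2.217, 3.795))
  second <- data.frame(label = c("bucket", "agricultural_machine"),
                       a = c(2.0, 2.0), b = c(-1.354, 1.872))
  simulate_blocks(n, blocks = list(main, second),
                  noise_p = c(0.84, 0.047, 0.037),
                  noise_labels = c("bicycle", "second_house", "cars"),
                  seed = seed)
}

#' Write a synthetic household table as delimited text
#'
#' Comma-separated with a header row of item labels plus `expenditure` and,
#' optionally, the true `theta` (useful only for test fixtures).
#'
#' @param data a `synthetic_dataset`.
#' @param path output file.
#' @param include_theta include the latent trait column?
#' @return `path`, invisibly.
#' @export
write_household_table <- function(data, path, include_theta = FALSE) {
  stopifnot(inherits(data, "synthetic_dataset"))
  df <- as.data.frame(unclass(data$responses))
  df$expenditure <- data$expenditure
  if (include_theta) df$theta <- data$theta
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
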