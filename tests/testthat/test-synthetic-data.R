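test_that("identical configurations reproduce bit-identical datasets", {
  cfg <- latent_config(300, data.frame(a = 2, b = c(-1, 0, 1)), seed = 99)
  d1 <- simulate_responses(cfg)
  d2 <- simulate_responses(cfg)
  expect_identical(unclass(d1$responses), unclass(d2$responses))
  expect_identical(d1$theta, d2$theta)
  expect_identical(d1$expenditure, d2$expenditure)
  expect_true(all(d1$expenditure > 0))
})

test_that("configuration invariants are enforced", {
  expect_error(latent_config(10, data.frame(a = numeric(), b = numeric())),
               "non-empty")
  expect_error(latent_config(10, data.frame(a = c(1, -1), b = c(0, 0))),
               "positive")
  expect_error(latent_config(10, data.frame(a = 1, b = 0),
                             expenditure = list(mu = 7, lambda = .5,
                                                sigma = 0)))
})

test_that("infinite discrimination reproduces the deterministic Guttman limit", {
  cfg <- latent_config(500, data.frame(a = 1e6, b = c(-1, 0, 1)), seed = 3)
  d <- simulate_responses(cfg)
  expect_identical(unname(unclass(d$responses)),
                   unname(make_guttman(d$theta, c(-1, 0, 1))))
  r <- suppressMessages(compute_scalability(d$responses))
  expect_equal(r$scale_H, 1, tolerance = 1e-12)
})

test_that("empirical popularities match the quadrature marginal", {
  k <- 11
  bs <- seq(-2.5, 2.5, length.out = k)
  d <- simulate_responses(latent_config(5000, data.frame(a = 2, b = bs),
                                        seed = 1))
  p_emp <- colMeans(d$responses)
  p_true <- vapply(bs, function(b) pop_quadrature(2, b), numeric(1))
  se <- sqrt(p_true * (1 - p_true) / 5000)
  expect_true(all(abs(p_emp - p_true) <= 3 * se))
  expect_true(all(diff(p_emp) < 0))  # popularity strictly decreasing in b
})

test_that("make_guttman evaluates the indicator and rejects tied difficulties", {
  X <- make_guttman(c(-1, 0, 1), c(-0.5, 0.5))
  expect_equal(unname(X), rbind(c(0, 0), c(1, 0), c(1, 1)))
  expect_error(make_guttman(1:3, c(0.5, 0.5)), "distinct")
  # all theta below every difficulty: degenerate all-zero matrix is caught
  # by the downstream popularity check, not here
  X0 <- make_guttman(c(-3, -4), c(0, 1))
  expect_true(all(X0 == 0))
  expect_error(as_response_matrix(X0), "constant")
})

test_that("the injected unimodal item peaks in the middle of the trait", {
  d <- rasch_fixture(n = 5000, k = 5, seed = 41, b_range = c(-2, 2))
  d2 <- inject_nonmonotone_item(d, peak = 0, width = 0.5, seed = 42)
  item <- unclass(d2$responses)[, "nonmono1"]
  terc <- cut(d2$theta, quantile(d2$theta, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  pops <- tapply(item, terc, mean)
  expect_gt(pops[2], pops[1])
  expect_gt(pops[2], pops[3])
})

test_that("the crossing injector enforces its discrimination contrast", {
  d <- rasch_fixture(n = 500, k = 5, a = 1, seed = 43, b_range = c(-1, 1))
  expect_error(inject_intersecting_item(d, a_new = 1.5, b_new = 0),
               "3x")
  # analytic crossing point with item (a = 1, b = 0.5) lies inside [-3, 3]
  a_new <- 6; b_new <- 0
  cross <- (a_new * b_new - 1 * 0.5) / (a_new - 1)
  expect_true(cross >= -3 && cross <= 3)
  d2 <- inject_intersecting_item(d, a_new = 6, b_new = 0, seed = 44)
  expect_equal(ncol(d2$responses), 6)
  # parallel limit: same a and b adds a non-crossing duplicate item
  d3 <- inject_intersecting_item(d, a_new = 1, b_new = 0, seed = 45,
                                 require_contrast = FALSE)
  out <- iterative_iio_removal(d3$responses)
  expect_equal(nrow(out$removal_log), 0)
})

test_that("the sum score recovers the latent ordering", {
  d <- rasch_fixture(n = 5000, k = 11, a = 2, seed = 1)
  total <- rowSums(unclass(d$responses))
  expect_gte(cor(total, d$theta, method = "spearman"), 0.8)
})

test_that("log expenditure correlates with the trait at the design level", {
  d <- simulate_responses(latent_config(20000,
                                        data.frame(a = 2, b = c(-0.5, 0.5)),
                                        seed = 77))
  expect_equal(cor(log(d$expenditure), d$theta), 0.6, tolerance = 0.03)
})

test_that("block simulation labels items by block and keeps traits separate", {
  d <- two_block_fixture(n = 3000, seed = 51)
  expect_equal(attr(d, "item_block"), c(rep(1L, 5), rep(2L, 5), 0L, 0L))
  X <- unclass(d$responses)
  across <- cor(rowSums(X[, 1:5]), rowSums(X[, 6:10]))
  expect_lt(abs(across), 0.1)
  # first block's trait drives expenditure
  expect_gt(cor(rowSums(X[, 1:5]), log(d$expenditure)), 0.3)
})

test_that("the survey-shaped fixture matches its design popular spectrum", {
  d <- simulate_whs_like(n = 3810, seed = 1)
  p <- colMeans(d$responses)
  expect_equal(ncol(d$responses), 17)
  expect_gt(p["clock"], 0.85)
  expect_lt(p["dishwasher"], 0.02)
  expect_gt(p["bicycle"], 0.8)
})

test_that("the table writer round-trips through the reader", {
  d <- rasch_fixture(n = 50, k = 4, seed = 61, b_range = c(-1, 1))
  f <- withr::local_tempfile(fileext = ".csv")
  write_household_table(d, f, include_theta = TRUE)
  hh <- read_households(f)
  expect_equal(unname(unclass(hh$responses)), unname(unclass(d$responses)))
  expect_equal(hh$expenditure, d$expenditure)
  expect_equal(hh$exclusion_log$rows_excluded, 0)
})
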