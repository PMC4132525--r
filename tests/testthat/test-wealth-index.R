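test_that("quintile boundaries follow the empirical CDF with shared ties", {
  # six zeros: CDF(0) = .6 covers the first three fifths, so all share q1
  q <- quintile_assign(c(0, 0, 0, 0, 0, 0, 1, 2, 3, 4))
  expect_equal(as.integer(q), c(rep(1L, 6), 4L, 4L, 5L, 5L))
  expect_equal(attr(q, "boundaries"), c(0, 0, 0, 2))
  # distinct scores split into exact fifths
  q2 <- quintile_assign(1:100)
  expect_equal(as.vector(table(q2)), rep(20L, 5))
  expect_error(quintile_assign(rep(3, 10)), "constant")
  expect_error(quintile_assign(c(1, 2)), "at least 5")
})

test_that("quintiles are monotone in the score", {
  set.seed(12)
  for (rep in 1:20) {
    s <- sample(0:11, 200, replace = TRUE)
    q <- quintile_assign(s)
    o <- order(s)
    expect_true(all(diff(q[o]) >= 0))
    for (v in unique(s)) expect_length(unique(q[s == v]), 1)
  }
})

test_that("the Mokken sum score spans 0..k with matching quintile extremes", {
  d <- rasch_fixture(n = 1000, k = 11, a = 2, seed = 5)
  X <- unclass(d$responses)
  X[1, ] <- 0L; X[2, ] <- 1L  # pin one have-nothing and one have-all household
  w <- mokken_score(as_response_matrix(X))
  expect_equal(w$score[1], 0)
  expect_equal(w$quintile[1], 1L)
  expect_equal(w$score[2], 11)
  expect_equal(w$quintile[2], 5L)
})

test_that("tetrachoric estimate matches the arcsin closed form at zero thresholds", {
  est <- tetrachoric_rho(matrix(c(40, 10, 10, 40), 2, byrow = TRUE))
  expect_equal(est$thresholds, c(0, 0))
  expect_equal(est$rho, sin(2 * pi * 0.15), tolerance = 1e-4)
  expect_true(est$converged)
  expect_equal(tetrachoric_rho(matrix(25, 2, 2))$rho, 0, tolerance = 1e-4)
  # several rho values via the orthant identity P(++) = 1/4 + asin(rho)/2pi
  for (rho in c(-0.6, -0.2, 0.3, 0.7, 0.9)) {
    p11 <- 0.25 + asin(rho) / (2 * pi)
    tab <- 1000 * matrix(c(p11, 0.5 - p11, 0.5 - p11, p11), 2, byrow = TRUE)
    expect_equal(tetrachoric_rho(tab)$rho, rho, tolerance = 1e-4)
  }
})

test_that("tetrachoric boundary behaviour: correction, clipping, zero margins", {
  expect_message(est <- tetrachoric_rho(matrix(c(50, 0, 0, 50), 2)),
                 "continuity correction")
  expect_true(est$corrected)
  expect_gt(est$rho, 0.9)
  expect_error(tetrachoric_rho(matrix(c(50, 50, 0, 0), 2, byrow = TRUE)),
               "zero margin")
})

test_that("polychoric matrix recovers model-implied correlations", {
  k <- 4
  a <- 2
  bs <- c(-1, -0.3, 0.3, 1)
  d <- simulate_responses(latent_config(5000, data.frame(a = a, b = bs),
                                        seed = 14))
  R <- polychoric_matrix(d$responses)
  expect_equal(diag(R), rep(1, k), ignore_attr = TRUE)
  expect_true(isSymmetric(R))
  # quadrature oracle: exact joint cell probabilities under the 2PL model,
  # pushed through the same latent-normal inversion
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    pj <- integrate(function(t) plogis(a * (t - bs[i])) *
                      plogis(a * (t - bs[j])) * dnorm(t), -Inf, Inf)$value
    pi_ <- pop_quadrature(a, bs[i]); pjm <- pop_quadrature(a, bs[j])
    tab <- matrix(c(pj, pi_ - pj, pjm - pj, 1 - pi_ - pjm + pj),
                  2, byrow = TRUE) * 1e4
    rho_true <- tetrachoric_rho(tab)$rho
    expect_lt(abs(R[i, j] - rho_true), 0.05)
  }
  # independent items give near-zero off-diagonals
  set.seed(3)
  Xind <- matrix(rbinom(4000, 1, 0.5), 2000, 2)
  Rind <- polychoric_matrix(as_response_matrix(Xind))
  expect_lt(abs(Rind[1, 2]), 0.08)
})

test_that("first-component analytics match closed forms", {
  pc <- pca_first_component(matrix(c(1, .6, .6, 1), 2))
  expect_equal(pc$eigenvalues, c(1.6, 0.4), tolerance = 1e-10)
  expect_equal(pc$variance_proportions, c(0.8, 0.2), tolerance = 1e-10)
  pc5 <- pca_first_component(diag(5))
  expect_equal(pc5$variance_proportions, rep(0.2, 5), tolerance = 1e-12)
  expect_error(pca_first_component(matrix(c(1, .2, .6, 1), 2)),
               "symmetric")
})

test_that("eigenvalues sum to k and loadings are sign-normalised positive", {
  d <- rasch_fixture(n = 2000, k = 6, a = 2, seed = 19,
                     b_range = c(-1.5, 1.5))
  R <- polychoric_matrix(d$responses)
  pc <- pca_first_component(R)
  expect_equal(sum(pc$eigenvalues), 6, tolerance = 1e-8)
  expect_equal(sum(pc$variance_proportions), 1, tolerance = 1e-8)
  expect_true(all(pc$loadings > 0))
})

test_that("PCA scores are centred and track the Mokken sum score", {
  d <- rasch_fixture(n = 5000, k = 11, a = 2, seed = 23)
  R <- polychoric_matrix(d$responses)
  pc <- pca_first_component(R)
  wp <- pca_scores(d$responses, pc)
  expect_equal(mean(wp$score), 0, tolerance = 1e-10)
  wm <- mokken_score(d$responses)
  expect_gt(cor(wp$score, wm$score), 0.9)
  expect_error(pca_scores(as_response_matrix(unclass(d$responses)[, 1:3]),
                          pc), "loadings length")
})
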