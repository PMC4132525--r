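test_that("pairwise H matches the hand-counted Guttman-error example", {
  # p_A = .6, p_B = .3 (B harder), F = 1, E = 10 * .3 * .4 = 1.2
  r <- compute_scalability(as_response_matrix(hand_pair_matrix()),
                           transpose = FALSE)
  expect_equal(r$pairs$F, 1)
  expect_equal(r$pairs$E, 1.2)
  expect_equal(r$pairs$H_ij, 1 - 1 / 1.2)
  expect_equal(r$pairs$harder, "item2")
})

test_that("exact two-way independence gives H = 0", {
  X <- rbind(matrix(c(1, 1), 25, 2, byrow = TRUE),
             matrix(c(1, 0), 25, 2, byrow = TRUE),
             matrix(c(0, 1), 25, 2, byrow = TRUE),
             matrix(c(0, 0), 25, 2, byrow = TRUE))
  r <- compute_scalability(as_response_matrix(X), transpose = FALSE)
  expect_equal(r$pairs$F, 25)
  expect_equal(r$pairs$E, 25)
  expect_equal(r$scale_H, 0)
})

test_that("covariance form agrees with brute-force error counting", {
  set.seed(101)
  for (rep in 1:50) {
    X <- rand_binary_matrix(sample(5:50, 1), sample(2:5, 1))
    r <- compute_scalability(as_response_matrix(X), transpose = FALSE)
    for (row in seq_len(nrow(r$pairs))) {
      i <- match(r$pairs$item_i[row], colnames(as_response_matrix(X)))
      j <- match(r$pairs$item_j[row], colnames(as_response_matrix(X)))
      expect_equal(r$pairs$H_ij[row], unname(oracle_pair_H(X, i, j)),
                   tolerance = 1e-12)
    }
    expect_equal(r$scale_H, oracle_scale_H(X), tolerance = 1e-12)
    expect_equal(unname(r$item[1, "H_i"]), oracle_item_H(X, 1),
                 tolerance = 1e-12)
  }
})

test_that("H is invariant to row permutation and item relabeling", {
  set.seed(7)
  X <- rand_binary_matrix(60, 5)
  r1 <- compute_scalability(as_response_matrix(X), transpose = FALSE)
  r2 <- compute_scalability(as_response_matrix(X[sample(60), ]),
                            transpose = FALSE)
  expect_equal(r1$scale_H, r2$scale_H)
  expect_equal(r1$item$H_i, r2$item$H_i)
  perm <- c(3, 1, 5, 2, 4)
  r3 <- compute_scalability(as_response_matrix(X[, perm]), transpose = FALSE)
  expect_equal(sort(r3$item$H_i), sort(r1$item$H_i))
  expect_equal(r3$scale_H, r1$scale_H)
})

test_that("H increases toward 1 as discrimination grows", {
  hs <- vapply(c(0.5, 1, 2, 4, 8), function(a) {
    d <- rasch_fixture(n = 3000, k = 5, a = a, seed = 3,
                       b_range = c(-1.5, 1.5))
    compute_scalability(d$responses, transpose = FALSE)$scale_H
  }, numeric(1))
  expect_true(all(diff(hs) > 0))
  expect_gt(hs[5], 0.9)
})

test_that("item popularity counts and tie-ranking follow the declared rules", {
  X <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(1, 1, 1, 0))
  st <- item_popularity(as_response_matrix(X))
  expect_equal(st$popularity, c(0.5, 0.5, 0.75))
  # c most popular; a beats b on the tie by column index
  expect_equal(st$rank, c(2L, 3L, 1L))
})

test_that("construction rejects invalid matrices", {
  expect_error(as_response_matrix(cbind(c(1, 1, 1), c(0, 1, 0))), "constant")
  expect_error(as_response_matrix(cbind(c(1, NA, 0), c(0, 1, 0))), "missing")
  expect_error(as_response_matrix(cbind(c(1, 2, 0), c(0, 1, 0))), "0/1")
  expect_error(as_response_matrix(matrix(c(0, 1), 2, 1)), "2 items")
})

test_that("strength labels follow the conventional interpretation bands", {
  expect_equal(scalability_strength(c(0.1, 0.33, 0.45, 0.74)),
               c("unscalable", "weak", "medium", "strong"))
})

test_that("transposed H matches brute-force computation and drops constant rows", {
  set.seed(42)
  X <- rand_binary_matrix(6, 4)
  X[1, ] <- c(1, 0, 1, 0)  # ensure at least one mixed row
  expect_equal(suppressMessages(transposed_H(as_response_matrix(X))),
               oracle_transposed_H(X), tolerance = 1e-12)
  # an all-ones household must be dropped with a message
  X2 <- rbind(X, rep(1L, 4))
  expect_message(transposed_H(as_response_matrix(X2)), "constant household")
  expect_equal(suppressMessages(transposed_H(as_response_matrix(X2))),
               oracle_transposed_H(X2), tolerance = 1e-12)
})

test_that("a Guttman matrix scores 1 on every coefficient", {
  g <- guttman_fixture(n = 150, k = 5, seed = 9)
  r <- suppressMessages(compute_scalability(as_response_matrix(g)))
  expect_equal(r$pairs$H_ij, rep(1, nrow(r$pairs)), tolerance = 1e-12)
  expect_equal(r$item$H_i, rep(1, 5), tolerance = 1e-12)
  expect_equal(r$scale_H, 1, tolerance = 1e-12)
  expect_equal(r$transposed_H, 1, tolerance = 1e-12)
})

test_that("bootstrap SEs are seed-reproducible and flag degenerate data", {
  d <- rasch_fixture(n = 400, k = 5, seed = 2)
  s1 <- se_item_H(d$responses, n_boot = 200, seed = 7)
  s2 <- se_item_H(d$responses, n_boot = 200, seed = 7)
  expect_identical(s1$se, s2$se)
  expect_true(all(s1$se > 0))
  # near-degenerate data: one rare response pattern, so resamples missing it
  # have constant columns and are dropped, tripping the >10% warning
  X <- rbind(matrix(rep(c(1L, 0L), each = 99), 99, 2), c(0L, 1L))
  expect_warning(suppressMessages(se_item_H(as_response_matrix(X),
                                            n_boot = 200, seed = 1)),
                 "10%")
})

test_that("bootstrap SE tracks the repeated-sampling standard deviation", {
  d <- rasch_fixture(n = 3810, k = 11, a = 2, seed = 7)
  bse <- se_item_H(d$responses, n_boot = 500, seed = 7)$se
  # oracle: SD of H_i across independently regenerated datasets
  his <- vapply(1:500, function(s) {
    ds <- rasch_fixture(n = 3810, k = 11, a = 2, seed = 10000 + s)
    compute_scalability(ds$responses, transpose = FALSE)$item$H_i
  }, numeric(11))
  true_sd <- apply(his, 1, sd)
  expect_true(all(abs(bse - true_sd) / true_sd < 0.15))
})
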