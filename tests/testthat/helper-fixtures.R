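# Shared fixtures, all generated in code under fixed seeds.

# equal-discrimination (Rasch-like, non-intersecting) 2PL fixture
rasch_fixture <- function(n = 5000, k = 11, a = 2, seed = 1,
                          b_range = c(-2.5, 2.5)) {
  simulate_responses(latent_config(
    n, data.frame(a = a, b = seq(b_range[1], b_range[2], length.out = k)),
    seed = seed))
}

# error-free Guttman matrix with difficulties strictly inside the theta range
guttman_fixture <- function(n = 200, k = 4, seed = 1) {
  set.seed(seed)
  theta <- rnorm(n)
  diffs <- quantile(theta, probs = seq(0.15, 0.85, length.out = k),
                    names = FALSE)
  diffs <- diffs + seq_len(k) * 1e-9  # guarantee distinctness
  make_guttman(theta, diffs)
}

# two independent 5-item blocks plus two pure-noise items
two_block_fixture <- function(n = 5000, seed = 11) {
  bl <- data.frame(a = rep(2, 5), b = c(-1.5, -0.75, 0, 0.75, 1.5))
  simulate_blocks(n, blocks = list(bl, bl), noise_p = c(0.5, 0.3),
                  seed = seed)
}

# tiny hand-enumerable two-item matrix: patterns (1,1)x2 (1,0)x4 (0,1)x1 (0,0)x3
hand_pair_matrix <- function() {
  rbind(matrix(c(1, 1), 2, 2, byrow = TRUE),
        matrix(c(1, 0), 4, 2, byrow = TRUE),
        matrix(c(0, 1), 1, 2, byrow = TRUE),
        matrix(c(0, 0), 3, 2, byrow = TRUE))
}
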