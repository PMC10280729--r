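test_that("sampling grids match their defining formulas", {
  # log grid: direct evaluation of the defining formula is the oracle
  n <- 161; H <- 15
  i <- seq_len(n)
  oracle <- 10^((i - 1) * log10(H + 1) / (n - 1)) - 1
  oracle[1] <- 0; oracle[n] <- H
  expect_equal(make_log_grid(n, H), oracle, tolerance = 1e-15)
  expect_equal(make_log_grid(2, 15), c(0, 15))
  expect_error(make_log_grid(1, 15))

  expect_equal(diff(make_linear_grid(81, 320)), rep(4, 80))
  expect_equal(make_linear_grid(3, 10), c(0, 5, 10))
  expect_equal(make_linear_grid(2, 7), c(0, 7))
})

test_that("MID convolution and marginals follow the combinatorial rules", {
  # delta identity
  mid2 <- c(0.2, 0.5, 0.3)
  expect_equal(mid_convolve(c(1, 0), mid2), c(mid2, 0))
  # hand-expanded one-atom pools p = 0.3, q = 0.5:
  # (1-p)(1-q), p(1-q)+q(1-p), pq
  expect_equal(mid_convolve(c(0.7, 0.3), c(0.5, 0.5)), c(0.35, 0.50, 0.15))
  # commutativity on random normalized vectors
  set.seed(42)
  for (i in 1:20) {
    a <- stats::runif(sample(2:4, 1)); a <- a / sum(a)
    b <- stats::runif(sample(2:4, 1)); b <- b / sum(b)
    expect_equal(mid_convolve(a, b), mid_convolve(b, a))
    expect_equal(sum(mid_convolve(a, b)), 1)
  }
  expect_error(mid_convolve(c(0.5, 0.1), mid2), class = "localmfa_validation_error")

  # one-atom marginal of a two-atom MID: labeled probability m1/2 + m2
  expect_equal(mid_marginal(mid2, 1), c(0.45, 0.55))
  expect_equal(mid_marginal(mid2, 2), mid2)
})

test_that("simulation matches the closed form on a two-pool chain", {
  sc <- two_pool_chain(v = 2, pool_B = 4)
  traj <- simulate_labeling(sc, make_log_grid(61, 15))
  expect_lt(max(abs(trajectory_enrichment(traj, "B") -
                      (1 - exp(-0.5 * traj$times)))), 1e-6)
})

test_that("simulated MIDs start unlabeled, stay normalized and bounded", {
  cache <- synthetic_cache()
  traj <- cache$traj
  for (m in names(traj$mids)) {
    mid <- traj$mids[[m]]
    if (!cache$sc$network$metabolites$is_source[
      cache$sc$network$metabolites$id == m]) {
      expect_equal(unname(mid[1, 1]), 1)
    }
    expect_lt(max(abs(rowSums(mid) - 1)), 1e-6)
    expect_true(all(mid >= -1e-8 & mid <= 1 + 1e-8))
  }
  # monotone enrichment in an acyclic chain with a constant source
  chain <- two_pool_chain()
  tr <- simulate_labeling(chain, make_log_grid(41, 15))
  expect_true(all(diff(trajectory_enrichment(tr, "B")) >= -1e-8))
})

test_that("zero-pool metabolites with throughput are rejected", {
  mets <- data.frame(id = c("S", "B"), n_atoms = 1L,
                     pool_size = c(NA, 1), is_source = c(TRUE, FALSE))
  net <- network(mets, list(reaction("v1", "1 S -> 1 B", "S[1] -> B[1]"),
                            reaction("v2", "1 B ->", "B[1] ->")))
  fx <- flux_distribution(data.frame(reaction_id = c("v1", "v2"),
                                     direction = "fwd", value = 2))
  sc <- scenario(net, fx, 15)
  sc$network$metabolites$pool_size[2] <- NA
  expect_error(build_odes(sc), class = "localmfa_validation_error")
})

test_that("subsampling is even in index space and keeps the endpoints", {
  cache <- synthetic_cache()
  traj <- cache$traj
  full <- subsample_trajectory(traj, length(traj$times))
  expect_setequal(unique(full$time_min), traj$times)
  two <- subsample_trajectory(traj, 2)
  expect_setequal(unique(two$time_min), range(traj$times))
  # 161 -> 81: every second grid index
  half <- subsample_trajectory(traj, 81)
  expect_equal(sort(unique(half$time_min)), traj$times[seq(1, 161, by = 2)])
  expect_error(subsample_trajectory(traj, 1))
})

test_that("noise injection is seeded, clipped, renormalized and unbiased", {
  cache <- synthetic_cache()
  ds <- subsample_trajectory(cache$traj, 11, sd = 0.01)
  expect_identical(add_noise(ds, 42)$fraction, add_noise(ds, 42)$fraction)
  expect_false(identical(add_noise(ds, 42)$fraction, add_noise(ds, 43)$fraction))
  # sd = 0 is the identity
  ds0 <- ds; ds0$sd <- 0
  expect_equal(add_noise(ds0, 1)$fraction, ds0$fraction)
  # MIDs stay normalized
  noisy <- add_noise(ds, 7)
  sums <- tapply(noisy$fraction, paste(noisy$metabolite, noisy$time_min), sum)
  expect_lt(max(abs(sums - 1)), 1e-9)

  # empirical spread of a balanced two-class record: renormalization
  # projects out the common noise mode, so the delta-method standard
  # deviation is sd / sqrt(2)
  rec <- labeling_dataset(data.frame(
    metabolite = "A", time_min = 1, mass_shift = c(0, 1),
    fraction = c(0.5, 0.5), sd = 0.01))
  draws <- vapply(seq_len(10000), function(s)
    add_noise(rec, s)$fraction[2], numeric(1))
  expect_equal(stats::sd(draws), 0.01 / sqrt(2), tolerance = 0.05)
})
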