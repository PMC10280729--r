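# Whole-process Monte-Carlo sensitivity analysis.

kfp_chain_pipeline <- function(pool_B = 4) {
  fit <- function(ds, seed) NULL  # instant-labeling input, nothing to fit
  estimate <- function(ds, inputs, seed) {
    series <- dataset_unlabeled(ds, "B")
    res <- kfp_estimate(series, "instant", pool = pool_B)
    data.frame(reaction = "v1", direction = "fwd", estimate = res$flux)
  }
  list(fit = fit, estimate = estimate)
}

test_that("quantile summaries are order statistics of the replicates", {
  d <- summarize_distribution(c(3, 1, 5, 2, 4), level = 0.8)
  # order-statistic oracle: sorted[ceil(0.1 n)] and sorted[ceil(0.9 n)]
  expect_equal(d$ci_low, 1)
  expect_equal(d$ci_high, 5)
  expect_equal(d$median, 3)
  expect_true(d$ci_low <= d$median && d$median <= d$ci_high)
  # level 1 gives the range; constant replicates give width zero
  r <- summarize_distribution(c(2, 9, 4), level = 1)
  expect_equal(c(r$ci_low, r$ci_high), c(2, 9))
  const <- summarize_distribution(rep(1.5, 10), level = 0.95)
  expect_equal(const$ci_high - const$ci_low, 0)
  expect_error(summarize_distribution(1), class = "localmfa_validation_error")
})

test_that("monte_carlo is deterministic, seed-sensitive and parallel-invariant", {
  sc <- two_pool_chain()
  ds <- subsample_trajectory(simulate_labeling(sc, make_log_grid(41, 15)),
                             11, sd = 0.01)
  p <- kfp_chain_pipeline()
  a <- monte_carlo(p$fit, p$estimate, ds, n_reps = 8, rng_seed = 5)
  b <- monte_carlo(p$fit, p$estimate, ds, n_reps = 8, rng_seed = 5)
  expect_identical(a, b)
  c2 <- monte_carlo(p$fit, p$estimate, ds, n_reps = 8, rng_seed = 6)
  expect_false(identical(a[["v1:fwd"]]$replicates, c2[["v1:fwd"]]$replicates))
  par2 <- monte_carlo(p$fit, p$estimate, ds, n_reps = 8, rng_seed = 5,
                      parallel = 2)
  expect_equal(a, par2)
})

test_that("zero measurement noise collapses the interval", {
  sc <- two_pool_chain()
  ds <- subsample_trajectory(simulate_labeling(sc, make_log_grid(41, 15)),
                             11, sd = 0)
  p <- kfp_chain_pipeline()
  d <- monte_carlo(p$fit, p$estimate, ds, n_reps = 5, rng_seed = 1)[["v1:fwd"]]
  expect_equal(d$ci_high - d$ci_low, 0)
  expect_equal(length(unique(d$replicates)), 1)
})

test_that("the 95% interval covers the true chain flux", {
  sc <- two_pool_chain(v = 2, pool_B = 4)
  ds <- subsample_trajectory(simulate_labeling(sc, make_log_grid(41, 15)),
                             21, sd = 0.01)
  p <- kfp_chain_pipeline()
  d <- monte_carlo(p$fit, p$estimate, ds, n_reps = 100, rng_seed = 11)[["v1:fwd"]]
  expect_true(d$ci_low <= 2 && 2 <= d$ci_high)
})

test_that("replicate failures are recorded, and an excess is fatal", {
  sc <- two_pool_chain()
  ds <- subsample_trajectory(simulate_labeling(sc, make_log_grid(41, 15)),
                             11, sd = 0.01)
  flaky_calls <- 0
  flaky <- function(ds, inputs, seed) {
    flaky_calls <<- flaky_calls + 1
    if (flaky_calls %% 3 == 0) stop("sporadic failure")
    data.frame(reaction = "v1", direction = "fwd", estimate = 1)
  }
  d <- monte_carlo(function(ds, s) NULL, flaky, ds, n_reps = 9, rng_seed = 1)
  expect_equal(d[["v1:fwd"]]$n_failed, 3)
  always_fail <- function(ds, inputs, seed) stop("no")
  expect_error(monte_carlo(function(ds, s) NULL, always_fail, ds,
                           n_reps = 4, rng_seed = 1),
               class = "localmfa_monte_carlo_error")
})

test_that("coupling relations propagate replicate-wise to intervals", {
  dists <- list(
    "r3:fwd" = summarize_distribution(c(1.0, 1.2, 0.9, 1.1)),
    "r8:fwd" = summarize_distribution(c(0.5, 0.6, 0.4, 0.5)))
  coefs <- list("r7:fwd" = c("r3:fwd" = 1, "r8:fwd" = 0),
                "x:fwd" = c("r3:fwd" = 1, "r8:fwd" = -1))
  out <- propagate_coupled(dists, coefs)
  expect_equal(out[["r7:fwd"]]$replicates, dists[["r3:fwd"]]$replicates)
  expect_equal(out[["x:fwd"]]$replicates, c(0.5, 0.6, 0.5, 0.6))
  expect_true(out[["x:fwd"]]$ci_low <= out[["x:fwd"]]$median)
})
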