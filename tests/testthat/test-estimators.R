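# KFP, NSMFRA, and the coupled-flux post-processor.

test_that("KFP recovers the chain turnover and flux from simulated data", {
  sc <- two_pool_chain(v = 2, pool_B = 4)
  traj <- simulate_labeling(sc, make_log_grid(41, 15))
  series <- data.frame(time_min = traj$times,
                       unlabeled = traj$mids$B[, 1])
  res <- kfp_estimate(series, "instant", pool = 4)
  expect_equal(res$k, 0.5, tolerance = 1e-4)
  expect_equal(res$flux, 2, tolerance = 1e-4)
  expect_lt(res$rho, 1e-4)
  # flux reported only when a pool is supplied
  expect_true(is.na(kfp_estimate(series, "instant")$flux))
})

test_that("KFP rejects non-decaying series", {
  flat <- data.frame(time_min = 0:10, unlabeled = rep(1, 11))
  expect_error(kfp_estimate(flat), class = "localmfa_kfp_not_applicable")
})

test_that("KFP analytic solution equals numeric integration of the motif ODE", {
  set.seed(99)
  t <- make_log_grid(31, 15)
  worst <- 0
  for (i in 1:30) {
    k <- 10^stats::runif(1, -1, 1)
    rho <- stats::runif(1, 0, 0.9)
    a <- 10^stats::runif(1, -1, 1)
    c0 <- stats::runif(1, 0, 0.3)
    c1 <- stats::runif(1, 0, 1 - c0)
    inp <- list(c0 = c0, c1 = c1, a = a)
    ana <- kfp_unlabeled(t, k, rho, inp)
    rhs <- function(tt, y, p)
      list(k * (rho + (1 - rho) * (c0 + c1 * exp(-a * tt)) - y))
    num <- deSolve::ode(1, t, rhs, NULL, method = "lsoda",
                        rtol = 1e-11, atol = 1e-13)[, 2]
    worst <- max(worst, max(abs(ana - num)))
  }
  expect_lt(worst, 1e-8)
})

test_that("NSMFRA recovers the flux ratio of a converging motif", {
  sc <- converging_motif(v1 = 2, v2 = 1)
  ds <- as_labeling_dataset(simulate_labeling(sc, make_log_grid(81, 15)), sd = 0)
  zd <- ds[ds$metabolite == "Z", ]
  xs <- ds[ds$metabolite == "X", ]
  ys <- ds[ds$metabolite == "Y", ]
  res <- nsmfra_estimate(zd, list(xs, ys), P_Z = 1.5, rng_seed = 3)
  expect_equal(res$ratio, 2 / 3, tolerance = 0.01)
  expect_equal(res$v1, 2, tolerance = 0.05)
  expect_equal(res$v2, 1, tolerance = 0.05)
  expect_equal(res$turnover, 2, tolerance = 0.02)

  # without P_Z only ratio and turnover are identifiable, and both are
  # invariant under a common rescaling of the pool
  rel <- nsmfra_estimate(zd, list(xs, ys), rng_seed = 3)
  expect_true(is.na(rel$v1))
  expect_equal(rel$ratio, res$ratio, tolerance = 1e-6)
  doubled <- nsmfra_estimate(zd, list(xs, ys), P_Z = 3, rng_seed = 3)
  expect_equal(doubled$ratio, res$ratio, tolerance = 1e-3)
  expect_equal(doubled$turnover, res$turnover, tolerance = 1e-3)
  expect_equal(doubled$v1, 2 * res$v1, tolerance = 0.05)
})

test_that("NSMFRA handles a dead branch and flags the boundary", {
  sc <- converging_motif(v1 = 2, v2 = 0)
  ds <- as_labeling_dataset(simulate_labeling(sc, make_log_grid(61, 15)), sd = 0)
  res <- nsmfra_estimate(ds[ds$metabolite == "Z", ],
                         list(ds[ds$metabolite == "X", ],
                              ds[ds$metabolite == "Y", ]),
                         P_Z = 1.5, rng_seed = 3)
  expect_equal(res$ratio, 1, tolerance = 1e-3)
  expect_true(res$boundary)
})

test_that("NSMFRA refuses pointwise-identical branch inputs", {
  sc <- converging_motif(v1 = 2, v2 = 1)
  ds <- as_labeling_dataset(simulate_labeling(sc, make_log_grid(41, 15)), sd = 0)
  xs <- ds[ds$metabolite == "X", ]
  expect_error(nsmfra_estimate(ds[ds$metabolite == "Z", ], list(xs, xs),
                               P_Z = 1.5),
               class = "localmfa_unidentifiable_error")
})

test_that("a condensation branch convolves its two substrate inputs", {
  # constant enrichments p = 0.3 and q = 0.5: the branch MID is the
  # hand-expanded convolution (0.35, 0.50, 0.15)
  const_fit <- function(level) {
    structure(list(kind = "logistic",
                   params = c(A = level, K = level, r = 1, t0 = 1),
                   sse = 0, n_starts_used = 0, diagnostics = list()),
              class = "input_fit")
  }
  f <- localmfa:::branch_mid_fun(list(const_fit(0.3), const_fit(0.5)), 3)
  expect_equal(drop(f(5)), c(0.35, 0.50, 0.15))
})

test_that("coupled fluxes are derived from stoichiometry, with errors otherwise", {
  sc <- build_synthetic_scenario()
  known <- data.frame(reaction = "r3", direction = "fwd", estimate = 1.0)
  aug <- infer_coupled_fluxes(known, sc$network, "r7")
  expect_equal(aug$estimate[aug$reaction == "r7"], 1.0)

  # node balance: v6_bwd = v7 + v6_fwd - v8
  known2 <- data.frame(reaction = c("r7", "r6", "r8"),
                       direction = c("fwd", "fwd", "fwd"),
                       estimate = c(1.0, 0.4, 0.9))
  aug2 <- infer_coupled_fluxes(known2, sc$network, "r6:bwd")
  expect_equal(aug2$estimate[aug2$direction == "bwd"], 0.5)
  coefs <- attr(aug2, "coupling_coefficients")[["r6:bwd"]]
  expect_equal(unname(coefs[c("r7:fwd", "r6:fwd", "r8:fwd")]), c(1, 1, -1))

  # r1 is not derivable from r14 alone
  expect_error(
    infer_coupled_fluxes(data.frame(reaction = "r14", direction = "fwd",
                                    estimate = 0.5), sc$network, "r1"),
    class = "localmfa_coupling_error")
})
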