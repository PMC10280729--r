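test_that("free-flux parameterization reflects the enclosed stoichiometry", {
  sc <- build_synthetic_scenario()
  ds <- subsample_trajectory(synthetic_cache()$traj, 21, sd = 0)
  # single reaction: one free flux
  s1 <- build_subsystem(sc$network, "r2", "A", list(A = dataset_mid_fun(ds, "A")))
  expect_length(s1$free_idx, 1)
  # r3/r7 are fully coupled through G: still one free flux
  s2 <- build_subsystem(sc$network, c("r3", "r7"), "H",
                        list(H = dataset_mid_fun(ds, "H")))
  expect_length(s2$free_idx, 1)
  v <- s2$map_theta(1.3)
  expect_equal(v[s2$flow_keys == "r3:fwd"], v[s2$flow_keys == "r7:fwd"])
  # an uncovered external feed is an error
  expect_error(build_subsystem(sc$network, "r2", character(0), list()),
               class = "localmfa_missing_input_error")
  expect_error(build_subsystem(sc$network, "r2", "A", list()),
               class = "localmfa_missing_input_error")
})

test_that("estimation is self-consistent on data from its own forward model", {
  sc <- build_synthetic_scenario()
  input <- structure(list(kind = "logistic",
                          params = c(A = 0, K = 1, r = 1.5, t0 = 1.2),
                          sse = 0, n_starts_used = 0, diagnostics = list()),
                     class = "input_fit")
  sub <- build_subsystem(sc$network, "r2", "A", list(A = input))
  times <- make_log_grid(41, 15)
  truth <- 2
  sim <- localmfa:::simulate_subsystem(sub, truth, times)
  ds <- labeling_dataset(data.frame(
    metabolite = "B", time_min = rep(times, 2),
    mass_shift = rep(0:1, each = length(times)),
    fraction = c(sim$B[, 1], sim$B[, 2]), sd = 0.01))
  est <- subsystem_estimate(sub, ds, rng_seed = 5)
  expect_lt(abs(est$estimate[1] - truth) / truth, 1e-3)
  expect_true(est$converged[1])
})

test_that("a zero-flux subsystem is estimated at zero", {
  sc <- build_synthetic_scenario()
  input <- structure(list(kind = "logistic",
                          params = c(A = 0, K = 1, r = 1.5, t0 = 1.2),
                          sse = 0, n_starts_used = 0, diagnostics = list()),
                     class = "input_fit")
  sub <- build_subsystem(sc$network, "r2", "A", list(A = input))
  times <- make_log_grid(21, 15)
  # product stays unlabeled: the only consistent flux is zero
  ds <- labeling_dataset(data.frame(
    metabolite = "B", time_min = rep(times, 2),
    mass_shift = rep(0:1, each = length(times)),
    fraction = rep(c(1, 0), each = length(times)), sd = 0.01))
  est <- subsystem_estimate(sub, ds, rng_seed = 5)
  expect_lt(est$estimate[1], 1e-3)
})

test_that("fast feed-forward solver agrees with stiff integration", {
  sc <- build_synthetic_scenario()
  ds <- subsample_trajectory(synthetic_cache()$traj, 41, sd = 0)
  fits <- list(C = dataset_mid_fun(ds, "C"), G = dataset_mid_fun(ds, "G"))
  sub <- build_subsystem(sc$network, c("r6", "r7", "r8"), c("C", "G"), fits)
  expect_equal(sub$topo, c("D", "L"))
  times <- sort(unique(ds$time_min))
  v <- c(0.8, 0.3, 0.5, 1.0)
  fast <- localmfa:::simulate_subsystem_fast(sub, v, times)
  slow_sub <- sub; slow_sub$topo <- NULL
  slow <- localmfa:::simulate_subsystem(slow_sub, v, times, rtol = 1e-9,
                                        atol = 1e-11)
  expect_lt(max(abs(fast$D - slow$D)), 1e-4)
  expect_lt(max(abs(fast$L - slow$L)), 1e-4)
})

test_that("condensation subsystems estimate through the convolution path", {
  sc <- build_synthetic_scenario()
  ds <- subsample_trajectory(synthetic_cache()$traj, 41, sd = 0)
  fits <- list(I = dataset_mid_fun(ds, "I"), J = dataset_mid_fun(ds, "J"))
  sub <- build_subsystem(sc$network, "r12", c("I", "J"), fits)
  est <- subsystem_estimate(sub, ds[ds$metabolite == "H", ], rng_seed = 2)
  expect_lt(abs(est$estimate[1] - 1.0), 0.02)
})
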