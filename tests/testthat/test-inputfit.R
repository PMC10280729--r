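test_that("input-function forms evaluate as defined", {
  t <- seq(0, 15, by = 0.5)
  # a double logistic with the second term off reproduces a logistic
  lg <- c(A = 0.05, K = 0.9, r = 1.2, t0 = 4)
  dl <- c(A = 0.05, B1 = 0.85, r1 = 1.2, t01 = 4, B2 = 0, r2 = 1, t02 = 7)
  expect_equal(eval_input("double_logistic", dl, t), eval_input("logistic", lg, t))
  # logistic midpoint at t0
  expect_equal(eval_input("logistic", lg, 4), (0.05 + 0.9) / 2)
  # reversed exponential decay saturates at its plateau
  expect_equal(eval_input("rev_exp_decay", c(b = 0, P = 0.8, k = 50), 15), 0.8,
               tolerance = 1e-12)
  expect_error(eval_input("logistic", c(1, 2), t), class = "localmfa_validation_error")
  expect_error(eval_input("nope", c(1, 2, 3), t), class = "localmfa_reference_error")
})

test_that("multi-start PSO self-fits noiseless curves and is deterministic", {
  t <- make_log_grid(21, 15)
  y <- eval_input("logistic", c(0.02, 0.95, 1.3, 2.5), t)
  f1 <- fit_input(data.frame(time = t, enrichment = y), "logistic",
                  n_starts = 10, rng_seed = 7)
  expect_lt(f1$sse, 1e-8)
  f2 <- fit_input(data.frame(time = t, enrichment = y), "logistic",
                  n_starts = 10, rng_seed = 7)
  expect_identical(f1$params, f2$params)
  # recomputing the SSE from the stored parameters reproduces the field
  expect_equal(sum((eval_input(f1$kind, f1$params, t) - y)^2), f1$sse,
               tolerance = 1e-9)
  expect_error(fit_input(data.frame(time = t[1:4], enrichment = y[1:4]),
                         "logistic"),
               class = "localmfa_underdetermined_error")
})

test_that("near-step data produce a step-like diagnostic flag", {
  # a jump between two densely spaced early points needs a rate beyond the
  # bound, so the fitted rate pins there and is flagged
  t <- make_log_grid(21, 15)
  y <- as.numeric(t > 0.04)
  f <- fit_input(data.frame(time = t, enrichment = y), "logistic",
                 n_starts = 4, rng_seed = 1)
  expect_true(f$diagnostics$step_like)
})

test_that("selection guarantees the nested-model SSE bound", {
  cache <- synthetic_cache()
  ds <- subsample_trajectory(cache$traj, 21)
  for (seed in c(3, 11)) {
    noisy <- add_noise(ds, seed)
    for (m in c("M", "O")) {
      sel <- select_input(dataset_enrichment(noisy, m), n_starts = 4,
                          rng_seed = seed, control = list(n_iter = 80))
      fits <- attr(sel, "all_fits")
      expect_lte(fits$double_logistic$sse, fits$logistic$sse)
    }
  }
})

test_that("selection prefers the simplest kind on degenerate data and drops under-determined kinds", {
  t <- make_log_grid(21, 15)
  zero <- data.frame(time = t, enrichment = numeric(21))
  sel <- select_input(zero, n_starts = 3, rng_seed = 1,
                      control = list(n_iter = 50))
  expect_equal(sel$kind, "logistic")
  expect_equal(sel$sse, 0, tolerance = 1e-12)

  # 6 points cannot determine the 7-parameter double logistic
  six <- data.frame(time = make_log_grid(6, 15),
                    enrichment = eval_input("logistic", c(0, 0.9, 1, 2),
                                            make_log_grid(6, 15)))
  sel6 <- select_input(six, n_starts = 3, rng_seed = 1,
                       control = list(n_iter = 50))
  expect_equal(sel6$kind, "logistic")
  expect_named(attr(sel6, "all_fits"), "logistic")
})

test_that("reversed exponential decay fits delayed pools worse than a logistic", {
  cache <- synthetic_cache()
  ds <- subsample_trajectory(cache$traj, 21, sd = 0)
  # K labels late; its sigmoid delay cannot be captured without a center
  d <- dataset_enrichment(ds, "K")
  fl <- fit_input(d, "logistic", n_starts = 6, rng_seed = 2)
  fr <- fit_input(d, "rev_exp_decay", n_starts = 6, rng_seed = 2)
  expect_gt(fr$sse, 2 * fl$sse)
})

test_that("the kind registry is extensible", {
  register_input_kind(
    "linear_ramp", 2L, c("a", "b"),
    bounds = function(horizon) list(lower = c(0, 0), upper = c(1.2, 1)),
    eval_matrix = function(par, t)
      pmin(par[, 1] + outer(par[, 2], t), 1))
  expect_true("linear_ramp" %in% input_kinds())
  t <- 0:10
  y <- pmin(0.1 + 0.05 * t, 1)
  f <- fit_input(data.frame(time = t, enrichment = y), "linear_ramp",
                 n_starts = 4, rng_seed = 1)
  expect_lt(f$sse, 1e-6)
})
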