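# Kinetic flux profiling (KFP).
#
# KFP estimates the total flux through a metabolite B from the decay of its
# unlabeled (M+0) fraction. For the basic motif — B produced from a
# substrate A whose unlabeled fraction decays, plus an unlabeled recycle
# flux (e.g. macromolecule degradation) — the ODE
#   dB_U/dt = k [ rho + (1 - rho) A_U(t) - B_U ],   k = v_total / P_B,
#   rho = v_recycle / v_total
# has a closed-form solution for A_U(t) = c0 + c1 exp(-a t) (the unlabeled
# complement of a reversed-exponential-decay enrichment input):
#   B_U(t) = rho + (1-rho) c0 + (1-rho) c1 k/(k-a) exp(-a t) + C exp(-k t)
# with C fixed by B_U(0) = 1. Instant labeling (A_U = 0) reduces this to
# B_U(t) = rho + (1-rho) exp(-k t). The fit is nonlinear least squares on
# the analytic form; no ODE integration is involved.

#' Closed-form unlabeled fraction for the KFP motif
#'
#' @param t times (minutes).
#' @param k turnover rate (1/min).
#' @param rho recycle fraction in `[0, 1]`.
#' @param input `"instant"` for a fully labeled substrate from t = 0, or a
#'   list `list(c0=, c1=, a=)` describing the substrate's unlabeled fraction
#'   `c0 + c1 exp(-a t)`.
#' @return unlabeled fraction of the product at `t`.
#' @export
kfp_unlabeled <- function(t, k, rho, input = "instant") {
  if (identical(input, "instant")) {
    return(rho + (1 - rho) * exp(-k * t))
  }
  c0 <- input$c0; c1 <- input$c1; a <- input$a
  base <- rho + (1 - rho) * c0
  if (abs(k - a) < 1e-9 * max(k, a, 1)) {
    # confluent limit k -> a
    return(base + (1 - rho) * c1 * k * t * exp(-k * t) + (1 - base) * exp(-k * t))
  }
  g <- (1 - rho) * c1 * k / (k - a)
  base + g * exp(-a * t) + (1 - base - g) * exp(-k * t)
}

input_fit_as_kfp_input <- function(input_fn) {
  if (identical(input_fn, "instant")) return("instant")
  if (inherits(input_fn, "input_fit")) {
    if (input_fn$kind != "rev_exp_decay") {
      stop_localmfa(paste0(
        "kfp_estimate supports 'instant' or a rev_exp_decay input function; ",
        "got kind '", input_fn$kind, "'"), "localmfa_validation_error")
    }
    p <- input_fn$params
    # enrichment b + (P-b)(1-e^{-kt})  =>  unlabeled (1-P) + (P-b) e^{-kt}
    return(list(c0 = unname(1 - p["P"]), c1 = unname(p["P"] - p["b"]),
                a = unname(p["k"])))
  }
  if (is.list(input_fn) && all(c("c0", "c1", "a") %in% names(input_fn))) {
    return(input_fn)
  }
  stop_localmfa("unsupported KFP input specification", "localmfa_validation_error")
}

#' Estimate flux by kinetic flux profiling
#'
#' Fits the closed-form KFP solution to the product's unlabeled-fraction
#' time series by bounded Levenberg-Marquardt least squares with multiple
#' starts.
#'
#' @param product_series data.frame with columns `time_min` (or `time`/`t`)
#'   and `unlabeled` (M+0 fraction), starting at 1 at t = 0.
#' @param input_fn `"instant"`, a `rev_exp_decay` [fit_input()] result for
#'   the substrate's enrichment, or `list(c0=, c1=, a=)`.
#' @param pool pool size of the product; if supplied the absolute flux
#'   `k * pool` is reported.
#' @param u0_tol tolerance for the unlabeled fraction at t = 0.
#' @return object of class `kfp_result`: `k` (1/min), `rho`, `flux`
#'   (`k * pool`, `NA` without a pool), `sse`, `converged` (`FALSE` when `k`
#'   sits at a bound).
#' @export
kfp_estimate <- function(product_series, input_fn = "instant", pool = NULL,
                         u0_tol = 0.05) {
  tcol <- intersect(c("time_min", "time", "t"), names(product_series))[1]
  assert_that(!is.na(tcol) && "unlabeled" %in% names(product_series),
              "product_series needs time and unlabeled columns")
  t <- product_series[[tcol]]
  u <- product_series$unlabeled
  assert_that(all(u >= -1e-9 & u <= 1 + 1e-9), "unlabeled fractions must lie in [0,1]")
  if (any(t == 0) && abs(u[which.min(t)] - 1) > u0_tol) {
    stop_localmfa("unlabeled fraction at t = 0 is not 1", "localmfa_validation_error")
  }
  slope <- stats::coef(stats::lm(u ~ t))[2]
  if (slope >= -1e-10) {
    stop_localmfa("series does not decay: KFP is not applicable",
                  "localmfa_kfp_not_applicable")
  }
  input <- input_fit_as_kfp_input(input_fn)
  resid_fn <- function(par) kfp_unlabeled(t, par[1], par[2], input) - u
  lower <- c(1e-4, 0); upper <- c(1e3, 1)
  starts <- expand.grid(k = c(0.05, 0.5, 5, 50), rho = c(0, 0.3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = as.numeric(starts[i, ]), lower = lower,
                         upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(out)) next
    sse <- sum(resid_fn(out$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = out$par, sse = sse)
  }
  if (is.null(best)) {
    stop_localmfa("KFP fit failed for all starts", "localmfa_estimation_error")
  }
  k <- best$par[1]; rho <- best$par[2]
  at_bound <- k <= lower[1] * 1.01 || k >= upper[1] * 0.99
  if (at_bound) warning("KFP rate estimate at parameter bound; flagged as non-converged")
  structure(list(k = k, rho = rho,
                 flux = if (!is.null(pool)) k * pool else NA_real_,
                 pool = pool, sse = best$sse, converged = !at_bound),
            class = "kfp_result")
}

#' @export
print.kfp_result <- function(x, ...) {
  cat(sprintf("<kfp_result> k = %.4g /min, rho = %.3g, flux = %s, sse = %.3g%s\n",
              x$k, x$rho,
              if (is.na(x$flux)) "(no pool given)" else sprintf("%.4g", x$flux),
              x$sse, if (!x$converged) " [at bound]" else ""))
  invisible(x)
}

#' Unlabeled-fraction series of one metabolite from a labeling dataset
#'
#' @param ds a `labeling_dataset`.
#' @param metabolite metabolite id.
#' @return data.frame with columns `time_min`, `unlabeled` (the M+0
#'   fraction).
#' @export
dataset_unlabeled <- function(ds, metabolite) {
  d <- ds[ds$metabolite == metabolite & ds$mass_shift == 0, ]
  assert_that(nrow(d) > 0, sprintf("no M+0 records for '%s'", metabolite))
  data.frame(time_min = d$time_min, unlabeled = d$fraction)[order(d$time_min), ]
}
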