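# Nonstationary metabolic flux ratio analysis (NSMFRA) at converging nodes.
#
# For two reactions with fluxes v1, v2 converging on a junction metabolite
# Z with pool P_Z, every mass class m obeys
#   d(Z_m)/dt = (1/P_Z) [ v1 X_m(t) + v2 Y_m(t) - (v1 + v2) Z_m ].
# Only the ratio v1/(v1+v2) and the turnover (v1+v2)/P_Z are identifiable
# from Z's MID dynamics; absolute fluxes additionally require P_Z. A
# converging branch may itself be a condensation, in which case its
# transferred MID is the convolution of its two substrate inputs.

branch_mid_fun <- function(input, n_classes) {
  if (inherits(input, "input_fit")) {
    f <- input
    return(function(t) {
      e <- pmin(pmax(predict(f, t), 0), 1)
      cbind(1 - e, e)
    })
  }
  if (is.list(input) && length(input) == 2 &&
      all(vapply(input, inherits, logical(1), "input_fit"))) {
    f1 <- input[[1]]; f2 <- input[[2]]
    return(function(t) {
      e1 <- pmin(pmax(predict(f1, t), 0), 1)
      e2 <- pmin(pmax(predict(f2, t), 0), 1)
      # condensation branch: convolution of two one-atom MIDs
      cbind((1 - e1) * (1 - e2), e1 * (1 - e2) + e2 * (1 - e1), e1 * e2)
    })
  }
  if (is.data.frame(input)) {
    assert_that(all(c("time_min", "mass_shift", "fraction") %in% names(input)),
                "MID series input needs time_min, mass_shift, fraction")
    shifts <- sort(unique(input$mass_shift))
    tmax <- max(input$time_min)
    funs <- lapply(shifts, function(s) {
      d <- input[input$mass_shift == s, ]
      d <- d[order(d$time_min), ]
      # shape-preserving spline; constant extrapolation beyond the data
      sf <- stats::splinefun(d$time_min, d$fraction, method = "monoH.FC")
      last <- d$fraction[nrow(d)]; first <- d$fraction[1]; t0 <- d$time_min[1]
      function(t) {
        y <- sf(pmin(pmax(t, t0), tmax))
        pmin(pmax(y, 0), 1)
      }
    })
    return(function(t) do.call(cbind, lapply(funs, function(f) f(t))))
  }
  if (is.function(input)) return(input)
  stop_localmfa("unsupported branch input specification", "localmfa_validation_error")
}

#' Interpolating MID input from measured data
#'
#' Returns a `function(t)` interpolating a metabolite's measured MID, for
#' use as a branch input in [nsmfra_estimate()] or as a fitted input in
#' [build_subsystem()]. With noiseless data this is an exact input
#' representation; with noisy data an analytic [fit_input()] curve is
#' preferable.
#'
#' @param ds a `labeling_dataset`.
#' @param metabolite metabolite id.
#' @return function mapping times to a MID matrix.
#' @export
dataset_mid_fun <- function(ds, metabolite) {
  d <- ds[ds$metabolite == metabolite, c("time_min", "mass_shift", "fraction")]
  assert_that(nrow(d) > 0, sprintf("no records for '%s'", metabolite))
  branch_mid_fun(d, length(unique(d$mass_shift)))
}

#' Estimate a flux ratio at a converging node (NSMFRA)
#'
#' Fits the junction metabolite's MID dynamics, integrated from the
#' converging-motif ODE with the two branch inputs as forcing functions, by
#' bounded multi-start Levenberg-Marquardt least squares over all mass
#' classes.
#'
#' @param junction_data data.frame with columns `time_min`, `mass_shift`,
#'   `fraction` for the junction metabolite Z (a [labeling_dataset()] subset
#'   works).
#' @param branch_inputs list of two branch inputs, each one of: an
#'   [fit_input()] result (one-atom enrichment), a list of two such results
#'   (condensation branch, convolved), a long-format MID data.frame
#'   (interpolated), or a `function(t)` returning a MID matrix.
#' @param P_Z pool size of Z; with it, absolute `v1`, `v2` are reported,
#'   without it only ratio and turnover.
#' @param n_starts number of optimizer starts (log-uniform in flux or
#'   turnover, uniform in ratio).
#' @param rng_seed integer seed for the starts.
#' @param v_max upper flux bound.
#' @return object of class `nsmfra_result`: `v1`, `v2` (NA without `P_Z`),
#'   `ratio` = v1/(v1+v2), `turnover` = (v1+v2)/P_Z (1/min), `sse`,
#'   `converged`, `boundary` (TRUE when an estimate sits at 0 or at the
#'   bound).
#' @export
nsmfra_estimate <- function(junction_data, branch_inputs, P_Z = NULL,
                            n_starts = 5L, rng_seed = 1L, v_max = 1e3) {
  assert_that(length(branch_inputs) == 2, "exactly two branch inputs required")
  d <- junction_data[order(junction_data$time_min, junction_data$mass_shift), ]
  times <- sort(unique(d$time_min))
  shifts <- sort(unique(d$mass_shift))
  n_cl <- length(shifts)
  zmat <- matrix(d$fraction, nrow = length(times), ncol = n_cl, byrow = TRUE)
  xf <- branch_mid_fun(branch_inputs[[1]], n_cl)
  yf <- branch_mid_fun(branch_inputs[[2]], n_cl)
  probe <- seq(min(times), max(times), length.out = 101)
  if (max(abs(xf(probe) - yf(probe))) < 1e-6) {
    stop_localmfa("branch inputs are pointwise identical: ratio unidentifiable",
                  "localmfa_unidentifiable_error")
  }
  sim_times <- if (times[1] > 0) c(0, times) else times
  keep <- match(times, sim_times)
  z0 <- c(1, numeric(n_cl - 1))
  simulate_motif <- function(ratio, turnover) {
    rhs <- function(t, y, p) {
      list(turnover * (ratio * drop(xf(t)) + (1 - ratio) * drop(yf(t)) - y))
    }
    sol <- tryCatch(
      deSolve::ode(z0, sim_times, rhs, NULL, method = "lsoda",
                   rtol = 1e-8, atol = 1e-10),
      error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < length(sim_times)) return(NULL)
    unname(as.matrix(sol[keep, -1, drop = FALSE]))
  }
  with_pool <- !is.null(P_Z)
  resid_fn <- function(par) {
    if (with_pool) {
      v1 <- par[1]; v2 <- par[2]; tot <- v1 + v2
      if (tot <= 1e-12) return(rep(1e3, length(zmat)))
      ratio <- v1 / tot; turnover <- tot / P_Z
    } else {
      ratio <- par[1]; turnover <- par[2]
    }
    sim <- simulate_motif(ratio, turnover)
    if (is.null(sim)) return(rep(1e3, length(zmat)))
    as.vector(sim - zmat)
  }
  if (with_pool) {
    lower <- c(0, 0); upper <- c(v_max, v_max)
    starts <- with_seed(rng_seed, cbind(10^stats::runif(n_starts, -2, 2),
                                        10^stats::runif(n_starts, -2, 2)))
  } else {
    lower <- c(0, 1e-4); upper <- c(1, 1e3)
    starts <- with_seed(rng_seed, cbind(stats::runif(n_starts),
                                        10^stats::runif(n_starts, -2, 2)))
  }
  best <- NULL
  for (i in seq_len(n_starts)) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 100, epsfcn = 1e-8)),
      error = function(e) NULL)
    if (is.null(out)) next
    sse <- sum(resid_fn(out$par)^2)
    if (is.null(best) || sse < best$sse) best <- list(par = out$par, sse = sse)
  }
  if (is.null(best)) {
    stop_localmfa("NSMFRA fit failed for all starts", "localmfa_estimation_error")
  }
  if (with_pool) {
    v1 <- best$par[1]; v2 <- best$par[2]
    ratio <- v1 / (v1 + v2); turnover <- (v1 + v2) / P_Z
    at_vmax <- any(c(v1, v2) >= 0.99 * v_max)
  } else {
    v1 <- NA_real_; v2 <- NA_real_
    ratio <- best$par[1]; turnover <- best$par[2]
    at_vmax <- turnover >= 0.99 * 1e3
  }
  # a branch estimated at (effectively) zero flux is a boundary solution
  boundary <- at_vmax || ratio <= 1e-4 || ratio >= 1 - 1e-4
  structure(list(v1 = v1, v2 = v2, ratio = ratio, turnover = turnover,
                 sse = best$sse, converged = !boundary, boundary = boundary),
            class = "nsmfra_result")
}

#' @export
print.nsmfra_result <- function(x, ...) {
  cat(sprintf("<nsmfra_result> ratio = %.4g, turnover = %.4g /min%s, sse = %.3g%s\n",
              x$ratio, x$turnover,
              if (!is.na(x$v1)) sprintf(", v1 = %.4g, v2 = %.4g", x$v1, x$v2) else "",
              x$sse, if (x$boundary) " [boundary]" else ""))
  invisible(x)
}
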