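# Whole-process Monte-Carlo sensitivity analysis.
#
# Confidence intervals are obtained by repeating the estimation on data
# with freshly drawn measurement noise. Unlike the upstream default — which
# keeps the label-input fits from the original data and repeats only the
# estimation step — the whole process, including the input fitting, is
# repeated for every replicate (`refit_inputs = TRUE`), so that input-fit
# uncertainty propagates into the intervals. Replicate seeds are derived
# once from the master seed, so serial and parallel execution agree.

#' Monte-Carlo sensitivity analysis of a two-stage estimation pipeline
#'
#' @param fit_stage `function(dataset, rng_seed)` fitting the label inputs;
#'   returns an opaque object passed on to `estimate_stage`.
#' @param estimate_stage `function(dataset, inputs, rng_seed)` returning a
#'   data.frame with columns `reaction`, `direction` (optional, default
#'   `"fwd"`), `estimate`.
#' @param base_data `labeling_dataset` with per-record standard deviations;
#'   each replicate adds fresh noise via [add_noise()].
#' @param n_reps number of noise replicates (the benchmark default is 100).
#' @param rng_seed master seed.
#' @param refit_inputs repeat the input fitting for every replicate (the
#'   whole-process scheme); `FALSE` reproduces the estimation-only scheme,
#'   fitting inputs once on `base_data`.
#' @param level confidence level for the quantile intervals.
#' @param parallel number of worker processes (forked); 1 = serial. Results
#'   are identical either way.
#' @return named list of `estimate_distribution` objects (one per flow key
#'   `reaction:direction`): `replicates`, `median`, `ci_low`, `ci_high`,
#'   `level`, `n_failed`.
#' @export
monte_carlo <- function(fit_stage, estimate_stage, base_data, n_reps = 100L,
                        rng_seed = 1L, refit_inputs = TRUE, level = 0.95,
                        parallel = 1L) {
  assert_that(n_reps >= 2, "n_reps must be >= 2")
  seeds <- derive_seeds(rng_seed, n_reps)
  inputs0 <- if (!refit_inputs) fit_stage(base_data, rng_seed) else NULL
  run_rep <- function(i) {
    tryCatch({
      noisy <- add_noise(base_data, seeds[i])
      inputs <- if (refit_inputs) fit_stage(noisy, seeds[i]) else inputs0
      est <- estimate_stage(noisy, inputs, seeds[i])
      if (is.null(est$direction)) est$direction <- "fwd"
      est[, c("reaction", "direction", "estimate")]
    }, error = function(e) e)
  }
  reps <- if (parallel > 1L) {
    parallel::mclapply(seq_len(n_reps), run_rep, mc.cores = parallel,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(n_reps), run_rep)
  }
  failed <- vapply(reps, inherits, logical(1), "error")
  if (mean(failed) > 0.5) {
    stop_localmfa(sprintf(
      "more than half of the replicates failed (%d/%d); first error: %s",
      sum(failed), n_reps, conditionMessage(reps[[which(failed)[1]]])),
      "localmfa_monte_carlo_error")
  }
  ok <- reps[!failed]
  keys <- unique(unlist(lapply(ok, function(d) paste(d$reaction, d$direction, sep = ":"))))
  out <- lapply(keys, function(k) {
    vals <- vapply(ok, function(d) {
      i <- which(paste(d$reaction, d$direction, sep = ":") == k)
      if (length(i) == 1) d$estimate[i] else NA_real_
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    dist <- structure(list(key = k, replicates = vals, level = level,
                           n_failed = sum(failed)),
                      class = "estimate_distribution")
    summarize_distribution(dist, level)
  })
  stats::setNames(out, keys)
}

#' Summarize a replicate distribution into a confidence interval
#'
#' The interval bounds are empirical quantiles computed as order statistics
#' (`type = 1`), at probabilities `(1-level)/2` and `1-(1-level)/2`;
#' `level = 1` gives the replicate range.
#'
#' @param dist an `estimate_distribution` (or a bare numeric vector of
#'   replicates).
#' @param level confidence level in `(0, 1]`.
#' @return the `estimate_distribution` with `median`, `ci_low`, `ci_high`,
#'   `level` filled in.
#' @export
summarize_distribution <- function(dist, level = 0.95) {
  if (is.numeric(dist)) {
    dist <- structure(list(key = "", replicates = dist, n_failed = 0L),
                      class = "estimate_distribution")
  }
  assert_that(length(dist$replicates) >= 2,
              "need at least two successful replicates")
  assert_that(level > 0 && level <= 1, "level must be in (0, 1]")
  alpha <- (1 - level) / 2
  q <- stats::quantile(dist$replicates, c(alpha, 1 - alpha), type = 1,
                       names = FALSE)
  dist$median <- stats::median(dist$replicates)
  dist$ci_low <- q[1]
  dist$ci_high <- q[2]
  dist$level <- level
  dist
}

#' @export
print.estimate_distribution <- function(x, ...) {
  cat(sprintf("<estimate_distribution> %s: median %.4g, %g%% CI [%.4g, %.4g], %d reps%s\n",
              x$key, x$median, 100 * x$level, x$ci_low, x$ci_high,
              length(x$replicates),
              if (x$n_failed > 0) sprintf(" (%d failed)", x$n_failed) else ""))
  invisible(x)
}

#' Propagate coupling relations through replicate distributions
#'
#' Applies the linear combinations returned by [infer_coupled_fluxes()] to
#' each Monte-Carlo replicate, yielding distributions (and hence CIs) for
#' the inferred fluxes.
#'
#' @param dists named list of `estimate_distribution` (keys
#'   `reaction:direction`).
#' @param coefficients the `coupling_coefficients` attribute of
#'   [infer_coupled_fluxes()] output.
#' @param level confidence level.
#' @return `dists` extended with one entry per inferred flow.
#' @export
propagate_coupled <- function(dists, coefficients, level = 0.95) {
  for (key in names(coefficients)) {
    x <- coefficients[[key]]
    used <- names(x)[x != 0]
    missing <- setdiff(used, names(dists))
    assert_that(length(missing) == 0,
                sprintf("no replicate distribution for %s", paste(missing, collapse = ", ")))
    n <- min(vapply(dists[used], function(d) length(d$replicates), integer(1)))
    vals <- rowSums(vapply(used, function(k) x[[k]] * dists[[k]]$replicates[seq_len(n)],
                           numeric(n)))
    dist <- structure(list(key = key, replicates = vals, n_failed = 0L),
                      class = "estimate_distribution")
    dists[[key]] <- summarize_distribution(dist, level)
  }
  dists
}
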