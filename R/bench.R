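# Benchmark runner: three local estimators x time-point counts x noise
# replicates on a scenario, with motif eligibility derived from the
# stoichiometry.

producing_flows <- function(net, met) {
  flows <- network_flows(net)
  which(vapply(flows, function(f) !is.na(f$stoich[met]) && f$stoich[met] > 0,
               logical(1)))
}

#' Reactions eligible for KFP
#'
#' KFP estimates the total flux through a metabolite, which equals a
#' reaction flux only when the metabolite has that reaction as its sole
#' producer. Eligibility additionally requires a single substrate (the
#' basic KFP motif), so condensations are excluded.
#'
#' @param net an `mfa_network`.
#' @return data.frame with columns `reaction`, `product`, `substrate`.
#' @export
kfp_eligible_reactions <- function(net) {
  flows <- network_flows(net)
  rows <- list()
  for (i in seq_along(flows)) {
    f <- flows[[i]]
    if (f$direction != "fwd") next
    r <- get_reaction(net, f$reaction_id)
    if (r$reversible) next
    subs <- names(f$stoich)[f$stoich < 0]
    prods <- names(f$stoich)[f$stoich > 0]
    if (length(subs) != 1 || length(prods) == 0) next
    sole <- prods[vapply(prods, function(p) length(producing_flows(net, p)) == 1,
                         logical(1))]
    if (length(sole) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      reaction = f$reaction_id, product = sole[1], substrate = subs)
  }
  do.call(rbind, rows)
}

#' Converging-reaction junctions eligible for NSMFRA
#'
#' A junction is a non-source metabolite produced by exactly two flows,
#' both forward flows of irreversible reactions.
#'
#' @param net an `mfa_network`.
#' @return data.frame with columns `junction`, `reaction_1`, `reaction_2`,
#'   `input_1`, `input_2` (the branch substrates).
#' @export
nsmfra_junctions <- function(net) {
  flows <- network_flows(net)
  rows <- list()
  for (met in net$metabolites$id[!net$metabolites$is_source]) {
    pf <- producing_flows(net, met)
    if (length(pf) != 2) next
    ok <- all(vapply(pf, function(i) {
      flows[[i]]$direction == "fwd" && !get_reaction(net, flows[[i]]$reaction_id)$reversible
    }, logical(1)))
    if (!ok) next
    subs <- lapply(pf, function(i) names(flows[[i]]$stoich)[flows[[i]]$stoich < 0])
    if (any(lengths(subs) != 1)) next  # condensation branches need explicit setup
    rows[[length(rows) + 1L]] <- data.frame(
      junction = met,
      reaction_1 = flows[[pf[1]]]$reaction_id,
      reaction_2 = flows[[pf[2]]]$reaction_id,
      input_1 = subs[[1]], input_2 = subs[[2]])
  }
  do.call(rbind, rows)
}

#' Subsystem decomposition of a network for per-reaction estimation
#'
#' Builds the list of local subsystems the benchmark estimates: one
#' single-reaction subsystem per sole-produced product, one junction
#' subsystem per two-producer metabolite, and one cluster around each
#' reversible reaction (the reversible reaction plus every reaction
#' touching its exchange metabolite). Boundary efflux reactions carry no
#' labeling information and are skipped.
#'
#' @param net an `mfa_network`.
#' @return list of plans: each with `reactions`, `targets` (measured
#'   internal metabolites), `inputs` (boundary metabolites).
#' @export
subsystem_plan <- function(net) {
  flows <- network_flows(net)
  plans <- list()
  covered <- character(0)
  junc <- nsmfra_junctions(net)
  if (!is.null(junc)) for (i in seq_len(nrow(junc))) {
    rids <- c(junc$reaction_1[i], junc$reaction_2[i])
    plans[[length(plans) + 1L]] <- list(
      type = "junction", reactions = rids, targets = junc$junction[i],
      inputs = unique(c(junc$input_1[i], junc$input_2[i])))
    covered <- c(covered, rids)
  }
  for (r in net$reactions) {
    if (!r$reversible) next
    # cluster: the reversible exchange plus everything touching the
    # metabolite it shares with other producers
    ends <- names(r$stoich)
    for (end in ends[r$stoich > 0]) {
      touching <- unique(vapply(
        Filter(function(f) end %in% names(f$stoich), flows),
        function(f) f$reaction_id, character(1)))
      rids <- unique(c(r$id, touching))
      sub_flows <- Filter(function(f) f$reaction_id %in% rids, flows)
      produced <- unique(unlist(lapply(sub_flows, function(f)
        names(f$stoich)[f$stoich > 0])))
      substrates <- unique(unlist(lapply(sub_flows, function(f)
        names(f$stoich)[f$stoich < 0])))
      inputs <- unique(c(setdiff(substrates, setdiff(produced, substrates)),
                         character(0)))
      inputs <- setdiff(inputs, end)
      targets <- setdiff(produced, inputs)
      plans[[length(plans) + 1L]] <- list(
        type = "cluster", reactions = rids, targets = targets, inputs = inputs)
      covered <- c(covered, rids)
    }
  }
  for (i in seq_along(flows)) {
    f <- flows[[i]]
    if (f$direction != "fwd") next
    if (f$reaction_id %in% covered) next
    prods <- names(f$stoich)[f$stoich > 0]
    if (length(prods) == 0) next  # boundary efflux
    sole <- prods[vapply(prods, function(p) length(producing_flows(net, p)) == 1,
                         logical(1))]
    if (length(sole) == 0) next
    plans[[length(plans) + 1L]] <- list(
      type = "single", reactions = f$reaction_id, targets = sole,
      inputs = names(f$stoich)[f$stoich < 0])
    covered <- c(covered, f$reaction_id)
  }
  plans
}

scenario_pools <- function(sc) {
  stats::setNames(sc$network$metabolites$pool_size, sc$network$metabolites$id)
}

source_constant_mid <- function(sc, met) sc$source_mid[[met]]

fit_inputs_for <- function(sc, ds, mets, rng_seed, n_starts, fit_control,
                           input_mode) {
  sources <- sc$network$metabolites$id[sc$network$metabolites$is_source]
  fits <- list()
  seeds <- derive_seeds(rng_seed, max(length(mets), 1L))
  for (i in seq_along(mets)) {
    m <- mets[i]
    fits[[m]] <- if (m %in% sources) {
      source_constant_mid(sc, m)
    } else if (input_mode == "interpolated") {
      dataset_mid_fun(ds, m)
    } else {
      select_input(dataset_enrichment(ds, m), n_starts = n_starts,
                   rng_seed = seeds[i], control = fit_control)
    }
  }
  fits
}

#' Method pipelines for a scenario
#'
#' Construct the `fit_stage`/`estimate_stage` pair used by [monte_carlo()]
#' and [run_benchmark()] for one method.
#'
#' @param sc an `mfa_scenario`.
#' @param method `"kfp"`, `"nsmfra"` or `"subsystem"`.
#' @param reactions restrict to these reaction ids (default: all eligible).
#' @param n_starts starts for input fitting (PSO) and estimation (NLS).
#' @param fit_control PSO control list, see [fit_input()].
#' @param estimate_control control list for [subsystem_estimate()].
#' @param input_mode `"fitted"` (analytic input functions, the standard
#'   whole-process pipeline) or `"interpolated"` (shape-preserving splines
#'   through the measured MIDs; exact for noiseless data).
#' @return list with `fit_stage`, `estimate_stage`, and the eligibility
#'   table used.
#' @export
method_pipeline <- function(sc, method = c("kfp", "nsmfra", "subsystem"),
                            reactions = NULL, n_starts = 5L,
                            fit_control = list(), estimate_control = list(),
                            input_mode = c("fitted", "interpolated")) {
  method <- match.arg(method)
  input_mode <- match.arg(input_mode)
  net <- sc$network
  pools <- scenario_pools(sc)
  sources <- net$metabolites$id[net$metabolites$is_source]

  if (method == "kfp") {
    elig <- kfp_eligible_reactions(net)
    if (!is.null(reactions)) elig <- elig[elig$reaction %in% reactions, ]
    assert_that(nrow(elig) > 0, "no KFP-eligible reactions selected")
    need <- setdiff(unique(elig$substrate), sources)
    fit_stage <- function(ds, rng_seed) {
      seeds <- derive_seeds(rng_seed, max(length(need), 1L))
      fits <- list()
      for (i in seq_along(need)) {
        fits[[need[i]]] <- fit_input(dataset_enrichment(ds, need[i]),
                                     "rev_exp_decay", n_starts = n_starts,
                                     rng_seed = seeds[i], control = fit_control)
      }
      fits
    }
    estimate_stage <- function(ds, inputs, rng_seed) {
      rows <- list()
      for (i in seq_len(nrow(elig))) {
        sub <- elig$substrate[i]
        input_fn <- if (sub %in% sources) {
          e_src <- sum(source_constant_mid(sc, sub) *
                         (seq_along(source_constant_mid(sc, sub)) - 1)) /
            (length(source_constant_mid(sc, sub)) - 1)
          if (e_src >= 1 - 1e-12) "instant" else list(c0 = 1 - e_src, c1 = 0, a = 1)
        } else inputs[[sub]]
        series <- dataset_unlabeled(ds, elig$product[i])
        res <- kfp_estimate(series, input_fn, pool = pools[[elig$product[i]]])
        rows[[i]] <- data.frame(reaction = elig$reaction[i], direction = "fwd",
                                estimate = res$flux, sse = res$sse,
                                converged = res$converged)
      }
      do.call(rbind, rows)
    }
    return(list(fit_stage = fit_stage, estimate_stage = estimate_stage,
                eligible = elig, method = "kfp"))
  }

  if (method == "nsmfra") {
    junc <- nsmfra_junctions(net)
    if (!is.null(reactions)) {
      junc <- junc[junc$reaction_1 %in% reactions | junc$reaction_2 %in% reactions, ]
    }
    assert_that(!is.null(junc) && nrow(junc) > 0, "no NSMFRA-eligible junctions selected")
    need <- setdiff(unique(c(junc$input_1, junc$input_2)), sources)
    fit_stage <- function(ds, rng_seed) {
      fit_inputs_for(sc, ds, need, rng_seed, n_starts, fit_control, input_mode)
    }
    estimate_stage <- function(ds, inputs, rng_seed) {
      rows <- list()
      for (i in seq_len(nrow(junc))) {
        branch <- function(m) {
          if (m %in% sources) {
            mid <- source_constant_mid(sc, m); function(t) mid
          } else inputs[[m]]
        }
        zd <- ds[ds$metabolite == junc$junction[i], ]
        res <- nsmfra_estimate(zd, list(branch(junc$input_1[i]), branch(junc$input_2[i])),
                               P_Z = pools[[junc$junction[i]]],
                               n_starts = n_starts, rng_seed = rng_seed)
        rows[[length(rows) + 1L]] <- data.frame(
          reaction = c(junc$reaction_1[i], junc$reaction_2[i]),
          direction = "fwd", estimate = c(res$v1, res$v2),
          sse = res$sse, converged = res$converged)
      }
      do.call(rbind, rows)
    }
    return(list(fit_stage = fit_stage, estimate_stage = estimate_stage,
                eligible = junc, method = "nsmfra"))
  }

  plans <- subsystem_plan(net)
  if (!is.null(reactions)) {
    plans <- Filter(function(p) any(p$reactions %in% reactions), plans)
  }
  assert_that(length(plans) > 0, "no subsystem plans selected")
  need <- setdiff(unique(unlist(lapply(plans, `[[`, "inputs"))), sources)
  fit_stage <- function(ds, rng_seed) {
    fit_inputs_for(sc, ds, need, rng_seed, n_starts, fit_control, input_mode)
  }
  estimate_stage <- function(ds, inputs, rng_seed) {
    all_inputs <- inputs
    for (s in sources) all_inputs[[s]] <- source_constant_mid(sc, s)
    rows <- list()
    seeds <- derive_seeds(rng_seed, length(plans))
    for (i in seq_along(plans)) {
      p <- plans[[i]]
      sub <- build_subsystem(net, p$reactions, p$inputs, all_inputs[p$inputs])
      est <- subsystem_estimate(sub, ds[ds$metabolite %in% p$targets, ],
                                n_starts = n_starts, rng_seed = seeds[i],
                                control = estimate_control)
      est$plan <- p$type
      rows[[i]] <- est
    }
    out <- do.call(rbind, rows)
    # a reaction may appear in several plans; keep the best-fitting estimate
    key <- paste(out$reaction, out$direction)
    out <- out[order(key, out$sse), ]
    out[!duplicated(paste(out$reaction, out$direction)), ]
  }
  list(fit_stage = fit_stage, estimate_stage = estimate_stage,
       eligible = plans, method = "subsystem")
}

#' Run the benchmark: methods x time-point counts x noise replicates
#'
#' Simulates the scenario once on a dense grid, subsamples it to each
#' requested number of time points, and runs the whole-process Monte-Carlo
#' sensitivity analysis per (method, count) cell. Deterministic for a fixed
#' master seed.
#'
#' @param sc an `mfa_scenario`.
#' @param methods subset of `c("kfp", "nsmfra", "subsystem")`.
#' @param timepoint_counts numbers of measurement time points.
#' @param n_reps noise replicates per cell.
#' @param sd measurement standard deviation attached to every record.
#' @param master_seed master seed.
#' @param grid dense sampling grid (default: the 161-point log grid over
#'   the scenario horizon).
#' @param reactions optional reaction filter passed to [method_pipeline()].
#' @param level confidence level.
#' @param ... further arguments to [method_pipeline()].
#' @return data.frame of class `benchmark_report`, one row per (method,
#'   reaction, direction, count): median estimate, CI, true flux,
#'   `true_in_ci`, `rel_error_median`; replicate tables in attribute
#'   `replicates`.
#' @export
run_benchmark <- function(sc, methods = c("kfp", "nsmfra", "subsystem"),
                          timepoint_counts = c(6, 11, 21, 81), n_reps = 100L,
                          sd = 0.01, master_seed = 1L, grid = NULL,
                          reactions = NULL, level = 0.95, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  grid <- grid %||% make_log_grid(161, sc$horizon)
  traj <- simulate_labeling(sc, grid)
  true <- stats::setNames(
    sc$fluxes$value, paste(sc$fluxes$reaction_id, sc$fluxes$direction, sep = ":"))
  cells <- expand.grid(method = methods, count = timepoint_counts,
                       stringsAsFactors = FALSE)
  cell_seeds <- derive_seeds(master_seed, nrow(cells))
  rows <- list(); replicates <- list()
  for (ci in seq_len(nrow(cells))) {
    method <- cells$method[ci]; count <- cells$count[ci]
    ds <- subsample_trajectory(traj, count, sd = sd)
    pipe <- tryCatch(method_pipeline(sc, method, reactions = reactions, ...),
                     localmfa_validation_error = function(e) {
                       message(sprintf("skipping %s at %d points: %s",
                                       method, count, conditionMessage(e)))
                       NULL
                     })
    if (is.null(pipe)) next
    dists <- monte_carlo(pipe$fit_stage, pipe$estimate_stage, ds,
                         n_reps = n_reps, rng_seed = cell_seeds[ci],
                         refit_inputs = TRUE, level = level)
    for (key in names(dists)) {
      d <- dists[[key]]
      tv <- if (key %in% names(true)) true[[key]] else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$description, method = method,
        reaction = sub(":.*$", "", key),
        direction = sub("^.*:", "", key),
        n_timepoints = count, n_reps = length(d$replicates),
        median = d$median, ci_low = d$ci_low, ci_high = d$ci_high,
        true_flux = tv,
        true_in_ci = !is.na(tv) && tv >= d$ci_low && tv <= d$ci_high,
        rel_error_median = if (!is.na(tv) && tv > 0) abs(d$median - tv) / tv else NA_real_)
      replicates[[length(replicates) + 1L]] <- data.frame(
        method = method, n_timepoints = count, flow = key,
        rep = seq_along(d$replicates), estimate = d$replicates)
    }
  }
  report <- do.call(rbind, rows)
  attr(report, "replicates") <- do.call(rbind, replicates)
  class(report) <- c("benchmark_report", "data.frame")
  report
}

#' Write a benchmark report to CSV files
#'
#' Writes `summary.csv` (one row per method/reaction/count) and
#' `replicates.csv` (every Monte-Carlo estimate). Re-reading `summary.csv`
#' reproduces the in-memory report.
#'
#' @param report a `benchmark_report`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  assert_that(nrow(report) > 0, "empty benchmark report")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summary_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(as.data.frame(report), summary_path, row.names = FALSE)
  paths <- summary_path
  reps <- attr(report, "replicates")
  if (!is.null(reps)) {
    rep_path <- file.path(out_dir, "replicates.csv")
    utils::write.csv(reps, rep_path, row.names = FALSE)
    paths <- c(paths, rep_path)
  }
  invisible(paths)
}

#' Read back a benchmark summary written by [write_report()]
#'
#' @param out_dir directory passed to [write_report()].
#' @return the summary as a `benchmark_report` (without replicates).
#' @export
read_report <- function(out_dir) {
  report <- utils::read.csv(file.path(out_dir, "summary.csv"),
                            stringsAsFactors = FALSE)
  class(report) <- c("benchmark_report", "data.frame")
  report
}

#' Plot estimates against time-point counts
#'
#' One panel per reaction: median and CI versus the number of time points,
#' with the true flux as a horizontal line. Cosmetic companion to the CSV
#' contract.
#'
#' @param report a `benchmark_report`.
#' @param reactions which reactions to show (default all).
#' @export
plot_benchmark <- function(report, reactions = NULL) {
  reactions <- reactions %||% unique(report$reaction)
  n <- length(reactions)
  mfrow <- c(ceiling(n / 4), min(n, 4))
  op <- graphics::par(mfrow = mfrow, mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (r in reactions) {
    d <- report[report$reaction == r, ]
    ylim <- range(c(d$ci_low, d$ci_high, d$true_flux), na.rm = TRUE)
    graphics::plot(d$n_timepoints, d$median, log = "x", ylim = ylim,
                   xlab = "time points", ylab = "flux", main = r, pch = 19)
    graphics::arrows(d$n_timepoints, d$ci_low, d$n_timepoints, d$ci_high,
                     angle = 90, code = 3, length = 0.03)
    graphics::abline(h = d$true_flux[1], lty = 2)
  }
  invisible(report)
}
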