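# Forward simulation of MID dynamics.
#
# For each non-source metabolite Z with pool P_Z the MID obeys
#   d(MID_Z)/dt = (1/P_Z) [ sum_j v_j * MID_transferred_j - (sum_c v_c) * MID_Z ]
# where producing flows transfer the MID of the atoms they move:
# unimolecular transfers pass the substrate MID through, condensations
# convolve the substrate MIDs, and cleavages pass the marginal MID of the
# inherited atom subset (within-mass-class equidistribution closure).

# ---------------------------------------------------------------------------
# Time grids

#' Logarithmically spaced sampling grid
#'
#' `t_i = 10^((i-1) * log10(horizon + 1) / (n_points - 1)) - 1`, so the grid
#' starts at 0, ends exactly at the horizon, and concentrates points near
#' the start where labeling dynamics are fastest. With 161 points over a
#' 15-minute horizon the second point falls ~1 second after the start and
#' the second-to-last ~16 seconds before the end.
#'
#' @param n_points number of points (>= 2).
#' @param horizon last time point, minutes.
#' @return increasing numeric vector of times.
#' @export
make_log_grid <- function(n_points, horizon) {
  assert_that(n_points >= 2, "n_points must be >= 2")
  assert_that(horizon > 0, "horizon must be positive")
  i <- seq_len(n_points)
  t <- 10^((i - 1) * log10(horizon + 1) / (n_points - 1)) - 1
  t[1] <- 0
  t[n_points] <- horizon
  t
}

#' Equidistant sampling grid
#'
#' @inheritParams make_log_grid
#' @return increasing numeric vector including 0 and `horizon`.
#' @export
make_linear_grid <- function(n_points, horizon) {
  assert_that(n_points >= 2, "n_points must be >= 2")
  assert_that(horizon > 0, "horizon must be positive")
  seq(0, horizon, length.out = n_points)
}

# ---------------------------------------------------------------------------
# MID algebra

#' Convolve two mass isotopomer distributions
#'
#' The MID of a condensation product: `(a (*) b)_k = sum_j a_j b_(k-j)`.
#'
#' @param a,b normalized MID vectors (mass shifts 0..n).
#' @param tol normalization tolerance for the inputs.
#' @return MID vector of length `length(a) + length(b) - 1`.
#' @export
mid_convolve <- function(a, b, tol = 1e-6) {
  if (abs(sum(a) - 1) > tol || abs(sum(b) - 1) > tol) {
    stop_localmfa("mid_convolve: inputs must be normalized MIDs",
                  "localmfa_validation_error")
  }
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (j in seq_along(a)) {
    idx <- j:(j + length(b) - 1L)
    out[idx] <- out[idx] + a[j] * b
  }
  out
}

#' Marginal MID of an atom subset
#'
#' Given the MID of an `n`-atom metabolite, returns the MID of a `k`-atom
#' subset under the assumption that, within each mass class, all positional
#' isotopomers are equally likely (hypergeometric thinning). Exact whenever
#' the positions are exchangeable; for cleavage reactions this is the
#' MID-level closure used throughout the simulator.
#'
#' @param mid MID vector of the parent (length `n + 1`).
#' @param k subset size (`1 <= k <= n`).
#' @return MID vector of length `k + 1`.
#' @export
mid_marginal <- function(mid, k) {
  n <- length(mid) - 1L
  assert_that(k >= 1 && k <= n, "subset size out of range")
  if (k == n) return(mid)
  out <- numeric(k + 1L)
  for (m in 0:n) {
    if (mid[m + 1L] == 0) next
    j <- max(0L, k - (n - m)):min(k, m)
    out[j + 1L] <- out[j + 1L] +
      mid[m + 1L] * stats::dhyper(j, m, n - m, k)
  }
  out
}

# ---------------------------------------------------------------------------
# ODE system assembly

#' Assemble the labeling ODE system for a scenario
#'
#' Builds the state layout (one MID block per non-source metabolite), the
#' per-metabolite production terms (with atom-map-aware MID transfer), and
#' the right-hand-side function used by the integrator. The state dimension
#' is the sum of `n_atoms + 1` over non-source metabolites.
#'
#' @param sc an `mfa_scenario`.
#' @return list of class `mfa_odesystem` with elements `layout` (named list
#'   of state index vectors), `y0`, `rhs` (function of `(t, y, parms)`), and
#'   `dimension`.
#' @export
build_odes <- function(sc) {
  net <- sc$network
  mets <- net$metabolites
  flows <- network_flows(net)
  vals <- flow_values(net, sc$fluxes)

  dyn_ids <- mets$id[!mets$is_source]
  n_atoms <- stats::setNames(mets$n_atoms, mets$id)
  pools <- stats::setNames(mets$pool_size, mets$id)

  layout <- list(); pos <- 0L
  for (m in dyn_ids) {
    layout[[m]] <- pos + seq_len(n_atoms[[m]] + 1L)
    pos <- pos + n_atoms[[m]] + 1L
  }
  dimension <- pos

  # Per dynamic metabolite: production terms and total consumption flux.
  # A production term holds the flux value and a recipe for the transferred
  # MID: for each substrate, how many atom slots of the product it supplies.
  terms <- lapply(dyn_ids, function(z) {
    prod_terms <- list()
    cons <- 0
    for (i in seq_along(flows)) {
      f <- flows[[i]]
      s <- f$stoich[z]
      if (!is.na(s) && s < 0) cons <- cons - s * vals[i]
      if (is.na(s) || s <= 0) next
      if (vals[i] == 0) next
      am <- f$atom_map[f$atom_map$prod_id == z, , drop = FALSE]
      if (nrow(am) != n_atoms[[z]]) {
        stop_localmfa(sprintf("flow %s does not map all atoms of '%s'",
                              flow_key(flows)[i], z), "localmfa_atom_conservation_error")
      }
      counts <- table(am$sub_id)
      prod_terms[[length(prod_terms) + 1L]] <- list(
        v = s * vals[i],
        parts = lapply(names(counts), function(sb) {
          list(sub = sb, k = as.integer(counts[[sb]]),
               n = as.integer(n_atoms[[sb]]))
        }))
    }
    throughput <- max(cons, sum(vapply(prod_terms, `[[`, numeric(1), "v")))
    if (throughput > 0 && (is.na(pools[[z]]) || pools[[z]] <= 0)) {
      stop_localmfa(sprintf("metabolite '%s' has nonzero throughput but no positive pool", z),
                    "localmfa_validation_error")
    }
    list(id = z, prod = prod_terms, cons = cons, pool = pools[[z]])
  })
  names(terms) <- dyn_ids

  source_mid <- sc$source_mid
  get_mid <- function(y, id) {
    if (!is.null(layout[[id]])) y[layout[[id]]] else source_mid[[id]]
  }

  rhs <- function(t, y, parms) {
    dy <- numeric(dimension)
    for (tm in terms) {
      idx <- layout[[tm$id]]
      z <- y[idx]
      acc <- numeric(length(idx))
      for (p in tm$prod) {
        mid <- NULL
        for (part in p$parts) {
          sub_mid <- get_mid(y, part$sub)
          piece <- if (part$k == part$n) sub_mid else mid_marginal(sub_mid, part$k)
          mid <- if (is.null(mid)) piece else {
            # unchecked convolution: solver states can drift slightly
            n <- length(mid) + length(piece) - 1L
            out <- numeric(n)
            for (j in seq_along(mid)) {
              jj <- j:(j + length(piece) - 1L)
              out[jj] <- out[jj] + mid[j] * piece
            }
            out
          }
        }
        acc <- acc + p$v * mid
      }
      dy[idx] <- (acc - tm$cons * z) / tm$pool
    }
    list(dy)
  }

  y0 <- numeric(dimension)
  for (m in dyn_ids) y0[layout[[m]][1]] <- 1  # unlabeled start: M+0 = 1

  structure(list(layout = layout, y0 = y0, rhs = rhs, dimension = dimension,
                 dynamic_ids = dyn_ids, n_atoms = n_atoms,
                 source_mid = source_mid),
            class = "mfa_odesystem")
}

# ---------------------------------------------------------------------------
# Simulation

#' Simulate labeling dynamics
#'
#' Integrates the MID ODE system with a stiff-capable solver (lsoda,
#' relative tolerance 1e-8, absolute 1e-10). All non-source metabolites
#' start unlabeled; source MIDs are held fixed.
#'
#' @param sc an `mfa_scenario`.
#' @param grid output time grid (within `[0, horizon]`, starting at 0).
#' @param rtol,atol integrator tolerances.
#' @return object of class `mfa_trajectory`: list with `times` and `mids`, a
#'   named list of time-by-mass-shift matrices (sources included as constant
#'   rows).
#' @export
simulate_labeling <- function(sc, grid, rtol = 1e-8, atol = 1e-10) {
  assert_that(all(diff(grid) > 0) && grid[1] >= 0,
              "grid must be strictly increasing and nonnegative")
  assert_that(max(grid) <= sc$horizon + 1e-9, "grid exceeds the scenario horizon")
  sys <- build_odes(sc)
  times <- if (grid[1] > 0) c(0, grid) else grid
  sol <- deSolve::ode(y = sys$y0, times = times, func = sys$rhs, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0) {
    stop_localmfa(sprintf("ODE integration failed (istate = %d)", diagn[1]),
                  "localmfa_integration_error")
  }
  keep <- match(grid, times)
  y <- unname(as.matrix(sol[keep, -1, drop = FALSE]))
  mids <- list()
  for (m in sys$dynamic_ids) {
    mids[[m]] <- y[, sys$layout[[m]], drop = FALSE]
    colnames(mids[[m]]) <- paste0("m", seq_len(ncol(mids[[m]])) - 1L)
  }
  for (m in names(sys$source_mid)) {
    mids[[m]] <- matrix(sys$source_mid[[m]], nrow = length(grid),
                        ncol = length(sys$source_mid[[m]]), byrow = TRUE,
                        dimnames = list(NULL, paste0("m", seq_along(sys$source_mid[[m]]) - 1L)))
  }
  structure(list(times = grid, mids = mids), class = "mfa_trajectory")
}

#' Mean labeled fraction of a metabolite over time
#'
#' Enrichment = `sum_x x * MID_(m+x) / n_atoms`, the mean fraction of
#' labeled atoms in the pool.
#'
#' @param traj an `mfa_trajectory`.
#' @param metabolite metabolite id.
#' @return numeric vector over `traj$times`.
#' @export
trajectory_enrichment <- function(traj, metabolite) {
  mid <- traj$mids[[metabolite]]
  if (is.null(mid)) stop_localmfa(sprintf("no trajectory for '%s'", metabolite),
                                  "localmfa_reference_error")
  n <- ncol(mid) - 1L
  as.numeric(mid %*% (0:n)) / n
}

#' Enrichment of a labeling-dataset metabolite over time
#'
#' @param ds a `labeling_dataset`.
#' @param metabolite metabolite id.
#' @return data.frame with columns `time_min`, `enrichment`.
#' @export
dataset_enrichment <- function(ds, metabolite) {
  d <- ds[ds$metabolite == metabolite, ]
  assert_that(nrow(d) > 0, sprintf("no records for '%s'", metabolite))
  n <- max(d$mass_shift)
  agg <- tapply(d$fraction * d$mass_shift, d$time_min, sum) / n
  data.frame(time_min = as.numeric(names(agg)), enrichment = as.numeric(agg),
             row.names = NULL)
}

#' Convert a trajectory to a long-format labeling dataset
#'
#' @param traj an `mfa_trajectory`.
#' @param sd nominal measurement standard deviation attached to every record.
#' @param metabolites which metabolites to keep (default all).
#' @return a `labeling_dataset`.
#' @export
as_labeling_dataset <- function(traj, sd = 0.01, metabolites = NULL) {
  mets <- metabolites %||% names(traj$mids)
  rows <- lapply(mets, function(m) {
    mid <- traj$mids[[m]]
    data.frame(metabolite = m,
               time_min = rep(traj$times, ncol(mid)),
               mass_shift = rep(seq_len(ncol(mid)) - 1L, each = nrow(mid)),
               fraction = as.vector(mid),
               sd = sd)
  })
  df <- do.call(rbind, rows)
  # solver output can carry tiny negative values; snap before validating
  df$fraction <- pmin(pmax(df$fraction, 0), 1)
  labeling_dataset(df, tol = 1e-5)
}

#' Subsample a trajectory into a measurement dataset
#'
#' Selects `k` grid indices evenly spaced in index space, always including
#' the first and last grid point, and attaches the nominal standard
#' deviation to every record.
#'
#' @param traj an `mfa_trajectory`.
#' @param k number of time points to keep (`2 <= k <= length(traj$times)`).
#' @param sd nominal measurement standard deviation.
#' @param metabolites which metabolites to keep (default all).
#' @return a `labeling_dataset` with `k` distinct time points.
#' @export
subsample_trajectory <- function(traj, k, sd = 0.01, metabolites = NULL) {
  n <- length(traj$times)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(k <= n, "k exceeds the number of grid points")
  idx <- round(seq(1, n, length.out = k))
  assert_that(!anyDuplicated(idx), "subsampling produced duplicate indices")
  sub <- structure(list(times = traj$times[idx],
                        mids = lapply(traj$mids, function(m) m[idx, , drop = FALSE])),
                   class = "mfa_trajectory")
  as_labeling_dataset(sub, sd = sd, metabolites = metabolites)
}

#' Add measurement noise to a labeling dataset
#'
#' Adds independent Gaussian noise with each record's own standard
#' deviation, clips fractions to `[0, 1]`, and renormalizes each
#' (metabolite, time) MID to sum 1. Deterministic for a fixed seed.
#'
#' @param ds a `labeling_dataset`.
#' @param rng_seed integer seed.
#' @return a noisy `labeling_dataset` (the `sd` column is unchanged).
#' @export
add_noise <- function(ds, rng_seed) {
  noisy <- as.data.frame(ds)
  noisy$fraction <- with_seed(rng_seed,
    noisy$fraction + stats::rnorm(nrow(noisy), sd = noisy$sd))
  noisy$fraction <- pmin(pmax(noisy$fraction, 0), 1)
  key <- paste(noisy$metabolite, noisy$time_min)
  sums <- tapply(noisy$fraction, key, sum)
  noisy$fraction <- noisy$fraction / as.numeric(sums[key])
  labeling_dataset(noisy)
}
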