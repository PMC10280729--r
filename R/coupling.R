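# Coupled-flux inference: replace poorly identified estimates by linear
# combinations of well-identified ones, using relations implied by the
# steady-state stoichiometry.
#
# A target flow t is derivable from known flows K iff the unit vector e_t
# lies in span{ e_k (k in K) } + rowspace(S), where S is the internal
# stoichiometric matrix over directed flows: then e_t = sum_k x_k e_k + S^T y,
# and every steady-state flux vector satisfies v_t = sum_k x_k v_k. The
# coefficients x are found by least squares; a nonzero residual means the
# relation is not implied by stoichiometry.

parse_flow_ref <- function(ref) {
  parts <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(parts) == 1) c(reaction = parts[1], direction = "fwd")
  else c(reaction = parts[1], direction = parts[2])
}

internal_stoich_matrix <- function(net) {
  flows <- network_flows(net)
  mets <- net$metabolites
  consumed <- unique(unlist(lapply(flows, function(f) names(f$stoich)[f$stoich < 0])))
  internal <- mets$id[!mets$is_source & mets$id %in% consumed]
  S <- matrix(0, length(internal), length(flows),
              dimnames = list(internal, flow_key(flows)))
  for (i in seq_along(flows)) {
    st <- flows[[i]]$stoich
    common <- intersect(names(st), internal)
    S[common, i] <- st[common]
  }
  S
}

#' Infer poorly identified fluxes from coupled well-identified ones
#'
#' For each requested flow, derives the linear combination of the supplied
#' estimates that the steady-state stoichiometry forces (e.g. full coupling
#' `v7 = v3`, or the node balance `v6_bwd = v7 + v6_fwd - v8`), and appends
#' the inferred estimate. The derivation coefficients are returned in the
#' attribute `coupling_coefficients` so that confidence intervals can be
#' propagated by applying the same combination to each Monte-Carlo
#' replicate.
#'
#' @param estimates data.frame with columns `reaction`, `direction`,
#'   `estimate` (the reliable estimates used as knowns).
#' @param net the full `mfa_network`.
#' @param fluxes_to_infer character vector of flow references, `"r7"` or
#'   `"r6:bwd"`.
#' @return `estimates` with one appended row per inferred flow (method tag
#'   `"coupled"`), attribute `coupling_coefficients` mapping each inferred
#'   flow to its named coefficient vector over known flow keys.
#' @export
infer_coupled_fluxes <- function(estimates, net, fluxes_to_infer) {
  S <- internal_stoich_matrix(net)
  keys <- colnames(S)
  known_keys <- paste(estimates$reaction, estimates$direction, sep = ":")
  bad <- setdiff(known_keys, keys)
  assert_that(length(bad) == 0,
              sprintf("unknown flows in estimates: %s", paste(bad, collapse = ", ")))
  assert_that(!anyDuplicated(known_keys), "duplicate flows in estimates")
  E <- matrix(0, length(keys), length(known_keys),
              dimnames = list(keys, known_keys))
  for (j in seq_along(known_keys)) E[known_keys[j], j] <- 1
  lsq_coef <- function(A, b) {
    sv <- svd(A)
    pos <- sv$d > 1e-10 * max(sv$d)
    z <- sv$v[, pos, drop = FALSE] %*%
      ((t(sv$u[, pos, drop = FALSE]) %*% b) / sv$d[pos])
    list(z = drop(z), resid = sqrt(sum((A %*% z - b)^2)))
  }
  coefs <- list()
  out <- estimates
  for (ref in fluxes_to_infer) {
    fr <- parse_flow_ref(ref)
    key <- paste(fr["reaction"], fr["direction"], sep = ":")
    assert_that(key %in% keys, sprintf("unknown flow '%s'", ref))
    e_t <- as.numeric(keys == key)
    x <- NULL
    # 1. full coupling with a single known flow: v_t = alpha v_k
    for (j in seq_along(known_keys)) {
      fit <- lsq_coef(cbind(E[, j], t(S)), e_t)
      if (fit$resid < 1e-8) {
        x <- stats::setNames(numeric(length(known_keys)), known_keys)
        x[j] <- fit$z[1]
        break
      }
    }
    # 2. a node balance whose other flows are all known
    if (is.null(x)) {
      rows <- which(S[, key] != 0)
      for (m in rows) {
        others <- keys[S[m, ] != 0 & keys != key]
        if (all(others %in% known_keys)) {
          x <- stats::setNames(numeric(length(known_keys)), known_keys)
          for (o in others) {
            x[match(o, known_keys)] <- -S[m, o] / S[m, key]
          }
          break
        }
      }
    }
    # 3. general least-squares derivation over all knowns
    if (is.null(x)) {
      fit <- lsq_coef(cbind(E, t(S)), e_t)
      if (fit$resid > 1e-8) {
        stop_localmfa(sprintf(
          "flux '%s' is not derivable from the given estimates and stoichiometry (residual %.2g)",
          ref, fit$resid), "localmfa_coupling_error")
      }
      x <- stats::setNames(fit$z[seq_along(known_keys)], known_keys)
    }
    x[abs(x) < 1e-10] <- 0
    value <- sum(x * estimates$estimate)
    coefs[[key]] <- x
    row <- data.frame(reaction = unname(fr["reaction"]),
                      direction = unname(fr["direction"]),
                      estimate = value, method = "coupled",
                      sse = NA_real_, converged = TRUE)
    missing_cols <- setdiff(names(out), names(row))
    for (mc in missing_cols) row[[mc]] <- NA
    out <- rbind(out, row[names(out)])
  }
  attr(out, "coupling_coefficients") <- coefs
  out
}
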