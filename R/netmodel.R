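# Data model for metabolic sub-networks with atom-transition maps,
# steady-state flux distributions and time-resolved labeling data.
#
# A network couples a metabolite table (id, number of labelable atoms, pool
# size, source flag) with a reaction list (signed stoichiometry, atom map,
# reversibility flag). Sources carry a fixed mass isotopomer distribution
# (MID) instead of obeying labeling dynamics. Fluxes are stored per reaction
# and direction ("fwd"/"bwd"), both nonnegative, in pool-units per minute;
# any other flux unit (e.g. mmol gDW^-1 h^-1) is a linear rescaling left to
# the caller.

# ---------------------------------------------------------------------------
# Atom maps

#' Parse an atom-transition map
#'
#' The bracket grammar lists each participating metabolite with its 1-based
#' atom indices, e.g. `"A[1]+B[1] -> H[1,2]"`. Atom slots are matched
#' positionally: the i-th atom listed on the substrate side is transferred to
#' the i-th atom slot listed on the product side. An empty product side
#' (`"O[1] ->"`) denotes a boundary efflux whose atoms leave the system.
#'
#' @param text atom-map string.
#' @param n_atoms optional named integer vector of atom counts used for
#'   bounds and conservation checking (all indices of every metabolite must
#'   be covered exactly once).
#' @return a data.frame with columns `sub_id`, `sub_atom`, `prod_id`,
#'   `prod_atom` (1-based indices); zero rows for an efflux map.
#' @seealso [format_atom_map()] for the inverse operation.
#' @export
#' @examples
#' parse_atom_map("A[1]+B[1] -> H[1,2]")
parse_atom_map <- function(text, n_atoms = NULL) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) < 1 || length(sides) > 2) {
    stop_localmfa(sprintf("atom map '%s': expected exactly one '->'", text),
                  "localmfa_parse_error")
  }
  parse_side <- function(side) {
    side <- trimws(side)
    if (side == "") {
      return(data.frame(id = character(), atom = integer()))
    }
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    out <- lapply(terms, function(term) {
      m <- regmatches(term, regexec("^([A-Za-z][A-Za-z0-9_]*)\\[([0-9, ]+)\\]$", term))[[1]]
      if (length(m) != 3) {
        stop_localmfa(sprintf("atom map term '%s' does not match 'Met[i,j,...]'", term),
                      "localmfa_parse_error")
      }
      idx <- as.integer(trimws(strsplit(m[3], ",", fixed = TRUE)[[1]]))
      data.frame(id = m[2], atom = idx)
    })
    do.call(rbind, out)
  }
  subs <- parse_side(sides[1])
  prods <- if (length(sides) == 2) parse_side(sides[2]) else
    data.frame(id = character(), atom = integer())
  if (nrow(prods) > 0 && nrow(subs) != nrow(prods)) {
    stop_localmfa(sprintf(
      "atom map '%s': %d substrate atoms vs %d product atoms (atoms not conserved)",
      text, nrow(subs), nrow(prods)), "localmfa_atom_conservation_error")
  }
  map <- if (nrow(prods) > 0) {
    data.frame(sub_id = subs$id, sub_atom = subs$atom,
               prod_id = prods$id, prod_atom = prods$atom)
  } else {
    # boundary efflux: atoms leave the system, no transfers to record
    data.frame(sub_id = character(0), sub_atom = integer(0),
               prod_id = character(0), prod_atom = integer(0))
  }
  check_side <- function(df, what) {
    for (id in unique(df$id)) {
      idx <- sort(df$atom[df$id == id])
      if (anyDuplicated(idx)) {
        stop_localmfa(sprintf("atom map '%s': duplicate %s atom index for '%s'",
                              text, what, id), "localmfa_atom_conservation_error")
      }
      if (any(idx < 1)) {
        stop_localmfa(sprintf("atom map '%s': atom index < 1 for '%s'", text, id),
                      "localmfa_bounds_error")
      }
      if (!is.null(n_atoms)) {
        if (!id %in% names(n_atoms)) {
          stop_localmfa(sprintf("atom map '%s': unknown metabolite '%s'", text, id),
                        "localmfa_reference_error")
        }
        na <- n_atoms[[id]]
        if (any(idx > na)) {
          stop_localmfa(sprintf(
            "atom map '%s': atom index %d out of range for '%s' (%d atom(s))",
            text, max(idx), id, na), "localmfa_bounds_error")
        }
        if (!identical(idx, seq_len(na))) {
          stop_localmfa(sprintf(
            "atom map '%s': atoms of '%s' not fully mapped (need 1..%d)",
            text, id, na), "localmfa_atom_conservation_error")
        }
      }
    }
  }
  check_side(subs, "substrate")
  check_side(prods, "product")
  map
}

#' Write an atom map back to its string form
#'
#' Inverse of [parse_atom_map()]: `parse_atom_map(format_atom_map(m))`
#' reproduces `m` for any valid map.
#'
#' @param map data.frame as returned by [parse_atom_map()].
#' @return a single string in the bracket grammar.
#' @export
format_atom_map <- function(map) {
  fmt_side <- function(ids, atoms) {
    if (length(ids) == 0) return("")
    ord <- unique(ids)
    paste(vapply(ord, function(id) {
      sprintf("%s[%s]", id, paste(atoms[ids == id], collapse = ","))
    }, character(1)), collapse = "+")
  }
  paste0(fmt_side(map$sub_id, map$sub_atom), " -> ",
         fmt_side(map$prod_id, map$prod_atom))
}

# ---------------------------------------------------------------------------
# Network assembly

parse_equation <- function(text) {
  sides <- strsplit(text, "->", fixed = TRUE)[[1]]
  if (length(sides) < 1 || length(sides) > 2) {
    stop_localmfa(sprintf("equation '%s': expected exactly one '->'", text),
                  "localmfa_parse_error")
  }
  parse_side <- function(side, sign) {
    side <- trimws(side)
    if (side == "") return(numeric(0))
    terms <- trimws(strsplit(side, "+", fixed = TRUE)[[1]])
    coefs <- numeric(0)
    for (term in terms) {
      m <- regmatches(term, regexec("^(([0-9]+)\\s+)?([A-Za-z][A-Za-z0-9_]*)$", term))[[1]]
      if (length(m) != 4) {
        stop_localmfa(sprintf("equation term '%s' does not match '[coef] Met'", term),
                      "localmfa_parse_error")
      }
      coef <- if (m[3] == "") 1L else as.integer(m[3])
      prev <- if (m[4] %in% names(coefs)) coefs[[m[4]]] else 0
      coefs[m[4]] <- sign * coef + prev
    }
    coefs
  }
  subs <- parse_side(sides[1], -1)
  prods <- if (length(sides) == 2) parse_side(sides[2], +1) else numeric(0)
  stoich <- c(subs, prods)
  if (sum(stoich < 0) < 1) {
    stop_localmfa(sprintf("equation '%s': no substrate", text), "localmfa_validation_error")
  }
  stoich
}

format_equation <- function(stoich) {
  fmt <- function(v) paste(sprintf("%d %s", as.integer(abs(v)), names(v)), collapse = " + ")
  subs <- stoich[stoich < 0]
  prods <- stoich[stoich > 0]
  paste0(fmt(subs), " -> ", if (length(prods)) fmt(prods) else "")
}

#' Construct a reaction
#'
#' @param id reaction identifier.
#' @param equation equation string, e.g. `"1 A + 1 B -> 1 H"`; an empty
#'   product side denotes a boundary efflux.
#' @param atom_map atom-map string in the bracket grammar, or a parsed map.
#' @param reversible logical; reversible reactions carry separate
#'   nonnegative forward and backward flux values.
#' @return a list of class `mfa_reaction`.
#' @export
reaction <- function(id, equation, atom_map = "", reversible = FALSE) {
  stoich <- parse_equation(equation)
  map <- if (is.character(atom_map)) parse_atom_map(atom_map) else atom_map
  structure(list(id = id, stoich = stoich, atom_map = map,
                 reversible = isTRUE(reversible)),
            class = "mfa_reaction")
}

#' Assemble and validate a network
#'
#' @param metabolites data.frame with columns `id`, `n_atoms`, `pool_size`,
#'   `is_source`. Source metabolites hold a fixed MID and need no pool size
#'   (`NA` allowed); all other pool sizes must be positive.
#' @param reactions list of [reaction()] objects.
#' @return an object of class `mfa_network`.
#' @export
network <- function(metabolites, reactions) {
  stopifnot(is.data.frame(metabolites),
            all(c("id", "n_atoms", "pool_size", "is_source") %in% names(metabolites)))
  assert_that(!anyDuplicated(metabolites$id), "duplicate metabolite id")
  assert_that(all(metabolites$n_atoms >= 1), "every metabolite needs n_atoms >= 1")
  internal <- !metabolites$is_source
  assert_that(all(metabolites$pool_size[internal] > 0, na.rm = FALSE) &&
                !anyNA(metabolites$pool_size[internal]),
              "pool_size must be positive for all non-source metabolites")
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop_localmfa(sprintf("duplicate reaction id '%s'", ids[duplicated(ids)][1]),
                  "localmfa_validation_error")
  }
  n_atoms <- stats::setNames(metabolites$n_atoms, metabolites$id)
  for (r in reactions) {
    unknown <- setdiff(names(r$stoich), metabolites$id)
    if (length(unknown)) {
      stop_localmfa(sprintf("reaction '%s' references unknown metabolite '%s'",
                            r$id, unknown[1]), "localmfa_reference_error")
    }
    # atom maps assume each metabolite occurs once per side
    if (any(abs(r$stoich[unique(c(r$atom_map$sub_id, r$atom_map$prod_id))]) > 1)) {
      stop_localmfa(sprintf("reaction '%s': stoichiometric coefficients > 1 are not supported with atom maps",
                            r$id), "localmfa_validation_error")
    }
    map_subs <- unique(r$atom_map$sub_id)
    eq_subs <- names(r$stoich)[r$stoich < 0]
    eq_prods <- names(r$stoich)[r$stoich > 0]
    if (nrow(r$atom_map) > 0) {
      if (!setequal(map_subs, eq_subs) ||
          !setequal(unique(r$atom_map$prod_id),
                    if (length(eq_prods)) eq_prods else character(0))) {
        stop_localmfa(sprintf("reaction '%s': atom map inconsistent with stoichiometry", r$id),
                      "localmfa_validation_error")
      }
      # re-validate with atom counts for bounds + full coverage
      parse_atom_map(format_atom_map(r$atom_map), n_atoms[names(r$stoich)])
    }
  }
  structure(list(metabolites = metabolites, reactions = reactions),
            class = "mfa_network")
}

#' @export
print.mfa_network <- function(x, ...) {
  cat(sprintf("<mfa_network> %d metabolites, %d reactions (%d reversible)\n",
              nrow(x$metabolites), length(x$reactions),
              sum(vapply(x$reactions, `[[`, logical(1), "reversible"))))
  invisible(x)
}

reaction_ids <- function(net) vapply(net$reactions, `[[`, character(1), "id")

get_reaction <- function(net, id) {
  i <- match(id, reaction_ids(net))
  if (is.na(i)) stop_localmfa(sprintf("unknown reaction '%s'", id),
                              "localmfa_reference_error")
  net$reactions[[i]]
}

metabolite_info <- function(net, id) {
  i <- match(id, net$metabolites$id)
  if (is.na(i)) stop_localmfa(sprintf("unknown metabolite '%s'", id),
                              "localmfa_reference_error")
  net$metabolites[i, ]
}

#' Expand a network into directed flows
#'
#' Reversible reactions are split into a forward and a backward flow (the
#' backward flow has negated stoichiometry and the inverse atom map), so
#' downstream code can treat every flow as an irreversible conversion with
#' its own nonnegative flux value.
#' @noRd
network_flows <- function(net) {
  flows <- list()
  for (r in net$reactions) {
    flows[[length(flows) + 1L]] <- list(
      reaction_id = r$id, direction = "fwd", stoich = r$stoich,
      atom_map = r$atom_map)
    if (r$reversible) {
      inv <- r$atom_map
      if (nrow(inv) > 0) {
        inv <- data.frame(sub_id = inv$prod_id, sub_atom = inv$prod_atom,
                          prod_id = inv$sub_id, prod_atom = inv$sub_atom)
      }
      flows[[length(flows) + 1L]] <- list(
        reaction_id = r$id, direction = "bwd", stoich = -r$stoich,
        atom_map = inv)
    }
  }
  flows
}

flow_key <- function(flows) {
  vapply(flows, function(f) paste(f$reaction_id, f$direction, sep = ":"), character(1))
}

# ---------------------------------------------------------------------------
# Flux distributions

#' Construct a flux distribution
#'
#' @param df data.frame with columns `reaction_id`, `direction`
#'   (`"fwd"`/`"bwd"`), `value` (nonnegative, pool-units per minute).
#' @return data.frame of class `mfa_fluxes`.
#' @export
flux_distribution <- function(df) {
  stopifnot(all(c("reaction_id", "direction", "value") %in% names(df)))
  assert_that(all(df$direction %in% c("fwd", "bwd")), "direction must be fwd or bwd")
  assert_that(all(df$value >= 0), "flux values must be nonnegative")
  assert_that(!anyDuplicated(paste(df$reaction_id, df$direction)),
              "duplicate (reaction, direction) flux entry")
  class(df) <- c("mfa_fluxes", "data.frame")
  df
}

#' Look up a flux value
#'
#' @param fluxes an `mfa_fluxes` object.
#' @param reaction_id,direction which flow.
#' @return the flux value (error if missing).
#' @export
flux_value <- function(fluxes, reaction_id, direction = "fwd") {
  i <- which(fluxes$reaction_id == reaction_id & fluxes$direction == direction)
  if (length(i) != 1) {
    stop_localmfa(sprintf("missing flux for reaction '%s' (%s)", reaction_id, direction),
                  "localmfa_missing_flux_error")
  }
  fluxes$value[i]
}

flow_values <- function(net, fluxes) {
  flows <- network_flows(net)
  vapply(flows, function(f) flux_value(fluxes, f$reaction_id, f$direction),
         numeric(1))
}

#' Check steady state of a flux distribution
#'
#' For every internal metabolite (non-source, with at least one consuming
#' reaction) the total production must equal the total consumption. Sinks —
#' metabolites never consumed — are excluded, as their pools accumulate by
#' construction.
#'
#' @param net an `mfa_network`.
#' @param fluxes an `mfa_fluxes` object covering every reaction (both
#'   directions for reversible reactions).
#' @param tol absolute imbalance tolerance.
#' @return data.frame (class `steady_state_report`) with columns
#'   `metabolite`, `production`, `consumption`, `imbalance`, and attributes
#'   `ok` (all pass) and `tol`.
#' @export
validate_steady_state <- function(net, fluxes, tol = 1e-9) {
  flows <- network_flows(net)
  vals <- flow_values(net, fluxes)
  mets <- net$metabolites
  consumed <- unique(unlist(lapply(flows, function(f) names(f$stoich)[f$stoich < 0])))
  internal <- mets$id[!mets$is_source & mets$id %in% consumed]
  rows <- lapply(internal, function(m) {
    prod <- cons <- 0
    for (i in seq_along(flows)) {
      s <- flows[[i]]$stoich[m]
      if (is.na(s)) next
      if (s > 0) prod <- prod + s * vals[i]
      if (s < 0) cons <- cons - s * vals[i]
    }
    data.frame(metabolite = m, production = prod, consumption = cons,
               imbalance = prod - cons)
  })
  report <- do.call(rbind, rows)
  structure(report, ok = all(abs(report$imbalance) <= tol), tol = tol,
            class = c("steady_state_report", "data.frame"))
}

# ---------------------------------------------------------------------------
# Labeling datasets

#' Validate a labeling dataset
#'
#' Long-format records of time-resolved MID measurements: one row per
#' (metabolite, time, mass shift) with measured fraction and its standard
#' deviation. For each (metabolite, time) the fractions must sum to 1.
#'
#' @param df data.frame with columns `metabolite`, `time_min`, `mass_shift`,
#'   `fraction`, `sd`.
#' @param net optional network used to bound `mass_shift` by `n_atoms`.
#' @param tol normalization tolerance.
#' @return the validated data.frame, class `labeling_dataset`.
#' @export
labeling_dataset <- function(df, net = NULL, tol = 1e-6) {
  need <- c("metabolite", "time_min", "mass_shift", "fraction", "sd")
  stopifnot(all(need %in% names(df)))
  assert_that(all(df$fraction >= -tol & df$fraction <= 1 + tol),
              "fractions must lie in [0, 1]")
  assert_that(all(df$sd >= 0), "standard deviations must be nonnegative")
  assert_that(all(df$mass_shift >= 0), "mass shifts must be nonnegative")
  sums <- tapply(df$fraction, paste(df$metabolite, df$time_min), sum)
  if (any(abs(sums - 1) > tol)) {
    bad <- names(sums)[which.max(abs(sums - 1))]
    stop_localmfa(sprintf("MID fractions do not sum to 1 for (%s): sum = %.8f",
                          bad, sums[[which.max(abs(sums - 1))]]),
                  "localmfa_validation_error")
  }
  if (!is.null(net)) {
    na <- stats::setNames(net$metabolites$n_atoms, net$metabolites$id)
    assert_that(all(df$mass_shift <= na[df$metabolite]),
                "mass shift exceeds the metabolite's atom count")
  }
  class(df) <- unique(c("labeling_dataset", class(df)))
  df
}
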