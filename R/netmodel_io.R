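# Plain-text I/O for networks, fluxes, pools and labeling data.
#
# File dialects:
#   network TSV: reaction_id <TAB> equation <TAB> atom_map <TAB> reversible
#   fluxes TSV:  reaction_id <TAB> direction (fwd|bwd) <TAB> value
#   pools TSV:   metabolite_id <TAB> pool_size <TAB> n_atoms <TAB> is_source
#   labeling CSV (long): metabolite,time_min,mass_shift,fraction,sd

#' Load a network, its flux distribution and pool sizes from TSV files
#'
#' @param network_path,fluxes_path,pools_path paths to the three TSV files.
#' @param steady_state_tol tolerance for the steady-state validation applied
#'   on load; use `NA` to skip the check.
#' @return list with elements `network` (an `mfa_network`) and `fluxes`
#'   (an `mfa_fluxes`).
#' @export
load_network <- function(network_path, fluxes_path, pools_path,
                         steady_state_tol = 1e-6) {
  for (p in c(network_path, fluxes_path, pools_path)) {
    if (!file.exists(p)) stop_localmfa(sprintf("file not found: %s", p),
                                       "localmfa_io_error")
  }
  pools <- utils::read.delim(pools_path, stringsAsFactors = FALSE)
  need <- c("metabolite_id", "pool_size", "n_atoms", "is_source")
  assert_that(all(need %in% names(pools)),
              sprintf("pools TSV must have columns %s", paste(need, collapse = ", ")))
  mets <- data.frame(id = pools$metabolite_id,
                     n_atoms = as.integer(pools$n_atoms),
                     pool_size = as.numeric(pools$pool_size),
                     is_source = as.logical(pools$is_source))

  nettab <- utils::read.delim(network_path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "equation", "atom_map", "reversible")
  assert_that(all(need %in% names(nettab)),
              sprintf("network TSV must have columns %s", paste(need, collapse = ", ")))
  reactions <- vector("list", nrow(nettab))
  for (i in seq_len(nrow(nettab))) {
    reactions[[i]] <- tryCatch(
      reaction(nettab$reaction_id[i], nettab$equation[i],
               nettab$atom_map[i], as.logical(nettab$reversible[i])),
      localmfa_parse_error = function(e) {
        stop_localmfa(sprintf("%s (line %d of %s)", conditionMessage(e),
                              i + 1L, network_path), "localmfa_parse_error")
      })
  }
  net <- network(mets, reactions)

  fx <- utils::read.delim(fluxes_path, stringsAsFactors = FALSE)
  need <- c("reaction_id", "direction", "value")
  assert_that(all(need %in% names(fx)),
              sprintf("fluxes TSV must have columns %s", paste(need, collapse = ", ")))
  fluxes <- flux_distribution(fx)

  if (!is.na(steady_state_tol)) {
    rep <- validate_steady_state(net, fluxes, tol = steady_state_tol)
    if (!attr(rep, "ok")) {
      worst <- rep[which.max(abs(rep$imbalance)), ]
      stop_localmfa(sprintf(
        "flux distribution is not at steady state: imbalance %.3g at metabolite '%s'",
        worst$imbalance, worst$metabolite), "localmfa_steady_state_error")
    }
  }
  list(network = net, fluxes = fluxes)
}

#' Write a network, fluxes and pools to TSV files
#'
#' Inverse of [load_network()]: loading the written files reproduces the
#' network field-for-field.
#'
#' @param net an `mfa_network`.
#' @param fluxes an `mfa_fluxes`.
#' @param network_path,fluxes_path,pools_path output paths.
#' @return invisibly, the three paths.
#' @export
write_network <- function(net, fluxes, network_path, fluxes_path, pools_path) {
  nettab <- do.call(rbind, lapply(net$reactions, function(r) {
    data.frame(reaction_id = r$id,
               equation = format_equation(r$stoich),
               atom_map = format_atom_map(r$atom_map),
               reversible = as.integer(r$reversible))
  }))
  utils::write.table(nettab, network_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(as.data.frame(fluxes), fluxes_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pools <- data.frame(metabolite_id = net$metabolites$id,
                      pool_size = net$metabolites$pool_size,
                      n_atoms = net$metabolites$n_atoms,
                      is_source = as.integer(net$metabolites$is_source))
  utils::write.table(pools, pools_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(network_path, fluxes_path, pools_path))
}

#' Read a long-format labeling CSV
#'
#' @param path CSV with header `metabolite,time_min,mass_shift,fraction,sd`.
#' @param net optional network for mass-shift bounds checking.
#' @return a `labeling_dataset`.
#' @export
read_labeling <- function(path, net = NULL) {
  labeling_dataset(utils::read.csv(path, stringsAsFactors = FALSE), net = net)
}

#' Write a labeling dataset to CSV
#'
#' @param ds a `labeling_dataset`.
#' @param path output path.
#' @export
write_labeling <- function(ds, path) {
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a scenario to a directory of plain-text files
#'
#' Writes `network.tsv`, `fluxes.tsv`, `pools.tsv`, a `source_mid.tsv` with
#' the fixed MIDs of the source metabolites, and `scenario.tsv` holding the
#' horizon and description.
#'
#' @param scenario an `mfa_scenario` (see [build_synthetic_scenario()]).
#' @param dir output directory (created if needed).
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(scenario$network, scenario$fluxes,
                file.path(dir, "network.tsv"),
                file.path(dir, "fluxes.tsv"),
                file.path(dir, "pools.tsv"))
  src <- do.call(rbind, lapply(names(scenario$source_mid), function(m) {
    mid <- scenario$source_mid[[m]]
    data.frame(metabolite_id = m, mass_shift = seq_along(mid) - 1L, fraction = mid)
  }))
  utils::write.table(src, file.path(dir, "source_mid.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- data.frame(key = c("horizon", "description"),
                     value = c(format(scenario$horizon, digits = 15),
                               scenario$description))
  utils::write.table(meta, file.path(dir, "scenario.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a scenario written by [write_scenario()]
#'
#' @param dir directory with the scenario files.
#' @return an `mfa_scenario`.
#' @export
load_scenario <- function(dir) {
  loaded <- load_network(file.path(dir, "network.tsv"),
                         file.path(dir, "fluxes.tsv"),
                         file.path(dir, "pools.tsv"),
                         steady_state_tol = NA)
  src <- utils::read.delim(file.path(dir, "source_mid.tsv"), stringsAsFactors = FALSE)
  source_mid <- lapply(split(src, src$metabolite_id),
                       function(d) d$fraction[order(d$mass_shift)])
  meta <- utils::read.delim(file.path(dir, "scenario.tsv"), stringsAsFactors = FALSE)
  horizon <- as.numeric(meta$value[meta$key == "horizon"])
  descr <- meta$value[meta$key == "description"]
  scenario(loaded$network, loaded$fluxes, horizon,
           source_mid = source_mid[order(names(source_mid))],
           description = descr)
}
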