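test_that("atom maps parse, validate and round-trip through their writer", {
  m <- parse_atom_map("A[1]+B[1] -> H[1,2]")
  expect_equal(m$sub_id, c("A", "B"))
  expect_equal(m$prod_id, c("H", "H"))
  expect_equal(m$prod_atom, c(1L, 2L))

  inv <- parse_atom_map("H[1,2] -> A[1]+B[1]")
  expect_equal(inv$sub_atom, c(1L, 2L))
  expect_equal(inv$prod_id, c("A", "B"))

  # writer inverts the parser on a batch of valid maps
  for (txt in c("A[1] -> B[1]", "A[1]+B[1] -> H[1,2]",
                "H[1,2] -> G[1]+M[1]", "X[1,2,3] -> Y[2,1,3]")) {
    expect_equal(parse_atom_map(format_atom_map(parse_atom_map(txt))),
                 parse_atom_map(txt))
  }

  expect_error(parse_atom_map("A[1] -> B[2]", n_atoms = c(A = 1L, B = 1L)),
               class = "localmfa_bounds_error")
  expect_error(parse_atom_map("A[1]+B[1] -> H[1]"),
               class = "localmfa_atom_conservation_error")
  expect_error(parse_atom_map("A[1,1] -> H[1,2]"),
               class = "localmfa_atom_conservation_error")
  expect_error(parse_atom_map("A(1) -> B[1]"), class = "localmfa_parse_error")
})

test_that("network assembly enforces unique ids, references and atom coverage", {
  mets <- data.frame(id = c("A", "B"), n_atoms = 1L,
                     pool_size = c(1, 1), is_source = FALSE)
  expect_error(
    network(mets, list(reaction("r1", "1 A -> 1 B", "A[1] -> B[1]"),
                       reaction("r1", "1 B -> 1 A", "B[1] -> A[1]"))),
    class = "localmfa_validation_error")
  expect_error(
    network(mets, list(reaction("r1", "1 A -> 1 C", "A[1] -> C[1]"))),
    class = "localmfa_reference_error")
  # a minimal valid network
  net <- network(mets, list(reaction("r1", "1 A -> 1 B", "A[1] -> B[1]")))
  expect_s3_class(net, "mfa_network")
  expect_equal(nrow(net$metabolites), 2)
  expect_length(net$reactions, 1)
})

test_that("the packaged fixture files load to the synthetic network", {
  dir <- system.file("extdata", "synthetic", package = "localmfa")
  loaded <- load_network(file.path(dir, "network.tsv"),
                         file.path(dir, "fluxes.tsv"),
                         file.path(dir, "pools.tsv"))
  expect_equal(nrow(loaded$network$metabolites), 18)
  expect_length(loaded$network$reactions, 19)
  # and agree field-for-field with the in-code builder
  sc <- build_synthetic_scenario()
  expect_equal(lapply(loaded$network$reactions, unclass),
               lapply(sc$network$reactions, unclass))
  expect_equal(loaded$network$metabolites, sc$network$metabolites)
})

test_that("steady-state validation flags imbalances and passes the fixture", {
  sc <- build_synthetic_scenario()
  rep <- validate_steady_state(sc$network, sc$fluxes, tol = 1e-10)
  expect_true(attr(rep, "ok"))
  expect_lt(max(abs(rep$imbalance)), 1e-10)

  # linear chain with v1 = 2, v2 = 1: imbalance +1 at B
  mets <- data.frame(id = c("A", "B", "C"), n_atoms = 1L, pool_size = 1,
                     is_source = c(TRUE, FALSE, FALSE))
  net <- network(mets, list(reaction("v1", "1 A -> 1 B", "A[1] -> B[1]"),
                            reaction("v2", "1 B -> 1 C", "B[1] -> C[1]")))
  fx <- flux_distribution(data.frame(reaction_id = c("v1", "v2"),
                                     direction = "fwd", value = c(2, 1)))
  rep2 <- validate_steady_state(net, fx, tol = 1e-9)
  expect_false(attr(rep2, "ok"))
  expect_equal(rep2$imbalance[rep2$metabolite == "B"], 1)

  # editing one flux breaks loading; oracle: imbalance at D becomes
  # production (v7 + v6f = 0.5 + 0.8) minus consumption (v6b + 1.4) = -0.4
  dir <- system.file("extdata", "synthetic", package = "localmfa")
  fx_tab <- utils::read.delim(file.path(dir, "fluxes.tsv"))
  fx_tab$value[fx_tab$reaction_id == "r8"] <- 1.4
  bad <- tempfile(fileext = ".tsv")
  utils::write.table(fx_tab, bad, sep = "\t", quote = FALSE, row.names = FALSE)
  err <- tryCatch(
    load_network(file.path(dir, "network.tsv"), bad, file.path(dir, "pools.tsv")),
    localmfa_steady_state_error = function(e) e)
  expect_s3_class(err, "localmfa_steady_state_error")
  expect_match(conditionMessage(err), "-0.4")

  # missing flux errors
  fx_missing <- flux_distribution(data.frame(reaction_id = "v1",
                                             direction = "fwd", value = 2))
  expect_error(validate_steady_state(net, fx_missing),
               class = "localmfa_missing_flux_error")
})

test_that("the flux balance around the reversible node holds in the fixture", {
  sc <- build_synthetic_scenario()
  v <- function(r, d = "fwd") flux_value(sc$fluxes, r, d)
  expect_equal(v("r8") + v("r6", "bwd"), v("r7") + v("r6", "fwd"))
})

test_that("network write/load round-trips field-for-field", {
  sc <- build_synthetic_scenario()
  d <- withr::local_tempdir()
  write_scenario(sc, d)
  sc2 <- load_scenario(d)
  expect_equal(lapply(sc2$network$reactions, unclass),
               lapply(sc$network$reactions, unclass))
  expect_equal(sc2$network$metabolites, sc$network$metabolites)
  expect_equal(as.data.frame(sc2$fluxes), as.data.frame(sc$fluxes))
  expect_equal(sc2$horizon, sc$horizon)
  expect_equal(sc2$source_mid, sc$source_mid)
})

test_that("labeling datasets enforce normalization and mass-shift bounds", {
  good <- data.frame(metabolite = "A", time_min = c(0, 0), mass_shift = c(0, 1),
                     fraction = c(0.7, 0.3), sd = 0.01)
  expect_s3_class(labeling_dataset(good), "labeling_dataset")
  bad <- good; bad$fraction <- c(0.7, 0.4)
  expect_error(labeling_dataset(bad), class = "localmfa_validation_error")
  sc <- build_synthetic_scenario()
  shifted <- good; shifted$metabolite <- "A"; shifted$mass_shift <- c(0, 2)
  expect_error(labeling_dataset(shifted, net = sc$network))
})
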