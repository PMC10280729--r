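# Shared fixtures built in code. Objects that are expensive to compute
# (scenario trajectory) are built once per test run and cached here.

two_pool_chain <- function(v = 2, pool_B = 4, horizon = 15) {
  mets <- data.frame(id = c("S", "B"), n_atoms = 1L,
                     pool_size = c(NA, pool_B), is_source = c(TRUE, FALSE))
  net <- network(mets, list(
    reaction("v1", "1 S -> 1 B", "S[1] -> B[1]"),
    reaction("v2", "1 B ->", "B[1] ->")))
  fx <- flux_distribution(data.frame(reaction_id = c("v1", "v2"),
                                     direction = "fwd", value = v))
  scenario(net, fx, horizon, description = "two-pool chain")
}

converging_motif <- function(v1 = 2, v2 = 1, pools = c(X = 0.5, Y = 2, Z = 1.5),
                             horizon = 15) {
  mets <- data.frame(id = c("S", "X", "Y", "Z"), n_atoms = 1L,
                     pool_size = c(NA, pools[["X"]], pools[["Y"]], pools[["Z"]]),
                     is_source = c(TRUE, FALSE, FALSE, FALSE))
  net <- network(mets, list(
    reaction("a1", "1 S -> 1 X", "S[1] -> X[1]"),
    reaction("a2", "1 S -> 1 Y", "S[1] -> Y[1]"),
    reaction("b1", "1 X -> 1 Z", "X[1] -> Z[1]"),
    reaction("b2", "1 Y -> 1 Z", "Y[1] -> Z[1]"),
    reaction("c1", "1 Z ->", "Z[1] ->")))
  fx <- flux_distribution(data.frame(
    reaction_id = c("a1", "a2", "b1", "b2", "c1"), direction = "fwd",
    value = c(v1, v2, v1, v2, v1 + v2)))
  scenario(net, fx, horizon, description = "converging motif")
}

# cached dense trajectory of the packaged synthetic scenario
synthetic_cache <- local({
  env <- new.env()
  function() {
    if (is.null(env$traj)) {
      env$sc <- build_synthetic_scenario()
      env$traj <- simulate_labeling(env$sc, make_log_grid(161, 15))
    }
    list(sc = env$sc, traj = env$traj)
  }
})
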