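# Shared fixtures. Worlds are memoized so the expensive pools are built once
# per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small world for unit tests
small_world <- function() {
  memo("small", function()
    synthetic_world(seed = 2, reference_n = 8000, pool_n = 12000))
}

# study-scale world for the acceptance suite: in-domain pool >= 50k
acceptance_world <- function() {
  memo("acceptance", function()
    synthetic_world(seed = 1, reference_n = 20000, pool_n = 60000))
}

# reindex the atoms of a molgraph by permutation p
perm_graph <- function(g, p) {
  inv <- order(p)
  molgraph(g$element[p], g$hcount[p],
           if (length(g$bond_i))
             cbind(inv[g$bond_i], inv[g$bond_j], g$bond_order))
}

random_test_graphs <- function(n, max_heavy = 8, seed = 99) {
  generate_molecules(n, max_heavy, seed = seed)
}

# simulated ensemble block: submodels normal around targets + bias
sim_block <- function(n, n_ens, bias, sigma, targets = numeric(n), seed = 1) {
  set.seed(seed)
  P <- matrix(rnorm(n_ens * n, sd = sigma), n_ens, n) +
    matrix(targets + bias, n_ens, n, byrow = TRUE)
  ensemble_block(P, targets)
}
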