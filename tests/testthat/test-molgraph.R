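# molecular graphs, the restricted SMILES dialect, groups and fingerprints

test_that("parsing computes implicit hydrogens and validates valence", {
  g <- parse_smiles("C")
  expect_equal(length(g$element), 1L)
  expect_equal(g$hcount, 4L)
  expect_equal(length(g$bond_i), 0L)

  g <- parse_smiles("CCO")
  expect_equal(g$element, c("C", "C", "O"))
  expect_equal(g$hcount, c(3L, 2L, 1L))
  expect_equal(cbind(g$bond_i, g$bond_j, g$bond_order),
               cbind(c(1L, 2L), c(2L, 3L), c(1L, 1L)))

  # bond symbols and rings
  expect_equal(parse_smiles("O=C=O")$hcount, c(0L, 0L, 0L))
  expect_equal(parse_smiles("C#N")$hcount, c(1L, 0L))
  ring <- parse_smiles("C1CC1")
  expect_equal(length(ring$bond_i), 3L)
})

test_that("malformed SMILES raise parse errors naming the position", {
  expect_error(parse_smiles("C("), "unbalanced")
  expect_error(parse_smiles("CC)"), "position 3")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CX"), "position 2")
  expect_error(parse_smiles("C=="), "position 3")
  expect_error(parse_smiles(""), "parse error")
  expect_error(parse_smiles("F=C"), "valence")   # F cannot double-bond
  expect_error(parse_smiles("O(C)(C)C"), "valence")
})

test_that("graph construction enforces the valence table and connectivity", {
  expect_error(molgraph("C", hcount = 3L), "valence")
  expect_error(molgraph(c("C", "C"), bonds = cbind(1, 1, 1)), "self-bonds")
  expect_error(molgraph(c("C", "C"),
                        bonds = rbind(c(1, 2, 1), c(2, 1, 1))), "duplicate")
  expect_error(molgraph(c("C", "C")), "not connected")
  expect_error(molgraph("X"), "unsupported element")
})

test_that("canonical SMILES round-trips and is reindexing-invariant", {
  for (smi in c("C", "CCO", "C1CC1", "CC(C)(C)C", "N#CC1OC1F",
                "FC(F)(F)C(F)(F)F", "C1CCCCC1", "O=C=O")) {
    g <- parse_smiles(smi)
    s <- write_smiles(g)
    expect_identical(write_smiles(parse_smiles(s)), s)
  }
  set.seed(42)
  mols <- random_test_graphs(100, seed = 5)
  for (g in mols) {
    s <- write_smiles(g)
    g2 <- parse_smiles(s)
    # isomorphic: same canonical form, same sorted invariants
    expect_identical(write_smiles(g2), s)
    expect_identical(sort(g2$element), sort(g$element))
    expect_identical(sort(g2$hcount), sort(g$hcount))
    for (k in 1:3) {
      p <- sample(length(g$element))
      expect_identical(write_smiles(perm_graph(g, p)), s)
    }
  }
})

test_that("round trip holds on 1000 random generated graphs", {
  mols <- random_test_graphs(1000, seed = 7)
  smis <- vapply(mols, write_smiles, character(1))
  re <- vapply(smis, function(s) write_smiles(parse_smiles(s)), character(1),
               USE.NAMES = FALSE)
  expect_identical(re, smis)
  # and all parsed graphs satisfy the valence invariant
  for (s in smis[seq(1, 1000, by = 50)])
    expect_silent(validate_molgraph(parse_smiles(s)))
})

test_that("group extraction follows the 1-bond-radius definition", {
  expect_identical(extract_groups(parse_smiles("C")), "C;H4;")
  expect_identical(extract_groups(parse_smiles("CC")),
                   c("C;H3;1C", "C;H3;1C"))
  expect_identical(extract_groups(parse_smiles("CCO")),
                   c("C;H3;1C", "C;H2;1C+1O", "O;H1;1C"))
  # one group per heavy atom, invariant under reindexing
  g <- parse_smiles("N#CC1OC1F")
  base <- sort(extract_groups(g))
  set.seed(11)
  for (k in 1:100) {
    p <- sample(length(g$element))
    expect_identical(sort(extract_groups(perm_graph(g, p))), base)
  }
})

test_that("circular fingerprints are deterministic and canonical", {
  g <- parse_smiles("CC(=O)NC")
  expect_identical(circular_fingerprint(g, 2, 1024),
                   circular_fingerprint(g, 2, 1024))
  # methane at radius 0: exactly one environment, one bit
  expect_equal(sum(circular_fingerprint(parse_smiles("C"), 0, 1024)), 1L)
  # ethane vs ethanol differ
  expect_false(identical(circular_fingerprint(parse_smiles("CC"), 2, 1024),
                         circular_fingerprint(parse_smiles("CCO"), 2, 1024)))
  # isomorphic graphs give identical vectors
  set.seed(3)
  p <- sample(length(g$element))
  expect_identical(circular_fingerprint(perm_graph(g, p), 2, 256),
                   circular_fingerprint(g, 2, 256))
  # counted variant sums to the number of environments
  expect_equal(sum(circular_fingerprint(g, 2, 64, counts = TRUE)),
               3L * length(g$element))
  # the R reference hash (documented polynomial) matches the compiled path
  envs <- unlist(adduq:::atom_environments(g, 2))
  idx <- adduq:::poly_hash(unique(envs)) %% 256 + 1
  ref <- tabulate(idx[match(envs, unique(envs))], nbins = 256)
  expect_equal(circular_fingerprint(g, 2, 256, counts = TRUE), ref)
})

test_that("element corruption affects the feature view only", {
  g <- parse_smiles("CCN")
  v <- corrupt_elements(g, c(N = "C"))
  expect_identical(v$element, c("C", "C", "C"))
  expect_identical(v$hcount, g$hcount)      # H counts retained
  # identity map leaves features unchanged
  id <- corrupt_elements(g, c(C = "C", N = "N"))
  expect_identical(circular_fingerprint(id, 2, 128),
                   circular_fingerprint(g, 2, 128))
  # CCO and CCN views collide except for central H counts
  vO <- corrupt_elements(parse_smiles("CCO"), c(O = "C", N = "C"))
  vN <- corrupt_elements(parse_smiles("CCN"), c(O = "C", N = "C"))
  kO <- extract_groups(vO); kN <- extract_groups(vN)
  expect_identical(gsub("H[0-9]", "H", kO), gsub("H[0-9]", "H", kN))
  expect_false(identical(sort(kO), sort(kN)))
})
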