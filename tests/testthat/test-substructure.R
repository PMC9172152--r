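# Stereo-aware substructure matching.

test_that("worked examples match by hand-checked counts", {
  expect_equal(length(find_substructure_matches(parse_smiles("C(=O)NC"),
                                                parse_smiles("CC(=O)NC"))), 1)
  expect_equal(length(find_substructure_matches(parse_smiles("C"),
                                                parse_smiles("C"))), 1)
  expect_equal(length(find_substructure_matches(parse_smiles("c1ccccc1"),
                                                parse_smiles("Cc1ccccc1"))), 1)
  expect_equal(length(find_substructure_matches(parse_smiles("CCCC"),
                                                parse_smiles("CC"))), 0)
})

test_that("chiral matching distinguishes epimers and can be toggled", {
  sub <- parse_smiles("N[C@@H](C)C(=O)O")
  epimer <- parse_smiles("N[C@H](C)C(=O)O")
  same <- parse_smiles("N[C@@H](C)C(=O)O")
  expect_equal(length(find_substructure_matches(sub, epimer)), 0)
  expect_equal(length(find_substructure_matches(sub, epimer,
                                                match_chiral = FALSE)), 1)
  expect_equal(length(find_substructure_matches(sub, same)), 1)
})

test_that("stereo undefined in the query matches defined parents, not vice versa", {
  undef <- parse_smiles("NC(C)C(=O)O")
  def <- parse_smiles("N[C@@H](C)C(=O)O")
  expect_equal(length(find_substructure_matches(undef, def)), 1)
  expect_equal(length(find_substructure_matches(def, undef)), 0)
  # same directionality for double-bond stereo
  undef_b <- parse_smiles("CC=CC")
  def_b <- parse_smiles("C/C=C/C")
  expect_equal(length(find_substructure_matches(undef_b, def_b)), 1)
  expect_equal(length(find_substructure_matches(def_b, undef_b)), 0)
})

test_that("cis/trans matching compares configurations through the mapping", {
  trans <- parse_smiles("C/C=C/C")
  cis <- parse_smiles("C/C=C\\C")
  expect_equal(length(find_substructure_matches(trans, trans)), 1)
  expect_equal(length(find_substructure_matches(trans, cis)), 0)
  expect_equal(length(find_substructure_matches(trans, cis,
                                                match_cis_trans = FALSE)), 1)
})

test_that("matcher equals the exhaustive-embedding oracle on small pairs", {
  queries <- c("C", "CC", "CCC", "CCO", "C=O", "C(=O)N", "CN", "CO",
               "C=C", "C1CCCCC1", "c1ccccc1", "C(=O)O")
  supers <- c("CC(=O)NC", "CCO", "CC(C)CO", "c1ccccc1C(=O)O",
              "O=C1CCCCC1", "CC(=O)Oc1ccccc1C(=O)O", "CCCCCC",
              "C1CCCCC1", "OCC(O)CO", "CNC(=O)CNC(=O)C")
  for (q in queries) {
    subq <- parse_smiles(q)
    for (p in supers) {
      sup <- parse_smiles(p)
      mine <- find_substructure_matches(subq, sup, match_chiral = FALSE,
                                        match_cis_trans = FALSE)
      mine_sets <- sort(vapply(mine, function(m) {
        paste(m$atoms, collapse = ",")
      }, character(1)))
      oracle <- oracle_embeddings(subq, sup)
      oracle_sets <- sort(vapply(oracle, paste, character(1), collapse = ","))
      expect_equal(mine_sets, oracle_sets, label = paste(q, "in", p))
    }
  }
})

test_that("matcher equals the oracle on stereo pairs in both modes", {
  pairs <- list(
    c("N[C@@H](C)C(=O)O", "CC(=O)N[C@@H](C)C(=O)O"),
    c("N[C@@H](C)C(=O)O", "CC(=O)N[C@H](C)C(=O)O"),
    c("C/C=C/C", "C/C=C/CCC"),
    c("C/C=C/C", "C/C=C\\CCC"))
  for (pr in pairs) {
    subq <- parse_smiles(pr[[1]])
    sup <- parse_smiles(pr[[2]])
    # stereo-blind mode must equal the topological oracle
    blind <- find_substructure_matches(subq, sup, match_chiral = FALSE,
                                       match_cis_trans = FALSE)
    expect_equal(length(blind), length(oracle_embeddings(subq, sup)),
                 label = paste(pr, collapse = " in "))
    # stereo-aware matches are a subset of stereo-blind matches
    aware <- find_substructure_matches(subq, sup)
    aware_sets <- vapply(aware, function(m) paste(m$atoms, collapse = ","),
                         character(1))
    blind_sets <- vapply(blind, function(m) paste(m$atoms, collapse = ","),
                         character(1))
    expect_true(all(aware_sets %in% blind_sets))
  }
})

test_that("matches on generated molecules agree with the oracle", {
  smis <- generate_test_smiles(fixture_spec(seed = 31, count = 8,
                                            size_range = c(4L, 10L)))
  queries <- c("CC", "CCO", "C=C", "CN", "C(F)Cl")
  for (p in smis) {
    sup <- parse_smiles(p)
    for (q in queries) {
      subq <- parse_smiles(q)
      mine <- find_substructure_matches(subq, sup, match_chiral = FALSE,
                                        match_cis_trans = FALSE)
      oracle <- oracle_embeddings(subq, sup)
      expect_equal(length(mine), length(oracle), label = paste(q, "in", p))
    }
  }
})

test_that("highlighting recolours exactly the matched atoms and bonds", {
  parent <- parse_smiles("CC(=O)NC")
  m <- find_substructure_matches(parse_smiles("C(=O)N"), parent)
  d <- highlight_matches(parent, m, "red")
  expect_setequal(as.integer(names(d$atom_colour)), m[[1]]$atoms)
  expect_setequal(as.integer(names(d$bond_colour)), m[[1]]$bonds)
  expect_true(all(unlist(d$atom_colour) == "#ff0000"))

  # no matches: drawing identical to a plain render
  d0 <- highlight_matches(parent, list(), "red")
  plain <- layout_molecule(parent)
  expect_identical(d0$coords, plain$coords)
  expect_equal(length(d0$atom_colour), 0)

  # two substructure sets in two colours
  m2 <- list(find_substructure_matches(parse_smiles("C=O"), parent),
             find_substructure_matches(parse_smiles("NC"), parent))
  d2 <- highlight_matches(parent, m2, c("#00ff00", "blue"))
  expect_true("#00ff00" %in% unlist(d2$atom_colour))
  expect_true("#0000ff" %in% unlist(d2$atom_colour))
})
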