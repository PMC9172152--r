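# Reaction targets and graph-edit reactions.

test_that("target definitions locate bonds through substructure search", {
  peptide <- target_definition("C(=O)NC", 0, 2, name = "peptide bond")
  hits <- find_targets(peptide, parse_smiles("CC(=O)NC"))
  expect_equal(length(hits), 1)
  b <- hits[[1]]
  s <- parse_smiles("CC(=O)NC")
  expect_setequal(c(s$atoms[[as.character(b$a)]]$element,
                    s$atoms[[as.character(b$b)]]$element), c("C", "N"))

  expect_equal(length(find_targets(peptide, parse_smiles("CCCCO"))), 0)
  # a diketopiperazine carries two amide bonds
  expect_equal(length(find_targets(peptide, parse_smiles("O=C1CNC(=O)CN1"))), 2)

  expect_error(target_definition("C(=O)NC", 0, 7), "heavy-atom count")
  expect_error(target_definition("C(=O)NC", 0, 3), "not bonded")
})

test_that("bond breaking caps both ends with hydrogen", {
  s <- parse_smiles("CCCC")
  prods <- split_disconnected(break_bond(s, bond_between(s, 1, 2)))
  expect_equal(length(prods), 2)
  expect_setequal(vapply(prods, write_smiles, character(1)), c("CC", "CC"))
  for (p in prods) expect_silent(refresh_structure(p))
})

test_that("bond making consumes hydrogens and revalidates", {
  s <- parse_smiles("CC.CC")
  comp <- graph_components(s)
  joined <- make_bond(s, 1, 2)
  expect_equal(length(graph_components(joined)), 1)
  expect_equal(write_smiles(joined), "CCCC")
  expect_silent(refresh_structure(joined))
  # no free valence: fluorine already saturated
  s2 <- parse_smiles("FC.C")
  expect_error(make_bond(s2, 0, 2), "free valence|bonding laws")
})

test_that("atom addition and removal keep valences legal", {
  s <- parse_smiles("CC")
  s2 <- add_atom(s, 0, "O")
  expect_true(structures_isomorphic(s2, parse_smiles("CCO")))
  expect_silent(refresh_structure(s2))

  s3 <- remove_atom(parse_smiles("CCO"), 2)
  expect_equal(write_smiles(s3), "CC")

  # removing a ring atom leaves an open chain, capped with hydrogens
  ring <- parse_smiles("C1CCCCC1")
  open <- remove_atom(ring, 0)
  expect_equal(length(open$rings$sssr), 0)
  expect_equal(write_smiles(open), "CCCCC")
  expect_silent(refresh_structure(open))
})

test_that("atom indices are never reused after deletion", {
  s <- parse_smiles("CCO")
  n0 <- s$next_atom_index
  s <- remove_atom(s, 2)
  s <- add_atom(s, 0, "N")
  new_idx <- setdiff(vapply(s$atoms, function(a) a$index, integer(1)), 0:(n0 - 1))
  expect_true(all(new_idx >= n0))
})

test_that("split_disconnected partitions atoms and preserves annotations", {
  s <- parse_smiles("CCO")
  expect_equal(length(split_disconnected(s)), 1)

  s2 <- parse_smiles("CC.O.[Na+]")
  parts <- split_disconnected(s2)
  expect_equal(length(parts), 3)
  all_atoms <- sort(unlist(lapply(parts, function(p) {
    vapply(p$atoms, function(a) a$index, integer(1))
  })))
  expect_equal(all_atoms, sort(vapply(s2$atoms, function(a) a$index,
                                      integer(1))))

  s3 <- annotate(parse_smiles("CC(=O)NC"), "origin", "x")
  prods <- hydrolyse(s3, find_targets(target_definition("C(=O)NC", 0, 2),
                                      s3)[[1]])
  expect_true(all(vapply(prods, function(p) {
    "origin" %in% p$annotation_names
  }, logical(1))))
})

test_that("hydrolysis and condensation are inverse up to graph isomorphism", {
  peptide <- target_definition("C(=O)NC", 0, 2)
  amides <- c("CC(=O)NC", "CCC(=O)NCC", "CC(C)C(=O)NC", "CC(=O)NCCO",
              "c1ccccc1C(=O)NC")
  for (smi in amides) {
    s <- parse_smiles(smi)
    b <- find_targets(peptide, s)[[1]]
    prods <- hydrolyse(s, b)
    expect_equal(length(prods), 2)
    for (p in prods) expect_silent(refresh_structure(p))
    # find the acyl carbon (has =O and -OH) and the amine nitrogen
    acid <- prods[[1]]; amine <- prods[[2]]
    acyl <- NULL
    for (a in acid$atoms) {
      if (a$element != "C") next
      nb <- neighbours(acid, a$index)
      has_dbl_o <- any(vapply(nb, function(j) {
        acid$atoms[[as.character(j)]]$element == "O" &&
          bond_between(acid, a$index, j)$type == "double"
      }, logical(1)))
      if (has_dbl_o) acyl <- a$index
    }
    nidx <- Filter(function(a) a$element == "N", amine$atoms)[[1]]$index
    back <- condense(acid, amine, acyl, nidx)
    expect_true(structures_isomorphic(back, s), label = smi)
  }
})

test_that("hydrolysing a plain C-C bond is rejected", {
  s <- parse_smiles("CCCC")
  err <- tryCatch(hydrolyse(s, bond_between(s, 1, 2)), error = function(e) e)
  expect_s3_class(err, "chemkit_structure_error")
})

test_that("ketoreduction turns the carbonyl into an annotated hydroxyl", {
  # beta-keto group in a thioester-bound diketide chain
  s <- parse_smiles("CC(=O)CC(=O)SC")
  keto <- target_definition("CC(=O)CC(=O)S", 1, 2)
  b <- find_targets(keto, s)[[1]]
  red <- ketoreduce(s, b)
  expect_silent(refresh_structure(red))
  expect_equal(write_smiles(red), "CC(O)CC(=O)SC")
  # the reduced carbon and oxygen are annotated for highlighting
  marked <- Filter(function(a) {
    identical(get_annotation(red, a$index, "ketoreduction"), "reduced")
  }, red$atoms)
  expect_equal(length(marked), 2)

  # applying the reduction again at the same position fails
  err <- tryCatch(ketoreduce(red, b$index), error = function(e) e)
  expect_s3_class(err, "chemkit_structure_error")

  # product and substrate fingerprints differ
  expect_false(identical(ecfp(red)$ids, ecfp(s)$ids))
})

test_that("random edits keep structures valence-valid", {
  smis <- generate_test_smiles(fixture_spec(seed = 77, count = 6))
  set.seed(5)
  for (smi in smis) {
    s <- parse_smiles(smi)
    with_h <- Filter(function(a) {
      a$element != "H" && any(vapply(neighbours(s, a$index), function(j) {
        s$atoms[[as.character(j)]]$element == "H"
      }, logical(1)))
    }, s$atoms)
    v <- with_h[[sample(length(with_h), 1)]]$index
    edited <- add_atom(s, v, "C")
    expect_silent(refresh_structure(edited))
    singles <- Filter(function(b) {
      b$type == "single" &&
        edited$atoms[[as.character(b$a)]]$element != "H" &&
        edited$atoms[[as.character(b$b)]]$element != "H"
    }, edited$bonds)
    if (length(singles)) {
      edited2 <- break_bond(edited, singles[[sample(length(singles), 1)]])
      expect_silent(refresh_structure(edited2))
    }
  }
})
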