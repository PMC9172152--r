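# SMILES reading and writing.

test_that("basic parsing materialises implicit hydrogens", {
  s <- parse_smiles("C")
  expect_equal(length(s$atoms), 5)   # C + 4 H
  expect_equal(sum(vapply(s$atoms, function(a) a$element == "H",
                          logical(1))), 4)

  s <- parse_smiles("[CH3]")
  expect_equal(sum(vapply(s$atoms, function(a) a$element == "H",
                          logical(1))), 3)

  # pyrrole nitrogen: valence 3 - 2 ring bonds = 1 hydrogen
  s <- parse_smiles("N1C=CC=C1")
  n_idx <- Filter(function(a) a$element == "N", s$atoms)[[1]]$index
  expect_equal(sum(vapply(neighbours(s, n_idx), function(j) {
    s$atoms[[as.character(j)]]$element == "H"
  }, logical(1))), 1)
})

test_that("benzene is perceived as one aromatic system over one SSSR ring", {
  s <- parse_smiles("c1ccccc1")
  expect_equal(length(s$rings$sssr), 1)
  expect_equal(length(s$aromatic_systems), 1)
  expect_equal(s$aromatic_systems[[1]]$pi_electrons, 6)
  arom <- vapply(s$atoms, function(a) a$aromatic, logical(1))
  expect_equal(sum(arom), 6)
})

test_that("valency selection prefers the smallest achievable valency", {
  sulphur <- new_atom(0, "S")
  expect_equal(assign_valency(sulphur, 6), 6)
  expect_equal(assign_valency(sulphur, 3), 4)
  expect_equal(assign_valency(sulphur, 2), 2)
  phosphorus <- new_atom(0, "P")
  expect_equal(assign_valency(phosphorus, 3), 3)
  expect_equal(assign_valency(phosphorus, 4), 5)
  carbon <- new_atom(0, "C")
  err <- tryCatch(assign_valency(carbon, 5), error = function(e) e)
  expect_s3_class(err, "chemkit_structure_error")
  expect_equal(err$category, "bonding-law violation")
})

test_that("the nitro tolerance rewrites pentavalent nitrogen", {
  s <- parse_smiles("CN(=O)=O")
  n <- Filter(function(a) a$element == "N", s$atoms)[[1]]
  expect_equal(n$valency, 4)
  expect_equal(n$charge, 1)
  o_charges <- sort(unname(vapply(Filter(function(a) a$element == "O", s$atoms),
                           function(a) a$charge, integer(1))))
  expect_equal(o_charges, c(-1L, 0L))
  # one N-O bond became single, one stayed double
  n_bonds <- vapply(s$adj[[as.character(n$index)]], function(bi) {
    s$bonds[[as.character(bi)]]$type
  }, character(1))
  expect_setequal(unname(table(n_bonds)[c("single", "double")]), c(2, 1))

  # a trivalent amine is untouched by the correction
  s2 <- parse_smiles("CN(C)C")
  n2 <- Filter(function(a) a$element == "N", s2$atoms)[[1]]
  expect_equal(n2$valency, 3)
  expect_equal(n2$charge, 0)
})

test_that("pentavalent nitrogen without a doubly bonded oxygen is a bonding-law error", {
  err <- tryCatch(parse_smiles("CN(C)(C)(C)C"), error = function(e) e)
  expect_s3_class(err, "chemkit_structure_error")
  expect_equal(err$category, "bonding-law violation")
  expect_equal(conditionMessage(err),
               'Error parsing "CN(C)(C)(C)C": Basic bonding laws have been violated')
})

test_that("conflicting directional marks raise the documented stereo error", {
  err <- tryCatch(parse_smiles("F/C(\\Cl)=C(F)/Cl"), error = function(e) e)
  expect_s3_class(err, "chemkit_structure_error")
  expect_equal(err$category, "conflicting double-bond stereochemistry")
  expect_equal(conditionMessage(err),
               'Error parsing "F/C(\\Cl)=C(F)/Cl": Conflicting double bond stereochemistry')
})

test_that("syntax errors are reported with the offending SMILES", {
  for (bad in c("C(C", "C)C", "C1CC", "[C", "C=", "C%1")) {
    err <- tryCatch(parse_smiles(bad), error = function(e) e)
    expect_s3_class(err, "chemkit_structure_error")
    expect_equal(err$category, "syntax error", label = bad)
    expect_match(conditionMessage(err), "^Error parsing", label = bad)
  }
})

test_that("isotope digits are accepted and ignored", {
  a <- parse_smiles("[13CH4]")
  b <- parse_smiles("C")
  expect_true(structures_isomorphic(a, b))
  expect_equal(write_smiles(a), "C")
  c13 <- parse_smiles("C[13CH](C)C")
  c12 <- parse_smiles("CC(C)C")
  expect_true(structures_isomorphic(c13, c12))
})

test_that("cis/trans perception stores reference substituents and configuration", {
  s <- parse_smiles("C/C=C/C")
  b <- Filter(function(b) b$type == "double", s$bonds)[[1]]
  expect_equal(b$stereo$config, "trans")
  s <- parse_smiles("C/C=C\\C")
  b <- Filter(function(b) b$type == "double", s$bonds)[[1]]
  expect_equal(b$stereo$config, "cis")
  # undirectional double bonds carry no stereo
  s <- parse_smiles("CC=CC")
  b <- Filter(function(b) b$type == "double", s$bonds)[[1]]
  expect_null(b$stereo)
})

test_that("writing is kekulised and round trips preserve the labelled graph", {
  expect_equal(write_smiles(parse_smiles("C")), "C")
  expect_false(grepl("c", write_smiles(parse_smiles("c1ccccc1"))))
  for (smi in curated_smiles()) {
    s <- parse_smiles(smi)
    rt <- parse_smiles(write_smiles(s))
    expect_true(structures_isomorphic(s, rt), label = smi)
  }
})

test_that("round trips agree with an external canonicaliser, stereo included", {
  smis <- curated_smiles()
  written <- vapply(smis, function(x) write_smiles(parse_smiles(x)),
                    character(1))
  canon_in <- rdkit_canon(smis)
  canon_out <- rdkit_canon(written)
  expect_equal(canon_out, canon_in)
})

test_that("alternative spellings parse to identical graphs", {
  pairs <- list(c("c1ccccc1", "C1=CC=CC=C1"),
                c("CCO", "OCC"),
                c("CC(=O)O", "OC(C)=O"),
                c("N[C@@H](C)C(=O)O", "C[C@H](N)C(=O)O"))
  for (p in pairs) {
    expect_true(structures_isomorphic(parse_smiles(p[[1]]),
                                      parse_smiles(p[[2]])),
                label = paste(p, collapse = " vs "))
  }
})
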