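# Cycle enumeration, SSSR, aromaticity, kekulisation.

test_that("elementary cycle counts match hand-derived cases", {
  expect_equal(length(enumerate_simple_cycles(parse_smiles("CCCC"))), 0)
  expect_equal(length(enumerate_simple_cycles(parse_smiles("c1ccccc1"))), 1)
  # two triangles sharing an edge: two 3-cycles plus the outer 4-cycle
  s <- build_structure(
    lapply(0:3, function(i) new_atom(i, "C")),
    list(new_bond(0, 0, 1), new_bond(1, 1, 2), new_bond(2, 0, 2),
         new_bond(3, 1, 3), new_bond(4, 2, 3)))
  cyc <- enumerate_simple_cycles(s)
  expect_equal(sort(lengths(cyc)), c(3, 3, 4))
})

test_that("cycle enumeration equals the subset-enumeration oracle on random graphs", {
  for (i in 1:40) {
    s <- random_graph_structure(n = sample(4:10, 1),
                                extra_edges = sample(0:4, 1), seed = 1000 + i)
    mine <- sort(vapply(enumerate_simple_cycles(s), canonical_cycle_key,
                        character(1)))
    oracle <- sort(vapply(oracle_cycles(s), canonical_cycle_key,
                          character(1)))
    expect_equal(mine, oracle, label = paste("graph", i))
  }
})

test_that("the cycle-count guard rejects pathologically fused inputs", {
  s <- random_graph_structure(n = 12, extra_edges = 20, seed = 99)
  expect_error(enumerate_simple_cycles(s, limit = 10), "cycle")
})

test_that("SSSR picks the expected rings for textbook cases", {
  expect_equal(lengths(find_sssr(parse_smiles("c1ccccc1"))), 6)
  # naphthalene: two six-rings, never the ten-ring
  expect_equal(sort(lengths(find_sssr(parse_smiles("c1ccc2ccccc2c1")))),
               c(6, 6))
  # cubane: 12 bonds - 8 atoms + 1 = 5 four-rings
  expect_equal(sort(lengths(find_sssr(parse_smiles("C12C3C4C1C5C2C3C45")))),
               rep(4, 5))
})

test_that("SSSR size equals the cyclomatic number and basis sizes are minimal", {
  for (i in 1:60) {
    s <- random_graph_structure(n = sample(5:12, 1),
                                extra_edges = sample(0:4, 1), seed = 2000 + i)
    sssr <- find_sssr(s)
    n_expect <- length(s$bonds) - length(s$atoms) + length(graph_components(s))
    expect_equal(length(sssr), n_expect, label = paste("graph", i))
    if (n_expect == 0) next
    # independence over GF(2) in bond space
    all_bonds <- sort(vapply(s$bonds, function(b) b$index, integer(1)))
    vecs <- lapply(sssr, function(cyc) cycle_bond_vector(s, cyc, all_bonds))
    expect_equal(gf2_rank(vecs), n_expect, label = paste("independence", i))
    # size-minimality against a greedy basis over oracle cycles (the size
    # multiset of a minimum cycle basis is unique)
    oracle <- oracle_cycles(s)
    oracle <- oracle[order(lengths(oracle))]
    sizes <- integer()
    basis <- list()
    for (cyc in oracle) {
      cand <- c(basis, list(cycle_bond_vector(s, cyc, all_bonds)))
      if (gf2_rank(cand) > length(basis)) {
        basis <- cand
        sizes <- c(sizes, length(cyc))
        if (length(sizes) == n_expect) break
      }
    }
    expect_equal(sort(lengths(sssr)), sort(sizes),
                 label = paste("minimality", i))
  }
})

test_that("Hueckel perception labels the classic aromatics and rejects antiaromatics", {
  expect_equal(length(parse_smiles("c1ccccc1")$rings$aromatic), 1)
  expect_equal(length(parse_smiles("C1=CC=CC=C1")$rings$aromatic), 1)
  # cyclobutadiene: 2 double bonds, even sum, not aromatic
  expect_equal(length(parse_smiles("C1=CC=C1")$rings$aromatic), 0)
  # cyclohexane: no pi system at all
  expect_equal(length(parse_smiles("C1CCCCC1")$rings$aromatic), 0)
  # pyrrole through nitrogen lone-pair promotion
  s <- parse_smiles("C1=CC=CN1")
  expect_equal(length(s$rings$aromatic), 1)
  n <- Filter(function(a) a$element == "N", s$atoms)[[1]]
  expect_true(n$aromatic)
  expect_equal(n$hybridisation, "sp2")
  expect_equal(s$aromatic_systems[[1]]$pi_electrons, 6)
  # furan and thiophene donate one heteroatom lone pair each
  expect_equal(parse_smiles("c1ccoc1")$aromatic_systems[[1]]$pi_electrons, 6)
  expect_equal(parse_smiles("c1ccsc1")$aromatic_systems[[1]]$pi_electrons, 6)
})

test_that("aromaticity perception is idempotent", {
  for (smi in c("c1ccccc1", "c1cc[nH]c1", "c1ccc2ccccc2c1", "c1ccncc1",
                "C1=CC=CC=C1", "Cc1ccccc1C(=O)O")) {
    s <- parse_smiles(smi)
    before <- list(length(s$rings$aromatic),
                   vapply(s$aromatic_systems, function(x) x$pi_electrons,
                          integer(1)),
                   vapply(s$atoms, function(a) a$aromatic, logical(1)))
    s2 <- detect_aromaticity(s)
    after <- list(length(s2$rings$aromatic),
                  vapply(s2$aromatic_systems, function(x) x$pi_electrons,
                         integer(1)),
                  vapply(s2$atoms, function(a) a$aromatic, logical(1)))
    expect_identical(before, after, label = smi)
  }
})

test_that("non-kekulisable lowercase rings are rejected", {
  err <- tryCatch(parse_smiles("c1ccc1"), error = function(e) e)
  expect_s3_class(err, "chemkit_structure_error")
  expect_equal(err$category, "bonding-law violation")
})

test_that("kekulisation covers every pi-contributing atom exactly once", {
  check_kekulised <- function(smi, n_double_expected) {
    s <- parse_smiles(smi)
    sys <- s$aromatic_systems[[1]]
    ks <- kekulise(s)
    doubles <- Filter(function(b) b$index %in% sys$bonds &&
                        b$type == "double", ks$bonds)
    expect_equal(length(doubles), n_double_expected, label = smi)
    # matched-bond set is a matching covering the pi-contributing atoms
    matched_atoms <- unlist(lapply(doubles, function(b) c(b$a, b$b)))
    expect_false(any(duplicated(matched_atoms)), label = smi)
    contributors <- as.integer(names(sys$contribution)[sys$contribution == 1])
    expect_setequal(matched_atoms, contributors)
    expect_silent(refresh_structure(ks))
  }
  check_kekulised("c1ccccc1", 3)
  check_kekulised("c1ccc2ccccc2c1", 5)
  check_kekulised("c1cc[nH]c1", 2)  # the N lone-pair donor stays unmatched
})

test_that("blossom maximum matching agrees with the brute-force oracle", {
  set.seed(11)
  for (i in 1:40) {
    n <- sample(3:10, 1)
    all_edges <- t(combn(n, 2))
    m <- sample(seq_len(nrow(all_edges)), min(nrow(all_edges),
                                              sample(2:14, 1)))
    edges <- lapply(m, function(r) all_edges[r, ])
    mm <- maximum_matching(n, edges)
    size <- sum(mm > 0) / 2
    expect_equal(size, oracle_max_matching_size(n, edges),
                 label = paste("graph", i))
    # symmetry of the matching array
    for (v in seq_len(n)) {
      if (mm[v] > 0) expect_equal(mm[mm[v]], v)
    }
  }
})

test_that("kekulised double-bond counts equal the brute-force matching optimum", {
  for (smi in c("c1ccccc1", "c1ccc2ccccc2c1", "c1cc[nH]c1", "c1ccncc1",
                "c1ccc2[nH]ccc2c1", "c1ccc2ccc3ccccc3c2c1")) {
    s <- parse_smiles(smi)
    for (sys in s$aromatic_systems) {
      contributors <- as.integer(names(sys$contribution)[sys$contribution == 1])
      edges <- list()
      for (bi in sys$bonds) {
        b <- s$bonds[[as.character(bi)]]
        u <- match(b$a, contributors); v <- match(b$b, contributors)
        if (!is.na(u) && !is.na(v)) edges[[length(edges) + 1L]] <- c(u, v)
      }
      optimum <- oracle_max_matching_size(length(contributors), edges)
      ks <- kekulise(s)
      n_double <- sum(vapply(ks$bonds, function(b) {
        b$index %in% sys$bonds && b$type == "double"
      }, logical(1)))
      expect_equal(n_double, optimum, label = smi)
      expect_equal(n_double, length(contributors) / 2, label = smi)
    }
  }
})
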