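# 2D layout, clash handling, wedges, rendering and MOL output.

test_that("ring classification follows the three-way definition", {
  expect_equal(classify_rings(parse_smiles("C1CCCCC1"))$labels, "simple")
  expect_equal(classify_rings(parse_smiles("c1ccc2ccccc2c1"))$labels,
               c("overlapping", "overlapping"))
  # norbornane: rings share 3 atoms
  rc <- classify_rings(parse_smiles("C1CC2CCC1C2"))
  expect_true(all(rc$labels == "bridged"))
  expect_equal(length(rc$systems), 1)
  # a spiro pair overlaps in exactly one atom
  expect_equal(classify_rings(parse_smiles("C1CCC2(CC1)CCCC2"))$labels,
               c("overlapping", "overlapping"))
})

test_that("bonded atoms sit one bond length apart outside bridged systems", {
  for (smi in c("CC", "CCCCCC", "c1ccccc1", "c1ccc2ccccc2c1",
                "CC(C)(C)C", "CC(=O)Oc1ccccc1C(=O)O")) {
    d <- layout_molecule(parse_smiles(smi))
    ks <- d$structure
    for (b in ks$bonds) {
      ka <- as.character(b$a); kb <- as.character(b$b)
      if (ks$atoms[[ka]]$element == "H" || ks$atoms[[kb]]$element == "H") next
      len <- sqrt(sum((d$coords[ka, ] - d$coords[kb, ])^2))
      expect_true(abs(len - 1) <= 0.2, label = paste(smi, b$a, b$b, len))
    }
  }
})

test_that("ethane is two atoms at unit distance", {
  d <- layout_molecule(parse_smiles("CC"))
  expect_equal(sqrt(sum((d$coords["0", ] - d$coords["1", ])^2)), 1,
               tolerance = 1e-9)
})

test_that("a four-branch centre uses 90-degree angles", {
  d <- layout_molecule(parse_smiles("CC(C)(C)C"))
  ctr <- d$coords["1", ]
  angs <- sort(vapply(c("0", "2", "3", "4"), function(k) {
    atan2(d$coords[k, 2] - ctr[2], d$coords[k, 1] - ctr[1])
  }, numeric(1)))
  gaps <- round(unname(diff(c(angs, angs[1] + 2 * pi)) * 180 / pi))
  expect_equal(gaps, rep(90, 4))
})

test_that("declared cis/trans is drawn as declared", {
  geometry_ok <- function(smi) {
    d <- layout_molecule(parse_smiles(smi))
    s <- d$structure
    ok <- TRUE
    for (b in s$bonds) {
      if (b$type != "double" || is.null(b$stereo)) next
      pa <- d$coords[as.character(b$a), ]; pb <- d$coords[as.character(b$b), ]
      ra <- d$coords[as.character(b$stereo$ref_a), ]
      rb <- d$coords[as.character(b$stereo$ref_b), ]
      ax <- pb - pa
      cs <- function(v, w) sign(v[1] * w[2] - v[2] * w[1])
      same <- cs(ax, ra - pa) == cs(ax, rb - pb)
      ok <- ok && (same == (b$stereo$config == "cis"))
    }
    ok
  }
  # the amino group must land cis to the methyl across the double bond
  expect_true(geometry_ok("C/C=C(\\N)/C"))
  for (smi in c("C/C=C/C", "C/C=C\\C", "F/C=C/F", "F/C=C\\F",
                "c1ccc(cc1)/C=C/c1ccccc1", "C/C=C/C=C/C", "C/C=C\\C=C\\C")) {
    expect_true(geometry_ok(smi), label = smi)
  }
})

test_that("clash detection applies the strict half-bond-length rule", {
  s <- parse_smiles("CCCC")
  d <- layout_molecule(s, draw_options(finetune = FALSE))
  # force coordinates: terminal atoms close together, bonded atoms closer
  d$coords["0", ] <- c(0, 0); d$coords["1", ] <- c(1, 0)
  d$coords["2", ] <- c(1.5, 0.6); d$coords["3", ] <- c(0.4, 0)
  cl <- detect_clashes(d)
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$a, cl$b), c(0, 3))

  # neighbours are exempt however close
  d$coords["1", ] <- c(0.3, 0); d$coords["2", ] <- c(2, 1)
  d$coords["3", ] <- c(3, 1)
  expect_equal(nrow(detect_clashes(d)), 0)

  # exactly at the threshold is no clash (strict less-than); the chain is
  # built so every bond has length exactly 1 (mean bond length 1)
  d$coords["0", ] <- c(0, 0); d$coords["1", ] <- c(1, 0)
  d$coords["2", ] <- c(0.75, 0.9682458)
  d$coords["3", ] <- c(0.5, 0)
  expect_equal(nrow(detect_clashes(d)), 0)
  # a hair closer and it counts
  d$coords["3", ] <- c(0.499, 0)
  d$coords["2", ] <- c(0.7495, 0.9682463)
  expect_equal(nrow(detect_clashes(d)), 1)
})

test_that("finetuning resolves a folded chain and never increases clashes", {
  s <- parse_smiles("CCCCCCCC")
  d <- layout_molecule(s, draw_options(finetune = FALSE))
  # fold the tail back onto the head around the middle bond
  for (k in c("5", "6", "7")) {
    d$coords[k, ] <- d$coords[as.character(7 - as.integer(k)), ] + c(0.1, 0.1)
  }
  before <- nrow(detect_clashes(d))
  expect_gt(before, 0)
  after <- nrow(detect_clashes(finetune(d)))
  expect_lte(after, before)
  expect_equal(after, 0)
})

test_that("finetuning leaves clash-free and rigid drawings unchanged", {
  d <- layout_molecule(parse_smiles("CCCC"), draw_options(finetune = FALSE))
  expect_equal(nrow(detect_clashes(d)), 0)
  expect_identical(finetune(d)$coords, d$coords)

  # a clash inside a ring has no rotatable bond: unchanged
  d2 <- layout_molecule(parse_smiles("C1CCCCC1"), draw_options(finetune = FALSE))
  d2$coords["3", ] <- d2$coords["0", ] + c(0.2, 0)
  expect_identical(finetune(d2)$coords, d2$coords)
})

test_that("wedges follow the priority rules", {
  # exactly one wedge at the alanine alpha-carbon
  d <- layout_molecule(parse_smiles("N[C@@H](C)C(=O)O"))
  expect_equal(length(d$bond_style), 1)
  wedge_bond <- d$structure$bonds[[names(d$bond_style)[[1]]]]
  expect_true(1 %in% c(wedge_bond$a, wedge_bond$b))
  expect_true(d$bond_style[[1]] %in% c("wedge_up", "wedge_down"))

  # achiral molecules carry no wedges
  expect_equal(length(layout_molecule(parse_smiles("CCO"))$bond_style), 0)

  # a ring stereocentre wedges its exocyclic branch, not a ring bond
  d3 <- layout_molecule(parse_smiles("C[C@H]1CCCO1"))
  expect_equal(length(d3$bond_style), 1)
  wb <- d3$structure$bonds[[names(d3$bond_style)[[1]]]]
  ring_atoms <- d3$structure$rings$sssr[[1]]
  expect_false(wb$a %in% ring_atoms && wb$b %in% ring_atoms)
})

test_that("SVG output suppresses carbon labels and honours colours", {
  d <- layout_molecule(parse_smiles("c1ccccc1"))
  svg_path <- tempfile(fileext = ".svg")
  render(d, svg_path)
  svg <- readLines(svg_path)
  expect_equal(sum(grepl("<line", svg)), 9)  # 3 single + 3 double bonds
  expect_equal(sum(grepl("<text", svg)), 0)

  d$atom_colour[["0"]] <- "#ff0000"
  d$bond_colour[["0"]] <- "#ff0000"
  render(d, svg_path)
  expect_true(any(grepl("#ff0000", readLines(svg_path))))

  # colour names resolve, unknown names fail
  d2 <- highlight_matches(parse_smiles("CCO"),
                          find_substructure_matches(parse_smiles("CO"),
                                                    parse_smiles("CCO")),
                          colours = "firebrick")
  expect_true(length(d2$atom_colour) > 0)
  expect_error(highlight_matches(parse_smiles("CCO"), list(), "notacolour"),
               "unknown colour")
})

test_that("font/bond ratios are constant across drawings", {
  ratio_of <- function(smi) {
    p <- tempfile(fileext = ".svg")
    render(layout_molecule(parse_smiles(smi)), p)
    svg <- paste(readLines(p), collapse = "\n")
    font <- as.numeric(sub('.*font-size="([0-9.]+)".*', "\\1", svg))
    font
  }
  # same font size (same pixel-per-bond scale) for different molecules
  expect_equal(ratio_of("CCO"), ratio_of("CC(=O)Oc1ccccc1C(=O)O"))
})

test_that("PNG rendering writes a file", {
  p <- tempfile(fileext = ".png")
  render(layout_molecule(parse_smiles("c1ccccc1O")), p)
  expect_true(file.exists(p) && file.size(p) > 0)
})

test_that("MOL V2000 output has the documented shape", {
  p <- tempfile(fileext = ".mol")
  write_molfile(layout_molecule(parse_smiles("CCO")), p)
  mol <- readLines(p)
  expect_match(mol[4], "^  3  2")  # heavy atoms only, hydrogens suppressed
  expect_equal(mol[length(mol)], "M  END")

  # chiral centre: exactly one bond with stereo flag 1 or 6
  p2 <- tempfile(fileext = ".mol")
  write_molfile(layout_molecule(parse_smiles("N[C@@H](C)C(=O)O")), p2)
  mol2 <- readLines(p2)
  counts <- as.integer(c(substr(mol2[4], 1, 3), substr(mol2[4], 4, 6)))
  bond_lines <- mol2[(4 + counts[1] + 1):(4 + counts[1] + counts[2])]
  flags <- trimws(substr(bond_lines, 10, 12))
  expect_equal(sum(flags %in% c("1", "6")), 1)

  # charges appear as M CHG lines
  p3 <- tempfile(fileext = ".mol")
  write_molfile(layout_molecule(parse_smiles("CC(=O)[O-]")), p3)
  expect_true(any(grepl("^M  CHG  1", readLines(p3))))
})

test_that("an independent reader recovers molecule, stereo included, from MOL files", {
  smis <- c("CCO", "N[C@@H](C)C(=O)O", "C[C@@H](O)CC", "C/C=C/C",
            "C/C=C\\C", "CC(=O)[O-]", "c1ccc2[nH]ccc2c1", "C[C@H]1CCCO1")
  paths <- vapply(smis, function(smi) {
    p <- tempfile(fileext = ".mol")
    write_molfile(layout_molecule(parse_smiles(smi)), p)
    p
  }, character(1))
  got <- rdkit_mol_to_smiles(paths)
  want <- rdkit_canon(smis)
  expect_equal(got, want)
})

test_that("undepictable ring cis/trans raises a chirality error", {
  # trans double bond inside a cyclopentene ring cannot be drawn
  err <- tryCatch(layout_molecule(parse_smiles("C1C/C=C\\C1CC")),
                  error = function(e) e)
  # the cis form in a 5-ring is fine either way; the hard conflict is a
  # ring-internal trans with both references ring-bound:
  err2 <- tryCatch(layout_molecule(parse_smiles("C1CC/C=C/C1")),
                   error = function(e) e)
  expect_true(inherits(err2, "chemkit_chirality_error") ||
                inherits(err2, "chemkit_drawing"))
})
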