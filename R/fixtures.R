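# Seeded generator of valid test molecules.
#
# Molecules are assembled as graphs (not strings): a random heavy-atom
# backbone tree with optional feature motifs (extra ring bond, fused
# benzene/pyridine, charged groups, a halogenated stereocentre, a
# stereo-restricted double bond), then finalised through the same valence /
# hydrogen / electron / aromaticity pipeline as parsed molecules and
# written out with the SMILES writer. Every emitted SMILES therefore
# parses back without error by construction.

with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specification for the molecule generator
#'
#' @param seed integer seed; the same spec always yields the same list.
#' @param count number of molecules (> 0).
#' @param size_range heavy-atom count range targeted per molecule.
#' @param rings,aromatics,charges,stereocentres,cis_trans feature toggles;
#'   each enabled feature is guaranteed at least once per batch.
#' @return a `chemkit_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, count = 10L, size_range = c(4L, 12L),
                         rings = TRUE, aromatics = TRUE, charges = TRUE,
                         stereocentres = TRUE, cis_trans = TRUE) {
  if (count <= 0) stop("count must be > 0")
  if (rings && size_range[[2]] < 3) {
    stop("infeasible spec: rings need at least 3 heavy atoms")
  }
  if (aromatics && size_range[[2]] < 7) {
    stop("infeasible spec: aromatic rings need at least 7 heavy atoms")
  }
  if ((stereocentres || cis_trans) && size_range[[2]] < 4) {
    stop("infeasible spec: stereo features need at least 4 heavy atoms")
  }
  structure(list(seed = as.integer(seed), count = as.integer(count),
                 size_range = as.integer(size_range), rings = rings,
                 aromatics = aromatics, charges = charges,
                 stereocentres = stereocentres, cis_trans = cis_trans),
            class = "chemkit_fixture_spec")
}

# -- graph-building helpers (work on a growing Structure + free-valence map)

.builder_new <- function() {
  list(s = build_structure(list(new_atom(0, "C")), list()),
       rv = c("0" = 4L), stereo_centres = integer())
}

.builder_add_atom <- function(st, to, element, charge = 0L,
                              bond_type = "single") {
  s <- st$s
  a <- new_atom(s$next_atom_index, element, charge = charge)
  s$atoms[[ak(a$index)]] <- a
  s$adj[[ak(a$index)]] <- integer()
  s$next_atom_index <- s$next_atom_index + 1L
  ord <- round(bond_order(bond_type))
  s <- add_bond_edge(s, new_bond(s$next_bond_index, to, a$index, bond_type))
  val <- allowed_valences(element, charge)
  st$rv[[ak(a$index)]] <- (if (is.null(val)) 0L else val[[1]]) - ord
  st$rv[[ak(to)]] <- st$rv[[ak(to)]] - ord
  st$s <- s
  st
}

.builder_candidates <- function(st, need = 1L) {
  keys <- names(st$rv)[st$rv >= need]
  as.integer(keys)
}

.feature_ring <- function(st) {
  cand <- .builder_candidates(st)
  if (length(cand) < 2) return(list(st = st, ok = FALSE))
  for (a in sample(cand)) {
    others <- setdiff(cand, a)
    dists <- vapply(others, function(b) {
      length(shortest_path_atoms(st$s, a, b)) - 1L
    }, integer(1))
    pick <- others[dists >= 2 & dists <= 6]
    if (length(pick)) {
      b <- pick[sample.int(length(pick), 1)]
      if (!is.null(bond_between(st$s, a, b))) next
      st$s <- add_bond_edge(st$s, new_bond(st$s$next_bond_index, a, b))
      st$rv[[ak(a)]] <- st$rv[[ak(a)]] - 1L
      st$rv[[ak(b)]] <- st$rv[[ak(b)]] - 1L
      return(list(st = st, ok = TRUE))
    }
  }
  list(st = st, ok = FALSE)
}

.feature_aromatic <- function(st) {
  cand <- .builder_candidates(st)
  if (length(cand) == 0) return(list(st = st, ok = FALSE))
  anchor <- cand[sample.int(length(cand), 1)]
  ring_el <- if (stats::runif(1) < 0.3) c("C", "C", "N", "C", "C", "C") else rep("C", 6)
  first <- st$s$next_atom_index
  st <- .builder_add_atom(st, anchor, ring_el[[1]])
  types <- c("double", "single", "double", "single", "double")
  for (i in 2:6) {
    st <- .builder_add_atom(st, st$s$next_atom_index - 1L, ring_el[[i]],
                            bond_type = types[[i - 1]])
  }
  last <- st$s$next_atom_index - 1L
  st$s <- add_bond_edge(st$s, new_bond(st$s$next_bond_index, last, first))
  st$rv[[ak(first)]] <- st$rv[[ak(first)]] - 1L
  st$rv[[ak(last)]] <- st$rv[[ak(last)]] - 1L
  list(st = st, ok = TRUE)
}

.feature_charge <- function(st) {
  cand <- .builder_candidates(st)
  if (length(cand) == 0) return(list(st = st, ok = FALSE))
  anchor <- cand[sample.int(length(cand), 1)]
  if (stats::runif(1) < 0.5) {
    st <- .builder_add_atom(st, anchor, "O", charge = -1L)
  } else {
    st <- .builder_add_atom(st, anchor, "N", charge = 1L)
  }
  list(st = st, ok = TRUE)
}

.feature_stereocentre <- function(st) {
  cand <- .builder_candidates(st)
  cand <- cand[vapply(cand, function(i) {
    st$s$atoms[[ak(i)]]$element == "C"
  }, logical(1))]
  if (length(cand) == 0) return(list(st = st, ok = FALSE))
  anchor <- cand[sample.int(length(cand), 1)]
  centre <- st$s$next_atom_index
  st <- .builder_add_atom(st, anchor, "C")
  st <- .builder_add_atom(st, centre, "F")
  st <- .builder_add_atom(st, centre, "Cl")
  st$stereo_centres <- c(st$stereo_centres, centre)
  list(st = st, ok = TRUE)
}

.feature_cis_trans <- function(st) {
  cand <- .builder_candidates(st)
  if (length(cand) == 0) return(list(st = st, ok = FALSE))
  anchor <- cand[sample.int(length(cand), 1)]
  a <- st$s$next_atom_index
  st <- .builder_add_atom(st, anchor, "C")
  b <- st$s$next_atom_index
  st <- .builder_add_atom(st, a, "C", bond_type = "double")
  cc <- st$s$next_atom_index
  st <- .builder_add_atom(st, b, "C")
  bd <- bond_between(st$s, a, b)
  st$s$bonds[[ak(bd$index)]]$stereo <- list(
    ref_a = if (bd$a == a) anchor else cc,
    ref_b = if (bd$a == a) cc else anchor,
    config = sample(c("cis", "trans"), 1))
  list(st = st, ok = TRUE)
}

.finalise_built <- function(st) {
  s <- st$s
  s <- .assign_all_valencies(s)
  s <- add_implicit_hydrogens(s)
  s <- .allocate_electrons(s)
  s <- perceive_rings_and_aromaticity(s)
  for (i in st$stereo_centres) {
    nb <- neighbours(s, i)
    if (length(nb) == 4 && !anyDuplicated(nb)) {
      s$atoms[[ak(i)]]$chiral <- sample(c("clockwise", "counterclockwise"), 1)
      s$atoms[[ak(i)]]$chiral_order <- nb
    }
  }
  s
}

.generate_one <- function(n_backbone, features) {
  st <- .builder_new()
  elements <- c("C", "C", "C", "C", "C", "C", "C", "N", "O", "O", "S")
  while (length(st$s$atoms) < n_backbone) {
    cand <- .builder_candidates(st)
    if (length(cand) == 0) break
    anchor <- cand[sample.int(length(cand), 1)]
    el <- sample(elements, 1)
    type <- if (st$rv[[ak(anchor)]] >= 2 && el == "C" &&
                stats::runif(1) < 0.12) "double" else "single"
    st <- .builder_add_atom(st, anchor, el, bond_type = type)
  }
  ok_all <- TRUE
  for (f in features) {
    res <- switch(f,
                  ring = .feature_ring(st),
                  aromatic = .feature_aromatic(st),
                  charge = .feature_charge(st),
                  stereocentre = .feature_stereocentre(st),
                  cis_trans = .feature_cis_trans(st))
    st <- res$st
    ok_all <- ok_all && res$ok
  }
  list(s = .finalise_built(st), ok = ok_all)
}

#' Generate a seeded batch of valid SMILES
#'
#' @param spec a [fixture_spec()].
#' @return character vector of `spec$count` SMILES strings; each parses
#'   without error, and every enabled feature toggle is present in at
#'   least one molecule of the batch.
#' @examples
#' generate_test_smiles(fixture_spec(seed = 1, count = 3))
#' @export
generate_test_smiles <- function(spec) {
  vapply(generate_test_structures(spec), write_smiles, character(1))
}

#' @rdname generate_test_smiles
#' @export
generate_test_structures <- function(spec) {
  stopifnot(inherits(spec, "chemkit_fixture_spec"))
  enabled <- c(
    if (spec$rings) "ring", if (spec$aromatics) "aromatic",
    if (spec$charges) "charge", if (spec$stereocentres) "stereocentre",
    if (spec$cis_trans) "cis_trans")
  costs <- c(ring = 0L, aromatic = 6L, charge = 1L, stereocentre = 3L,
             cis_trans = 3L)
  with_seed(spec$seed, {
    out <- vector("list", spec$count)
    for (mi in seq_len(spec$count)) {
      forced <- enabled[((seq_along(enabled) - 1L) %% spec$count) + 1L ==
                          mi]
      optional <- setdiff(enabled, forced)
      feats <- c(forced, optional[stats::runif(length(optional)) < 0.3])
      for (attempt in 1:25) {
        cost <- sum(costs[feats])
        lo <- max(spec$size_range[[1]] - cost, if ("ring" %in% feats) 3L else 1L)
        hi <- max(spec$size_range[[2]] - cost, lo)
        n_backbone <- sample(seq(lo, hi), 1)
        res <- .generate_one(n_backbone, feats)
        if (res$ok) break
      }
      out[[mi]] <- res$s
    }
    out
  })
}
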