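# Reaction targets and chemically validated graph edits.
#
# Targets are defined by a substructure SMILES plus one (atom) or two
# (bond) 0-based atom indices into that substructure; occurrences are found
# by substructure search and mapped into the parent. Edits (break/make
# bonds, add/remove atoms) cap open valences with hydrogen by default;
# passing cap = "none" defers validation so multiple edits can be chained
# before a single refresh.

#' Define a reaction target
#'
#' @param smiles substructure SMILES.
#' @param i first atom index within the substructure (0-based, heavy atoms
#'   in SMILES order).
#' @param j optional second atom index; when given the target is the bond
#'   `i`-`j` (the atoms must be bonded in the substructure).
#' @param name human-readable label.
#' @return a `chemkit_target` definition.
#' @examples
#' peptide_bond <- target_definition("C(=O)NC", 0, 2, name = "peptide bond")
#' @export
target_definition <- function(smiles, i, j = NULL, name = NULL) {
  sub <- parse_smiles(smiles)
  heavy <- .heavy_atoms(sub)
  if (i >= length(heavy) || (!is.null(j) && j >= length(heavy))) {
    stop("target atom index exceeds the substructure's heavy-atom count")
  }
  if (!is.null(j)) {
    b <- bond_between(sub, heavy[[i + 1L]], heavy[[j + 1L]])
    if (is.null(b)) stop("target atoms are not bonded in the substructure")
  }
  structure(list(substructure = sub, smiles = smiles, i = as.integer(i),
                 j = if (!is.null(j)) as.integer(j),
                 name = name %||% smiles),
            class = "chemkit_target")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Locate a target definition's occurrences within a structure
#'
#' @param defn a [target_definition()].
#' @param s the parent Structure.
#' @param ... passed to [find_substructure_matches()].
#' @return for bond targets, a list of parent bond records; for atom
#'   targets, a vector of parent atom indices. One entry per substructure
#'   match.
#' @export
find_targets <- function(defn, s, ...) {
  heavy <- .heavy_atoms(defn$substructure)
  matches <- find_substructure_matches(defn$substructure, s, ...)
  if (is.null(defn$j)) {
    vapply(matches, function(m) m$mapping[[ak(heavy[[defn$i + 1L]])]],
           integer(1))
  } else {
    lapply(matches, function(m) {
      bond_between(s, m$mapping[[ak(heavy[[defn$i + 1L]])]],
                   m$mapping[[ak(heavy[[defn$j + 1L]])]])
    })
  }
}

.add_hydrogen_to <- function(s, i) {
  h <- new_atom(s$next_atom_index, "H")
  h$valency <- 1L
  s$atoms[[ak(h$index)]] <- h
  s$adj[[ak(h$index)]] <- integer()
  s$next_atom_index <- s$next_atom_index + 1L
  for (nm in s$annotation_names) s$atoms[[ak(h$index)]]$annotations[nm] <- list(NULL)
  s <- add_bond_edge(s, new_bond(s$next_bond_index, i, h$index))
  s
}

#' Graph edits: break or make bonds, add or remove atoms
#'
#' Every edit leaves the structure valence-valid when `cap = "H"`
#' (default): open valences created by the edit are filled with hydrogen
#' atoms, and [refresh_structure()] is run. With `cap = "none"` the raw
#' edited graph is returned unvalidated so several edits can be chained.
#'
#' @param s a Structure.
#' @param bond a bond record or bond index to remove.
#' @param cap `"H"` or `"none"`.
#' @return the edited Structure.
#' @export
break_bond <- function(s, bond, cap = "H") {
  b <- if (is.numeric(bond)) s$bonds[[ak(bond)]] else bond
  if (is.null(b) || is.null(s$bonds[[ak(b$index)]])) stop("no such bond")
  if (s$bonds[[ak(b$index)]]$type == "aromatic") {
    # localise the aromatic system into alternating bonds before editing
    s <- kekulise(s)
    b <- s$bonds[[ak(b$index)]]
  }
  order <- bond_order(s$bonds[[ak(b$index)]]$type)
  s$bonds[[ak(b$index)]] <- NULL
  s$adj[[ak(b$a)]] <- setdiff(s$adj[[ak(b$a)]], b$index)
  s$adj[[ak(b$b)]] <- setdiff(s$adj[[ak(b$b)]], b$index)
  for (at in c(b$a, b$b)) {
    co <- s$atoms[[ak(at)]]$chiral_order
    s$atoms[[ak(at)]]$chiral_order <- co[co != setdiff(c(b$a, b$b), at)]
    if (s$atoms[[ak(at)]]$chiral != "none") s$atoms[[ak(at)]]$chiral <- "none"
  }
  if (identical(cap, "H")) {
    for (at in c(b$a, b$b)) {
      if (s$atoms[[ak(at)]]$element == "H") next
      for (q in seq_len(round(order))) s <- .add_hydrogen_to(s, at)
    }
    s <- refresh_structure(s)
  }
  s
}

#' @rdname break_bond
#' @param a,b atom indices to join.
#' @param type bond type for the new bond.
#' @export
make_bond <- function(s, a, b, type = "single", cap = "H") {
  if (!is.null(bond_between(s, a, b))) stop("atoms are already bonded")
  # consume hydrogens to free the required valence on each end
  order <- round(bond_order(type))
  for (at in c(a, b)) {
    if (identical(cap, "H")) {
      hs <- Filter(function(j) s$atoms[[ak(j)]]$element == "H",
                   neighbours(s, at))
      if (length(hs) < order) {
        structure_error("bonding-law violation",
                        "no free valence for the new bond")
      }
      for (h in hs[seq_len(order)]) s <- remove_atom(s, h, cap = "none")
    }
  }
  s <- add_bond_edge(s, new_bond(s$next_bond_index, a, b, type))
  s$atoms[[ak(a)]]$chiral_order <- c(s$atoms[[ak(a)]]$chiral_order, b)
  s$atoms[[ak(b)]]$chiral_order <- c(s$atoms[[ak(b)]]$chiral_order, a)
  if (identical(cap, "H")) s <- refresh_structure(s)
  s
}

#' @rdname break_bond
#' @param to_atom atom index the new atom bonds to.
#' @param element element of the added atom.
#' @export
add_atom <- function(s, to_atom, element = "H", cap = "H") {
  a <- new_atom(s$next_atom_index, element)
  s$atoms[[ak(a$index)]] <- a
  s$adj[[ak(a$index)]] <- integer()
  s$next_atom_index <- s$next_atom_index + 1L
  for (nm in s$annotation_names) s$atoms[[ak(a$index)]]$annotations[nm] <- list(NULL)
  new_idx <- a$index
  if (element == "H" || identical(cap, "none")) {
    s <- add_bond_edge(s, new_bond(s$next_bond_index, to_atom, new_idx))
    s$atoms[[ak(to_atom)]]$chiral_order <-
      c(s$atoms[[ak(to_atom)]]$chiral_order, new_idx)
    s$atoms[[ak(new_idx)]]$chiral_order <- to_atom
    if (element != "H" || identical(cap, "H")) {
      if (identical(cap, "H")) s <- refresh_structure(s)
    }
    return(s)
  }
  # heavy atom with H capping: consume one H on the anchor, fill the new
  # atom's remaining valence with hydrogens
  hs <- Filter(function(j) s$atoms[[ak(j)]]$element == "H",
               neighbours(s, to_atom))
  if (length(hs) == 0) {
    structure_error("bonding-law violation",
                    "anchor atom has no hydrogen to displace")
  }
  s <- remove_atom(s, hs[[1]], cap = "none")
  s <- add_bond_edge(s, new_bond(s$next_bond_index, to_atom, new_idx))
  s$atoms[[ak(to_atom)]]$chiral_order <-
    c(s$atoms[[ak(to_atom)]]$chiral_order, new_idx)
  s$atoms[[ak(new_idx)]]$chiral_order <- to_atom
  av <- allowed_valences(element, 0L)
  if (!is.null(av)) {
    for (q in seq_len(max(0, av[[1]] - 1L))) s <- .add_hydrogen_to(s, new_idx)
  }
  refresh_structure(s)
}

#' @rdname break_bond
#' @param atom atom index to delete; its bonds are deleted with it and the
#'   former neighbours' open valences are capped.
#' @export
remove_atom <- function(s, atom, cap = "H") {
  if (is.null(s$atoms[[ak(atom)]])) stop("no such atom")
  nbs <- neighbours(s, atom)
  orders <- vapply(s$adj[[ak(atom)]], function(bi) {
    bond_order(s$bonds[[ak(bi)]]$type)
  }, numeric(1))
  for (bi in s$adj[[ak(atom)]]) {
    b <- s$bonds[[ak(bi)]]
    other <- if (b$a == atom) b$b else b$a
    s$adj[[ak(other)]] <- setdiff(s$adj[[ak(other)]], bi)
    s$bonds[[ak(bi)]] <- NULL
    co <- s$atoms[[ak(other)]]$chiral_order
    s$atoms[[ak(other)]]$chiral_order <- co[co != atom]
    if (s$atoms[[ak(other)]]$chiral != "none") {
      s$atoms[[ak(other)]]$chiral <- "none"
    }
  }
  s$atoms[[ak(atom)]] <- NULL
  s$adj[[ak(atom)]] <- NULL
  if (identical(cap, "H")) {
    for (q in seq_along(nbs)) {
      if (is.null(s$atoms[[ak(nbs[[q]])]])) next
      if (s$atoms[[ak(nbs[[q]])]]$element == "H") {
        s <- remove_atom(s, nbs[[q]], cap = "none")
      } else {
        for (w in seq_len(round(orders[[q]]))) {
          s <- .add_hydrogen_to(s, nbs[[q]])
        }
      }
    }
    s <- refresh_structure(s)
  }
  s
}

#' Split a structure into its connected components
#'
#' Atom indices and annotations are preserved (indices are stable and never
#' reused, so each product keeps its original numbering).
#'
#' @param s a Structure.
#' @return list of Structures, one per connected component.
#' @export
split_disconnected <- function(s) {
  comps <- graph_components(s)
  lapply(comps, function(comp) {
    out <- s
    keep <- as.character(comp)
    out$atoms <- out$atoms[names(out$atoms) %in% keep]
    out$adj <- out$adj[names(out$adj) %in% keep]
    out$bonds <- Filter(function(b) b$a %in% comp && b$b %in% comp, out$bonds)
    refresh_structure(out)
  })
}

.acyl_side <- function(s, b) {
  # which end of a single bond carries a doubly bonded oxygen?
  for (end in c(b$a, b$b)) {
    for (bi in s$adj[[ak(end)]]) {
      nb <- s$bonds[[ak(bi)]]
      other <- if (nb$a == end) nb$b else nb$a
      if (nb$type == "double" && s$atoms[[ak(other)]]$element == "O") {
        return(end)
      }
    }
  }
  NA_integer_
}

#' Hydrolyse a bond, yielding two capped products
#'
#' The bond must be a hydrolysable linkage (an amide or ester-like single
#' bond whose one end carries a doubly bonded oxygen): the acyl side
#' receives a hydroxyl group, the leaving side a hydrogen, and the products
#' are split apart.
#'
#' @param s a Structure.
#' @param bond bond record or index (e.g. from [find_targets()]).
#' @return list of two Structures.
#' @export
hydrolyse <- function(s, bond) {
  b <- if (is.numeric(bond)) s$bonds[[ak(bond)]] else bond
  if (is.null(b) || b$type != "single") {
    structure_error("bonding-law violation", "bond is not hydrolysable")
  }
  acyl <- .acyl_side(s, b)
  if (is.na(acyl)) {
    structure_error("bonding-law violation", "bond is not hydrolysable")
  }
  leaving <- setdiff(c(b$a, b$b), acyl)
  s <- break_bond(s, b, cap = "none")
  # acyl side: -OH; leaving side: -H
  o <- new_atom(s$next_atom_index, "O")
  s$atoms[[ak(o$index)]] <- o
  s$adj[[ak(o$index)]] <- integer()
  s$next_atom_index <- s$next_atom_index + 1L
  for (nm in s$annotation_names) s$atoms[[ak(o$index)]]$annotations[nm] <- list(NULL)
  s <- add_bond_edge(s, new_bond(s$next_bond_index, acyl, o$index))
  s <- .add_hydrogen_to(s, o$index)
  s <- .add_hydrogen_to(s, leaving)
  s <- refresh_structure(s)
  split_disconnected(s)
}

#' Condense two structures with loss of water
#'
#' Removes a hydroxyl group from `atom1` of `s1` and a hydrogen from
#' `atom2` of `s2`, then joins the two fragments with a single bond
#' (`s2`'s atoms are re-indexed after those of `s1`).
#'
#' @param s1,s2 Structures.
#' @param atom1 atom of `s1` bearing an -OH group.
#' @param atom2 atom of `s2` bearing at least one hydrogen.
#' @return the condensed Structure.
#' @export
condense <- function(s1, s2, atom1, atom2) {
  oh <- NA_integer_
  for (j in neighbours(s1, atom1)) {
    a <- s1$atoms[[ak(j)]]
    if (a$element == "O" && hydrogen_count(s1, j) == 1 &&
        length(neighbours(s1, j, heavy_only = TRUE)) == 1 &&
        bond_between(s1, atom1, j)$type == "single") {
      oh <- j
      break
    }
  }
  if (is.na(oh)) structure_error("bonding-law violation",
                                 "atom1 carries no hydroxyl group")
  hs <- Filter(function(j) s2$atoms[[ak(j)]]$element == "H",
               neighbours(s2, atom2))
  if (length(hs) == 0) structure_error("bonding-law violation",
                                       "atom2 carries no hydrogen")
  s1 <- remove_atom(s1, oh, cap = "none")
  s2 <- remove_atom(s2, hs[[1]], cap = "none")
  # merge with re-indexing of s2
  offset <- s1$next_atom_index
  boffset <- s1$next_bond_index
  merged <- s1
  merged$annotation_names <- union(s1$annotation_names, s2$annotation_names)
  for (k in names(s2$atoms)) {
    a <- s2$atoms[[k]]
    a$index <- a$index + offset
    a$chiral_order <- a$chiral_order + offset
    merged$atoms[[ak(a$index)]] <- a
    merged$adj[[ak(a$index)]] <- integer()
  }
  for (k in names(s2$bonds)) {
    b <- s2$bonds[[k]]
    nb <- new_bond(b$index + boffset, b$a + offset, b$b + offset, b$type,
                   if (!is.null(b$stereo)) {
                     list(ref_a = b$stereo$ref_a + offset,
                          ref_b = b$stereo$ref_b + offset,
                          config = b$stereo$config)
                   })
    merged <- add_bond_edge(merged, nb)
  }
  merged <- add_bond_edge(merged, new_bond(merged$next_bond_index, atom1,
                                           atom2 + offset))
  merged$atoms[[ak(atom1)]]$chiral_order <-
    c(merged$atoms[[ak(atom1)]]$chiral_order, atom2 + offset)
  merged$atoms[[ak(atom2 + offset)]]$chiral_order <-
    c(merged$atoms[[ak(atom2 + offset)]]$chiral_order, atom1)
  refresh_structure(merged)
}

#' Reduce a carbonyl double bond to a hydroxyl group
#'
#' The ketoreduction reaction: the pi electrons of the targeted C=O bond
#' are removed, the bond set to single, the carbon and oxygen
#' re-hybridised to sp3, and one hydrogen added to each. The new hydroxyl
#' atoms and bond are annotated (`"ketoreduction"` = `"reduced"`) so they
#' can be highlighted.
#'
#' @param s a Structure.
#' @param carbonyl_bond bond record or index; must be a C=O double bond.
#' @param stereo optionally `"none"` (default): the configuration at the
#'   new alcohol carbon is left undefined.
#' @return the reduced Structure.
#' @export
ketoreduce <- function(s, carbonyl_bond, stereo = "none") {
  b <- if (is.numeric(carbonyl_bond)) s$bonds[[ak(carbonyl_bond)]] else {
    s$bonds[[ak(carbonyl_bond$index)]]
  }
  els <- c(s$atoms[[ak(b$a)]]$element, s$atoms[[ak(b$b)]]$element)
  if (is.null(b) || b$type != "double" || !setequal(els, c("C", "O"))) {
    structure_error("bonding-law violation",
                    "target is not a carbonyl double bond")
  }
  s$bonds[[ak(b$index)]]$type <- "single"
  s <- .add_hydrogen_to(s, b$a)
  s <- .add_hydrogen_to(s, b$b)
  s <- refresh_structure(s)
  if (!("ketoreduction" %in% s$annotation_names)) {
    s <- annotate(s, "ketoreduction", NULL)
  }
  s <- set_annotation(s, b$a, "ketoreduction", "reduced")
  s <- set_annotation(s, b$b, "ketoreduction", "reduced")
  s
}
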