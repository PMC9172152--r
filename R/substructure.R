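# Stereo-aware substructure matching with fast pre-filters.
#
# Matching proceeds in five stages (hydrogens ignored throughout):
#   1. element-count screen
#   2. per-atom local-environment screen (direct neighbour atoms + bonds)
#   3. seeded depth-first embedding, stereo-blind
#   4. tetrahedral-centre orientation check per match
#   5. double-bond cis/trans check
# A substructure with undefined stereo matches parents with defined
# stereo; a substructure with defined stereo does not match parents where
# it is undefined.

.heavy_atoms <- function(s) {
  sort(atom_indices(s)[vapply(s$atoms, function(a) a$element != "H",
                              logical(1))])
}

# (element, sorted multiset of (bond type, neighbour element)) signature
.local_signature <- function(s, i) {
  pairs <- character()
  for (bi in s$adj[[ak(i)]]) {
    b <- s$bonds[[ak(bi)]]
    other <- if (b$a == i) b$b else b$a
    el <- s$atoms[[ak(other)]]$element
    if (el != "H") pairs <- c(pairs, paste0(b$type, ">", el))
  }
  list(element = s$atoms[[ak(i)]]$element, pairs = sort(pairs))
}

# is multiset a contained in multiset b?
.multiset_subset <- function(a, b) {
  ta <- table(a); tb <- table(b)
  all(names(ta) %in% names(tb)) &&
    all(ta <= tb[names(ta)])
}

.check_chirality_match <- function(sub, super, mapping) {
  for (k in names(sub$atoms)) {
    sa <- sub$atoms[[k]]
    if (sa$chiral == "none" || sa$element == "H") next
    pj <- mapping[[ak(sa$index)]]
    pa <- super$atoms[[ak(pj)]]
    if (pa$chiral == "none") return(FALSE)
    # substructure neighbour order mapped into the superstructure; sub
    # hydrogens (or unmatched slots) become a single phantom filled with
    # the super neighbour not covered by the match
    sub_mapped <- vapply(sa$chiral_order, function(n) {
      if (sub$atoms[[ak(n)]]$element == "H") NA_integer_
      else as.integer(mapping[[ak(n)]])
    }, integer(1))
    super_order <- pa$chiral_order
    open <- setdiff(super_order, sub_mapped[!is.na(sub_mapped)])
    if (sum(is.na(sub_mapped)) == 1 && length(open) == 1) {
      sub_mapped[is.na(sub_mapped)] <- open
    } else if (sum(is.na(sub_mapped)) > 0) {
      next  # ambiguous phantom arrangement cannot contradict
    }
    par <- permutation_parity(sub_mapped, super_order)
    if (is.na(par)) next
    same_flag <- identical(sa$chiral, pa$chiral)
    if (same_flag != (par == 1L)) return(FALSE)
  }
  TRUE
}

.check_cis_trans_match <- function(sub, super, mapping) {
  for (bk in names(sub$bonds)) {
    sb <- sub$bonds[[bk]]
    if (sb$type != "double" || is.null(sb$stereo)) next
    A <- mapping[[ak(sb$a)]]; B <- mapping[[ak(sb$b)]]
    pb <- bond_between(super, A, B)
    if (is.null(pb$stereo)) return(FALSE)
    Ra <- mapping[[ak(sb$stereo$ref_a)]]
    Rb <- mapping[[ak(sb$stereo$ref_b)]]
    config <- pb$stereo$config
    # align super reference substituents with the mapped ones end by end
    ref_on <- function(end) if (pb$a == end) pb$stereo$ref_a else pb$stereo$ref_b
    if (Ra != ref_on(A)) config <- if (config == "cis") "trans" else "cis"
    if (Rb != ref_on(B)) config <- if (config == "cis") "trans" else "cis"
    if (config != sb$stereo$config) return(FALSE)
  }
  TRUE
}

#' Find occurrences of a substructure in a superstructure
#'
#' @param sub,super validated Structures (see [parse_smiles()]).
#' @param match_chiral require tetrahedral centres defined in `sub` to have
#'   the same orientation in `super`.
#' @param match_cis_trans require double-bond stereo defined in `sub` to
#'   match `super`.
#' @param all_mappings return every embedding rather than one per matched
#'   atom set (symmetry-equivalent embeddings are collapsed by default).
#' @return list of matches; each match has `mapping` (named list,
#'   substructure atom index -> superstructure atom index), `atoms` (sorted
#'   matched superstructure atoms) and `bonds` (matched superstructure bond
#'   indices). Empty list when there is no match.
#' @examples
#' m <- find_substructure_matches(parse_smiles("C(=O)NC"),
#'                                parse_smiles("CC(=O)NC"))
#' length(m)
#' @export
find_substructure_matches <- function(sub, super, match_chiral = TRUE,
                                      match_cis_trans = TRUE,
                                      all_mappings = FALSE) {
  sub_h <- .heavy_atoms(sub)
  sup_h <- .heavy_atoms(super)
  if (length(sub_h) == 0 || length(sub_h) > length(sup_h)) return(list())

  # stage 1: element counts
  sub_el <- table(vapply(sub_h, function(i) sub$atoms[[ak(i)]]$element,
                         character(1)))
  sup_el <- table(vapply(sup_h, function(i) super$atoms[[ak(i)]]$element,
                         character(1)))
  if (!all(names(sub_el) %in% names(sup_el)) ||
      !all(sub_el <= sup_el[names(sub_el)])) {
    return(list())
  }

  # stage 2: local-environment candidate sets
  sup_sig <- lapply(sup_h, function(i) .local_signature(super, i))
  candidates <- list()
  for (i in sub_h) {
    sig <- .local_signature(sub, i)
    cand <- sup_h[vapply(seq_along(sup_h), function(j) {
      sup_sig[[j]]$element == sig$element &&
        .multiset_subset(sig$pairs, sup_sig[[j]]$pairs)
    }, logical(1))]
    if (length(cand) == 0) return(list())
    candidates[[ak(i)]] <- cand
  }

  # stage 3: seeded depth-first embedding (stereo-blind).
  # seed: the substructure atom whose local signature is rarest in the
  # superstructure; ties by lowest index.
  rarity <- vapply(sub_h, function(i) length(candidates[[ak(i)]]), integer(1))
  # order atoms so each one (after a component seed) touches a mapped atom
  order_atoms <- integer()
  placed <- new.env(parent = emptyenv())
  remaining <- sub_h[order(rarity, sub_h)]
  while (length(remaining)) {
    seed <- remaining[[1]]
    comp <- integer()
    queue <- seed
    placed[[ak(seed)]] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in sort(neighbours(sub, v, heavy_only = TRUE))) {
        if (is.null(placed[[ak(w)]])) {
          placed[[ak(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    order_atoms <- c(order_atoms, comp)
    remaining <- setdiff(remaining, comp)
  }

  n_sub <- length(order_atoms)
  mapping <- new.env(parent = emptyenv())
  used <- new.env(parent = emptyenv())
  results <- list()

  extend <- function(pos) {
    if (pos > n_sub) {
      m <- stats::setNames(
        lapply(sub_h, function(i) mapping[[ak(i)]]),
        as.character(sub_h))
      results[[length(results) + 1L]] <<- m
      return(invisible())
    }
    v <- order_atoms[[pos]]
    mapped_nb <- Filter(function(w) !is.null(mapping[[ak(w)]]),
                        neighbours(sub, v, heavy_only = TRUE))
    cand <- candidates[[ak(v)]]
    if (length(mapped_nb)) {
      anchor <- mapping[[ak(mapped_nb[[1]])]]
      cand <- intersect(cand, neighbours(super, anchor, heavy_only = TRUE))
    }
    for (pj in cand) {
      if (!is.null(used[[ak(pj)]])) next
      ok <- TRUE
      for (w in mapped_nb) {
        sb <- bond_between(sub, v, w)
        pb <- bond_between(super, pj, mapping[[ak(w)]])
        if (is.null(pb) || pb$type != sb$type) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[[ak(v)]] <- pj
      used[[ak(pj)]] <- TRUE
      extend(pos + 1L)
      rm(list = ak(v), envir = mapping)
      rm(list = ak(pj), envir = used)
    }
  }
  extend(1L)

  # stages 4 + 5 and deduplication
  out <- list()
  seen_sets <- character()
  for (m in results) {
    if (match_chiral && !.check_chirality_match(sub, super, m)) next
    if (match_cis_trans && !.check_cis_trans_match(sub, super, m)) next
    atoms <- sort(unlist(m, use.names = FALSE))
    key <- paste(atoms, collapse = ",")
    if (!all_mappings && key %in% seen_sets) next
    seen_sets <- c(seen_sets, key)
    bonds <- integer()
    for (bk in names(sub$bonds)) {
      sb <- sub$bonds[[bk]]
      ea <- sub$atoms[[ak(sb$a)]]$element
      eb <- sub$atoms[[ak(sb$b)]]$element
      if (ea == "H" || eb == "H") next
      pb <- bond_between(super, m[[ak(sb$a)]], m[[ak(sb$b)]])
      bonds <- c(bonds, pb$index)
    }
    out[[length(out) + 1L]] <- list(mapping = m, atoms = atoms,
                                    bonds = sort(bonds))
  }
  out
}

# resolve a colour given as hex code or descriptive name to hex
resolve_colour <- function(col) {
  if (grepl("^#([0-9a-fA-F]{6}|[0-9a-fA-F]{3})$", col)) return(tolower(col))
  if (!(tolower(col) %in% grDevices::colours())) {
    stop("unknown colour name: ", col)
  }
  rgb <- grDevices::col2rgb(tolower(col))
  sprintf("#%02x%02x%02x", rgb[1], rgb[2], rgb[3])
}

#' Highlight substructure matches in a drawing
#'
#' Recolours the atoms and bonds of each match; with several match sets and
#' colours, later colours win on overlap.
#'
#' @param structure the parent Structure.
#' @param matches a list of matches from [find_substructure_matches()], or
#'   a list of such lists (one per colour).
#' @param colours one colour (hex code or name) per match set.
#' @param options [draw_options()].
#' @return a Drawing with colour assignments (see [layout()]).
#' @export
highlight_matches <- function(structure, matches, colours = "red",
                              options = draw_options()) {
  if (length(matches) && !is.null(matches[[1]]$mapping)) {
    matches <- list(matches)
  }
  colours <- vapply(colours, resolve_colour, character(1))
  if (length(colours) < length(matches)) {
    colours <- rep(colours, length.out = max(1, length(matches)))
  }
  d <- layout(structure, options)
  for (gi in seq_along(matches)) {
    col <- colours[[gi]]
    for (m in matches[[gi]]) {
      for (a in m$atoms) d$atom_colour[[ak(a)]] <- col
      for (b in m$bonds) d$bond_colour[[ak(b)]] <- col
    }
  }
  d
}

#' Highlight a single occurrence of a substructure
#'
#' One-call helpers: find matches of `sub_smiles` in `smiles` and return a
#' highlighted Drawing of the first (or all) occurrence(s).
#'
#' @param smiles parent molecule SMILES.
#' @param sub_smiles substructure SMILES (single string, or a vector with
#'   one colour each for multiple substructure sets).
#' @param colours colour per substructure set.
#' @param all_instances highlight all occurrences (default) or only one.
#' @param ... passed to [find_substructure_matches()].
#' @return a Drawing.
#' @export
highlight_substructure <- function(smiles, sub_smiles, colours = "red",
                                   all_instances = TRUE, ...) {
  parent <- parse_smiles(smiles)
  sets <- lapply(sub_smiles, function(q) {
    m <- find_substructure_matches(parse_smiles(q), parent, ...)
    if (!all_instances && length(m) > 1) m <- m[1]
    m
  })
  highlight_matches(parent, sets, colours)
}
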