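# Extended-connectivity fingerprints (ECFP), Tanimoto similarity, and
# bit-vector featurisation.
#
# Identifiers are 32-bit integers obtained from a murmur32 digest of a
# canonical string serialisation -- a fixed, platform-independent hash, so
# fingerprints are reproducible across machines and sessions.

hash32 <- function(x) {
  h <- digest::digest(x, algo = "murmur32", serialize = FALSE)
  strtoi(substr(h, 1, 4), 16L) * 65536 + strtoi(substr(h, 5, 8), 16L)
}

.atom_in_ring <- function(s, i) {
  any(vapply(s$rings$sssr, function(cyc) i %in% cyc, logical(1)))
}

#' Initial ECFP atom invariant
#'
#' A stable 32-bit identifier hashed from the 7-tuple (heavy-neighbour
#' count, valence, atomic number, standard atomic weight, formal charge,
#' hydrogen-neighbour count, ring membership). Identical chemical
#' environments map to identical identifiers. Atomic weight is the
#' standard per-element constant quantised to 2 decimals; isotopes are not
#' distinguished.
#'
#' @param s a validated Structure.
#' @param i heavy-atom index.
#' @return numeric identifier in `[0, 2^32)`.
#' @export
initial_atom_invariant <- function(s, i) {
  a <- s$atoms[[ak(i)]]
  nb <- neighbours(s, i)
  heavy <- sum(vapply(nb, function(j) s$atoms[[ak(j)]]$element != "H",
                      logical(1)))
  h <- length(nb) - heavy
  tuple <- paste(heavy, a$valency, atomic_number(a$element),
                 sprintf("%.2f", atomic_weight(a$element)), a$charge, h,
                 as.integer(.atom_in_ring(s, i)), sep = "|")
  hash32(tuple)
}

# spelling-invariant chirality tag: the @/@@ flag reinterpreted relative to
# the neighbour order sorted by current identifiers (H phantoms lowest);
# NULL when neighbouring identifiers tie.
.chiral_tag <- function(s, i, ids) {
  a <- s$atoms[[ak(i)]]
  if (a$chiral == "none" || length(a$chiral_order) != 4) return(NULL)
  key <- vapply(a$chiral_order, function(j) {
    if (s$atoms[[ak(j)]]$element == "H") -1 else ids[[ak(j)]]
  }, numeric(1))
  if (anyDuplicated(key)) return(NULL)
  sorted <- a$chiral_order[order(key)]
  par <- permutation_parity(a$chiral_order, sorted)
  flag <- a$chiral
  if (par == -1L) {
    flag <- if (flag == "clockwise") "counterclockwise" else "clockwise"
  }
  flag
}

#' Extended-connectivity fingerprint of a molecule
#'
#' Each heavy atom starts from [initial_atom_invariant()]; for each
#' iteration up to `radius`, an atom's identifier is rehashed together with
#' the sorted (bond-order tag, neighbour identifier) pairs of its heavy
#' neighbours, plus a spelling-invariant chirality tag when the atom is a
#' tetrahedral centre. The default radius 2 gives ECFP-4 behaviour
#' (environments of diameter 4). Duplicate identifiers are removed, as are
#' distinct identifiers covering the same atom-set substructure (the one
#' generated at smaller radius, then with the smaller identifier, is kept).
#'
#' @param s a validated Structure (or SMILES string).
#' @param radius non-negative iteration count (default 2 = ECFP-4).
#' @return an object of class `chemkit_fingerprint`: list with `ids`
#'   (sorted numeric identifiers) and `legend` (provenance: one row per
#'   identifier with the central atom, radius, and covered atom set).
#' @examples
#' fp <- ecfp(parse_smiles("CCO"))
#' length(fp$ids)
#' @export
ecfp <- function(s, radius = 2) {
  if (is.character(s)) s <- parse_smiles(s)
  if (radius < 0) stop("radius must be >= 0")
  heavy <- .heavy_atoms(s)
  ids <- list()
  env_atoms <- list()
  features <- list()
  for (i in heavy) {
    k <- ak(i)
    ids[[k]] <- initial_atom_invariant(s, i)
    env_atoms[[k]] <- i
    features[[length(features) + 1L]] <- list(
      id = ids[[k]], centre = i, radius = 0L, atoms = i)
  }
  r <- 0L
  while (r < radius) {
    r <- r + 1L
    new_ids <- ids
    new_env <- env_atoms
    for (i in heavy) {
      k <- ak(i)
      nb <- neighbours(s, i, heavy_only = TRUE)
      if (length(nb) == 0) next
      tags <- vapply(nb, function(j) {
        bond_order(bond_between(s, i, j)$type)
      }, numeric(1))
      nb_ids <- vapply(nb, function(j) ids[[ak(j)]], numeric(1))
      o <- order(tags, nb_ids)
      parts <- paste(r, ids[[k]],
                     paste(tags[o], nb_ids[o], sep = ":", collapse = ","),
                     sep = ";")
      ct <- .chiral_tag(s, i, ids)
      if (!is.null(ct)) parts <- paste(parts, ct, sep = ";")
      new_ids[[k]] <- hash32(parts)
      new_env[[k]] <- sort(unique(c(env_atoms[[k]],
                                    unlist(env_atoms[as.character(nb)]))))
      features[[length(features) + 1L]] <- list(
        id = new_ids[[k]], centre = i, radius = r, atoms = new_env[[k]])
    }
    ids <- new_ids
    env_atoms <- new_env
  }
  # deduplication: drop repeated identifiers, then alias identifiers whose
  # environments span the same atom set (keep smaller radius, then id)
  ord <- order(vapply(features, function(f) f$radius, integer(1)),
               vapply(features, function(f) f$id, numeric(1)))
  features <- features[ord]
  kept <- list()
  seen_id <- character()
  seen_set <- character()
  for (f in features) {
    idk <- sprintf("%.0f", f$id)
    setk <- paste(f$atoms, collapse = ",")
    if (idk %in% seen_id || setk %in% seen_set) next
    seen_id <- c(seen_id, idk)
    seen_set <- c(seen_set, setk)
    kept[[length(kept) + 1L]] <- f
  }
  structure(list(
    ids = sort(vapply(kept, function(f) f$id, numeric(1))),
    legend = kept
  ), class = "chemkit_fingerprint")
}

.fp_ids <- function(x) {
  if (inherits(x, "chemkit_fingerprint")) x$ids else as.numeric(x)
}

#' Tanimoto (Jaccard) similarity between two fingerprints
#'
#' `|A intersect B| / |A union B|`; two empty fingerprints count as
#' identical (similarity 1).
#'
#' @param a,b fingerprints from [ecfp()] (or bare identifier sets).
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  a <- unique(.fp_ids(a)); b <- unique(.fp_ids(b))
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' @rdname tanimoto
#' @export
tanimoto_distance <- function(a, b) 1 - tanimoto(a, b)

# SMILES-like rendering of an identifier's environment, for legends; built
# on the kekulised parent so bond symbols are plain.
.fragment_smiles <- function(ks, atoms) {
  atoms <- sort(atoms)
  emit_atom <- function(i) {
    a <- ks$atoms[[ak(i)]]
    if (a$element %in% .organic_subset && a$charge == 0L) a$element
    else paste0("[", a$element,
                if (a$charge > 0) paste0("+") else if (a$charge < 0) "-" else "",
                "]")
  }
  visited <- new.env(parent = emptyenv())
  closures <- new.env(parent = emptyenv())
  lab <- 0L
  pre <- function(v, parent) {
    visited[[ak(v)]] <- TRUE
    for (w in sort(intersect(neighbours(ks, v, heavy_only = TRUE), atoms))) {
      if (!is.na(parent) && w == parent) next
      if (!is.null(visited[[ak(w)]])) {
        key <- paste(sort(c(v, w)), collapse = "-")
        if (is.null(closures[[key]])) {
          lab <<- lab + 1L
          closures[[key]] <- lab
        }
      } else {
        pre(w, v)
      }
    }
  }
  walk <- function(v, parent) {
    token <- emit_atom(v)
    kids <- character()
    for (w in sort(intersect(neighbours(ks, v, heavy_only = TRUE), atoms))) {
      if (!is.na(parent) && w == parent) next
      key <- paste(sort(c(v, w)), collapse = "-")
      b <- bond_between(ks, v, w)
      sym <- .bond_symbol(b$type)
      if (!is.null(visited[[ak(w)]])) {
        if (!is.null(closures[[key]]) && closures[[key]] > 0) {
          token <- paste0(token, sym, closures[[key]])
          closures[[key]] <- -closures[[key]]  # emitted twice then done
        }
      } else {
        visited[[ak(w)]] <- TRUE
        kids <- c(kids, paste0(sym, walk(w, v)))
      }
    }
    if (length(kids) > 1) {
      token <- paste0(token,
                      paste0("(", kids[-length(kids)], ")", collapse = ""),
                      kids[length(kids)])
    } else if (length(kids) == 1) {
      token <- paste0(token, kids)
    }
    token
  }
  pre(atoms[[1]], NA_integer_)
  visited <- new.env(parent = emptyenv())
  visited[[ak(atoms[[1]])]] <- TRUE
  walk(atoms[[1]], NA_integer_)
}

#' Fold molecules into fixed-length bit vectors
#'
#' Bit `i` of a row is set when the molecule has an identifier congruent to
#' `i` modulo `length`. The legend lists, for every set bit, a
#' representative substructure (rendered as an environment SMILES).
#'
#' @param structures list of Structures or SMILES strings.
#' @param length vector length (default 1024).
#' @param radius ECFP radius (default 2).
#' @return list with `matrix` (0/1 integer matrix, one row per molecule)
#'   and `legend` (data.frame: bit, substructure).
#' @export
to_bit_vectors <- function(structures, length = 1024, radius = 2) {
  stopifnot(length > 0)
  n <- base::length(structures)
  mat <- matrix(0L, nrow = n, ncol = length)
  legend_map <- list()
  for (mi in seq_len(n)) {
    s <- structures[[mi]]
    if (is.character(s)) s <- parse_smiles(s)
    fp <- ecfp(s, radius = radius)
    ks <- kekulise(s)
    for (f in fp$legend) {
      bit <- (f$id %% length) + 1
      mat[mi, bit] <- 1L
      bk <- ak(bit)
      if (is.null(legend_map[[bk]]) || f$radius < legend_map[[bk]]$radius) {
        legend_map[[bk]] <- list(radius = f$radius,
                                 smiles = .fragment_smiles(ks, f$atoms))
      }
    }
  }
  bits <- sort(as.integer(names(legend_map)))
  list(
    matrix = mat,
    legend = data.frame(
      bit = bits,
      substructure = vapply(bits, function(b) legend_map[[ak(b)]]$smiles,
                            character(1)),
      stringsAsFactors = FALSE
    )
  )
}
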