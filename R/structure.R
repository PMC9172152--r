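# Core molecular graph: Structure, Atom, Bond.
#
# Atoms and bonds live in named lists keyed by their stable integer index
# (0-based, assigned in SMILES reading order, never reused after deletion).
# Adjacency maps atom index -> incident bond indices.

ak <- function(i) as.character(i)

#' Structure errors
#'
#' All chemically fatal conditions raised by the kit are
#' `chemkit_structure_error` conditions carrying a `category` field. During
#' SMILES parsing the message is formatted
#' `Error parsing "<smiles>": <category text>`.
#'
#' @param category one of `"bonding-law violation"`,
#'   `"conflicting double-bond stereochemistry"`, `"syntax error"`,
#'   `"chirality error"`.
#' @param message human-readable category text.
#' @param smiles the offending SMILES, if the error arose while parsing.
#' @keywords internal
structure_error <- function(category, message, smiles = NULL) {
  msg <- if (!is.null(smiles)) {
    sprintf('Error parsing "%s": %s', smiles, message)
  } else {
    message
  }
  stop(structure(
    class = c("chemkit_structure_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), category = category)
  ))
}

chirality_error <- function(message) {
  stop(structure(
    class = c("chemkit_chirality_error", "chemkit_structure_error",
              "error", "condition"),
    list(message = message, call = sys.call(-1), category = "chirality error")
  ))
}

#' Create an atom record
#'
#' @param index stable non-negative integer id, unique within a Structure.
#' @param element chemical symbol (`"C"`, `"Cl"`, ... or `"H"`).
#' @param charge integer formal charge.
#' @param chiral `"none"`, `"counterclockwise"` (`@`) or `"clockwise"`
#'   (`@@`), interpreted relative to `chiral_order`.
#' @param aromatic logical; set by aromaticity perception (or a lowercase
#'   SMILES symbol, later confirmed by perception).
#' @param explicit_h hydrogens declared inside a bracket atom (`NA` for
#'   organic-subset atoms, whose hydrogens are inferred from valence).
#' @param chiral_order neighbour atom indices in SMILES appearance order;
#'   the reference frame for `chiral`.
#' @return a list of class `chemkit_atom`.
#' @export
new_atom <- function(index, element, charge = 0L, chiral = "none",
                     aromatic = FALSE, explicit_h = NA_integer_,
                     chiral_order = integer()) {
  structure(list(
    index = as.integer(index), element = element, charge = as.integer(charge),
    chiral = chiral, aromatic = isTRUE(aromatic),
    explicit_h = as.integer(explicit_h),
    chiral_order = as.integer(chiral_order),
    annotations = list(),
    valency = NA_integer_, lone_pairs = NA_integer_,
    hybridisation = NA_character_, pi_electrons = 0L,
    shells = NULL
  ), class = "chemkit_atom")
}

#' Create a bond record
#'
#' @param index stable integer id.
#' @param a,b distinct atom indices (unordered pair).
#' @param type `"single"`, `"double"`, `"triple"`, `"quadruple"` or
#'   `"aromatic"`.
#' @param stereo `NULL`, or for a stereo-restricted double bond a list
#'   `list(ref_a =, ref_b =, config = "cis"|"trans")` where `ref_a`/`ref_b`
#'   are reference substituent atom indices on the `a`/`b` ends.
#' @return a list of class `chemkit_bond`.
#' @export
new_bond <- function(index, a, b, type = "single", stereo = NULL) {
  if (a == b) {
    structure_error("bonding-law violation", "self-bond is not allowed")
  }
  structure(list(
    index = as.integer(index), a = as.integer(a), b = as.integer(b),
    type = type, stereo = stereo
  ), class = "chemkit_bond")
}

bond_order <- function(type) {
  switch(type, single = 1, double = 2, triple = 3, quadruple = 4,
         aromatic = 1.5, stop("unknown bond type: ", type))
}

#' Assemble a Structure from atoms and bonds
#'
#' Builds the graph container and its adjacency; no chemical validation is
#' performed (see [refresh_structure()]).
#'
#' @param atoms list of atoms from [new_atom()].
#' @param bonds list of bonds from [new_bond()].
#' @return an object of class `chemkit_structure`.
#' @examples
#' s <- build_structure(list(new_atom(0, "C"), new_atom(1, "C")),
#'                      list(new_bond(0, 0, 1)))
#' atom_degree(s, 0)
#' @export
build_structure <- function(atoms = list(), bonds = list()) {
  s <- structure(list(
    atoms = list(), bonds = list(), adj = list(),
    next_atom_index = 0L, next_bond_index = 0L,
    rings = NULL, aromatic_systems = list(),
    aromaticity_done = FALSE, annotation_names = character()
  ), class = "chemkit_structure")
  for (a in atoms) {
    if (!is.null(s$atoms[[ak(a$index)]])) {
      structure_error("syntax error", paste0("duplicate atom index ", a$index))
    }
    s$atoms[[ak(a$index)]] <- a
    s$adj[[ak(a$index)]] <- integer()
    s$next_atom_index <- max(s$next_atom_index, a$index + 1L)
  }
  for (b in bonds) {
    s <- add_bond_edge(s, b)
  }
  s
}

add_bond_edge <- function(s, b) {
  if (is.null(s$atoms[[ak(b$a)]]) || is.null(s$atoms[[ak(b$b)]])) {
    structure_error("syntax error",
                    paste0("bond ", b$index, " references a missing atom"))
  }
  s$bonds[[ak(b$index)]] <- b
  s$adj[[ak(b$a)]] <- c(s$adj[[ak(b$a)]], b$index)
  s$adj[[ak(b$b)]] <- c(s$adj[[ak(b$b)]], b$index)
  s$next_bond_index <- max(s$next_bond_index, b$index + 1L)
  s
}

atom_indices <- function(s) {
  unname(vapply(s$atoms, function(a) a$index, integer(1)))
}

bond_indices <- function(s) {
  unname(vapply(s$bonds, function(b) b$index, integer(1)))
}

#' @rdname build_structure
#' @param s a Structure.
#' @param i an atom index.
#' @export
atom_degree <- function(s, i) length(s$adj[[ak(i)]])

#' Neighbour atom indices of an atom
#' @param s a Structure.
#' @param i atom index.
#' @param heavy_only drop hydrogen neighbours.
#' @return integer vector of atom indices.
#' @export
neighbours <- function(s, i, heavy_only = FALSE) {
  bs <- s$adj[[ak(i)]]
  if (length(bs) == 0) return(integer())
  out <- vapply(bs, function(bi) {
    b <- s$bonds[[ak(bi)]]
    if (b$a == i) b$b else b$a
  }, integer(1))
  if (heavy_only) {
    out <- out[vapply(out, function(j) s$atoms[[ak(j)]]$element != "H",
                      logical(1))]
  }
  out
}

#' Find the bond connecting two atoms
#' @param s a Structure.
#' @param a,b atom indices.
#' @return the bond record, or `NULL` when the atoms are not bonded.
#' @export
bond_between <- function(s, a, b) {
  for (bi in s$adj[[ak(a)]]) {
    bd <- s$bonds[[ak(bi)]]
    if ((bd$a == a && bd$b == b) || (bd$a == b && bd$b == a)) return(bd)
  }
  NULL
}

# Sum of bond orders at an atom. Aromatic bonds are resolved with the
# lone-pair-donor rule: their sum contribution is n_aromatic when that total
# is already an allowed valency, else n_aromatic + 1 (one pi bond).
bond_order_sum <- function(s, i, aromatic_as = c("resolve", "one")) {
  aromatic_as <- match.arg(aromatic_as)
  a <- s$atoms[[ak(i)]]
  bs <- s$adj[[ak(i)]]
  plain <- 0
  n_arom <- 0L
  for (bi in bs) {
    t <- s$bonds[[ak(bi)]]$type
    if (t == "aromatic") n_arom <- n_arom + 1L else plain <- plain + bond_order(t)
  }
  if (n_arom == 0L) return(plain)
  if (aromatic_as == "one") return(plain + n_arom)
  eh <- if (is.na(a$explicit_h)) 0L else a$explicit_h
  lo <- plain + n_arom
  av <- allowed_valences(a$element, a$charge)
  if (!is.null(av) && (lo + eh) %in% av) lo else lo + 1
}

hydrogen_count <- function(s, i) {
  sum(vapply(neighbours(s, i), function(j) s$atoms[[ak(j)]]$element == "H",
             logical(1)))
}

#' Deep-copy a Structure
#'
#' Returns a fully independent copy: mutating the copy never changes the
#' original. Chiral marks, cis/trans marks and annotations are preserved.
#' @param s a Structure.
#' @export
deep_copy <- function(s) {
  # R's copy-on-modify semantics already guarantee independence for this
  # pure-list representation; rebuilding through the constructor also
  # revalidates internal consistency.
  s2 <- s
  class(s2) <- class(s)
  s2
}

# ---- annotations -----------------------------------------------------------

#' Register an annotation on every atom of a structure
#'
#' Annotation names must be registered once on the whole structure before
#' per-atom values can be set or read; registration assigns `default` to
#' every atom (including hydrogens).
#'
#' @param s a Structure.
#' @param name annotation name.
#' @param default default value (any R value; `NULL` is allowed).
#' @return the updated Structure.
#' @export
annotate <- function(s, name, default = NULL) {
  s$annotation_names <- union(s$annotation_names, name)
  for (k in names(s$atoms)) {
    s$atoms[[k]]$annotations[name] <- list(default)
  }
  s
}

check_annotation_registered <- function(s, name) {
  if (!(name %in% s$annotation_names)) {
    stop("annotation '", name, "' has not been registered with annotate()")
  }
}

#' @rdname annotate
#' @param i atom index.
#' @param value value to store for that atom.
#' @export
set_annotation <- function(s, i, name, value) {
  check_annotation_registered(s, name)
  s$atoms[[ak(i)]]$annotations[name] <- list(value)
  s
}

#' @rdname annotate
#' @export
get_annotation <- function(s, i, name) {
  check_annotation_registered(s, name)
  s$atoms[[ak(i)]]$annotations[[name]]
}

# ---- graph utilities -------------------------------------------------------

#' Connected components of a structure
#' @param s a Structure.
#' @return list of integer vectors of atom indices.
#' @export
graph_components <- function(s) {
  idx <- atom_indices(s)
  seen <- new.env(parent = emptyenv())
  comps <- list()
  for (start in idx) {
    if (!is.null(seen[[ak(start)]])) next
    comp <- integer()
    queue <- start
    seen[[ak(start)]] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in neighbours(s, v)) {
        if (is.null(seen[[ak(w)]])) {
          seen[[ak(w)]] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}

# BFS shortest path between two atoms (inclusive); integer() if disconnected.
shortest_path_atoms <- function(s, from, to, heavy_only = FALSE) {
  if (from == to) return(from)
  prev <- new.env(parent = emptyenv())
  prev[[ak(from)]] <- -1L
  queue <- from
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in neighbours(s, v, heavy_only = heavy_only)) {
      if (is.null(prev[[ak(w)]])) {
        prev[[ak(w)]] <- v
        if (w == to) {
          path <- w
          while (path[[1]] != from) path <- c(prev[[ak(path[[1]])]], path)
          return(path)
        }
        queue <- c(queue, w)
      }
    }
  }
  integer()
}

#' @export
print.chemkit_structure <- function(x, ...) {
  nh <- sum(vapply(x$atoms, function(a) a$element == "H", logical(1)))
  cat(sprintf("<chemkit structure: %d atoms (%d heavy), %d bonds>\n",
              length(x$atoms), length(x$atoms) - nh, length(x$bonds)))
  invisible(x)
}
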