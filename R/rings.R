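# Ring perception: elementary cycle enumeration, smallest set of smallest
# rings (SSSR), recursive Hueckel aromaticity, and kekulisation.

#' Enumerate the elementary cycles of a structure
#'
#' Lists every simple (elementary) cycle of the heavy-atom graph once, up
#' to rotation and reflection; cycles shorter than three atoms are
#' discarded. The search follows Johnson's root-vertex scheme: cycles are
#' rooted at their smallest atom index and extended only through larger
#' indices, so each cycle is produced exactly twice (once per direction)
#' and the lexicographically oriented copy is kept.
#'
#' A guard aborts with an error when more than `limit` cycles are found
#' (heavily fused cage molecules such as fullerenes make full enumeration
#' intractable).
#'
#' @param s a Structure.
#' @param limit maximum number of cycles tolerated (default `1e6`, or
#'   `getOption("chemkit.cycle_limit")`).
#' @return list of integer vectors of atom indices (each a cycle, rotation
#'   starting at its smallest member).
#' @export
enumerate_simple_cycles <- function(s, limit = getOption("chemkit.cycle_limit", 1e6)) {
  # restrict to the 2-core: vertices of degree >= 2 after pruning leaves
  deg <- new.env(parent = emptyenv())
  alive <- new.env(parent = emptyenv())
  idx <- atom_indices(s)
  for (i in idx) {
    assign(ak(i), length(neighbours(s, i)), envir = deg)
    assign(ak(i), TRUE, envir = alive)
  }
  queue <- idx[vapply(idx, function(i) get(ak(i), deg) < 2, logical(1))]
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    if (!get(ak(v), alive)) next
    assign(ak(v), FALSE, envir = alive)
    for (w in neighbours(s, v)) {
      if (get(ak(w), alive)) {
        d <- get(ak(w), deg) - 1L
        assign(ak(w), d, envir = deg)
        if (d < 2) queue <- c(queue, w)
      }
    }
  }
  core <- sort(idx[vapply(idx, function(i) get(ak(i), alive), logical(1))])
  if (length(core) < 3) return(list())
  nbrs <- lapply(core, function(i) {
    sort(intersect(neighbours(s, i), core))
  })
  names(nbrs) <- as.character(core)

  cycles <- list()
  n_found <- 0L
  for (root in core) {
    # DFS over vertices > root; a path root..v closing back to root is a cycle
    path <- root
    on_path <- new.env(parent = emptyenv())
    assign(ak(root), TRUE, envir = on_path)
    dfs <- function(v) {
      for (w in nbrs[[ak(v)]]) {
        if (w == root) {
          if (length(path) >= 3 && path[[2]] < path[[length(path)]]) {
            n_found <<- n_found + 1L
            if (n_found > limit) {
              stop("simple-cycle enumeration exceeded ", limit,
                   " cycles; the input is too heavily fused (see option ",
                   "'chemkit.cycle_limit')")
            }
            cycles[[n_found]] <<- path
          }
        } else if (w > root && is.null(on_path[[ak(w)]])) {
          path <<- c(path, w)
          assign(ak(w), TRUE, envir = on_path)
          dfs(w)
          path <<- path[-length(path)]
          rm(list = ak(w), envir = on_path)
        }
      }
    }
    dfs(root)
  }
  cycles
}

# cyclomatic number (number of independent cycles) of a structure
cyclomatic_number <- function(s) {
  length(s$bonds) - length(s$atoms) + length(graph_components(s))
}

# bond index set of a cycle given as an atom sequence
.cycle_bond_set <- function(s, cyc) {
  m <- length(cyc)
  vapply(seq_len(m), function(i) {
    bond_between(s, cyc[[i]], cyc[[i %% m + 1L]])$index
  }, integer(1))
}

#' Smallest set of smallest rings
#'
#' Chooses, among the enumerated elementary cycles, a minimum cycle basis:
#' candidates are sorted by size (then by sorted atom-index tuple for
#' determinism) and greedily added when linearly independent over GF(2) in
#' bond space, until the cyclomatic number of rings has been collected.
#'
#' @param s a Structure.
#' @param cycles optionally, precomputed [enumerate_simple_cycles()] output.
#' @return list of integer vectors of atom indices, smallest rings first.
#' @export
find_sssr <- function(s, cycles = NULL) {
  target <- cyclomatic_number(s)
  if (target == 0) return(list())
  if (is.null(cycles)) cycles <- enumerate_simple_cycles(s)
  key <- lapply(cycles, function(cyc) sort(cyc))
  ord <- order(lengths(cycles),
               vapply(key, function(k) paste(sprintf("%06d", k), collapse = ","),
                      character(1)))
  cycles <- cycles[ord]

  all_bonds <- bond_indices(s)
  basis <- list()   # reduced GF(2) vectors (logical over bonds)
  pivots <- integer()
  chosen <- list()
  for (cyc in cycles) {
    vec <- all_bonds %in% .cycle_bond_set(s, cyc)
    for (j in seq_along(basis)) {
      if (vec[pivots[[j]]]) vec <- xor(vec, basis[[j]])
    }
    piv <- which(vec)[1]
    if (!is.na(piv)) {
      basis[[length(basis) + 1L]] <- vec
      pivots <- c(pivots, piv)
      chosen[[length(chosen) + 1L]] <- cyc
      if (length(chosen) == target) break
    }
  }
  chosen
}

# can this atom's lone pair be delocalised into the ring?
.is_lp_donor <- function(atom) {
  !is.na(atom$lone_pairs) && atom$lone_pairs >= 1 &&
    identical(atom$hybridisation, "sp3")
}

# does this atom already hold a pi bond (double/triple, anywhere)?
.has_pi_bond <- function(s, i) {
  for (bi in s$adj[[ak(i)]]) {
    if (s$bonds[[ak(bi)]]$type %in% c("double", "triple", "quadruple")) {
      return(TRUE)
    }
  }
  FALSE
}

# Hueckel evaluation of one cycle. Returns list(aromatic=, contribution=)
# where contribution maps position -> pi electrons surrendered (1 for a
# double-bond atom, 2 for a lone-pair donor, 0 otherwise).
#
# Atom classes (planarity screen doubles as the hybridisation screen):
#   pinned - already holds a pi bond (double/triple, in-ring or exocyclic)
#   donor  - no pi capacity left (sigma bonds saturate the valency) but a
#            delocalisable lone pair; sp3 donors get promoted on success
#   free   - sp2 with spare pi capacity: takes part in the greedy local
#            kekulisation of aromatic bond stretches
#   empty  - no pi capacity and no lone pair (e.g. borazine boron):
#            allowed in the ring, contributes nothing
.evaluate_cycle <- function(s, cyc) {
  m <- length(cyc)
  cls <- character(m)
  for (i in seq_len(m)) {
    a <- s$atoms[[ak(cyc[[i]])]]
    planar <- identical(a$hybridisation, "sp2") || .is_lp_donor(a)
    if (!planar) return(list(aromatic = FALSE))
    if (.has_pi_bond(s, cyc[[i]])) {
      cls[i] <- "pinned"
    } else {
      cap <- a$valency - atom_degree(s, a$index)
      if (cap >= 1) {
        cls[i] <- "free"
      } else if (!is.na(a$lone_pairs) && a$lone_pairs >= 1) {
        cls[i] <- "donor"
      } else {
        cls[i] <- "empty"
      }
    }
  }
  ring_bond <- lapply(seq_len(m), function(i) {
    bond_between(s, cyc[[i]], cyc[[i %% m + 1L]])
  })
  n_double <- sum(vapply(ring_bond, function(b) b$type == "double", logical(1)))

  # greedy local kekulisation over the free atoms: walk the cycle starting
  # after a non-free atom when one exists (determinism)
  free <- cls == "free"
  start <- which(!free)[1]
  ord <- if (is.na(start)) seq_len(m) else ((start + seq_len(m) - 1L) %% m) + 1L
  used <- logical(m)
  greedy <- 0L
  for (i in ord) {
    j <- i %% m + 1L
    b <- ring_bond[[i]]
    if (free[i] && free[j] && !used[i] && !used[j] &&
        b$type %in% c("single", "aromatic")) {
      greedy <- greedy + 1L
      used[i] <- TRUE
      used[j] <- TRUE
    }
  }
  n_lp <- sum(cls == "donor")
  aromatic <- (n_double + greedy + n_lp) %% 2L == 1L
  if (!aromatic) return(list(aromatic = FALSE))
  contribution <- integer(m)
  contribution[cls == "donor"] <- 2L
  contribution[used] <- 1L
  for (i in seq_len(m)) {
    if (cls[i] == "pinned") {
      # only an in-ring double bond surrenders an electron to this ring
      entering <- ring_bond[[if (i == 1) m else i - 1L]]
      leaving <- ring_bond[[i]]
      if (entering$type == "double" || leaving$type == "double") {
        contribution[i] <- 1L
      }
    }
  }
  list(aromatic = TRUE, contribution = contribution)
}

#' Perceive aromaticity of a structure
#'
#' Recursive fixed-point evaluation of Hueckel's 4n+2 rule on the SSSR:
#' each round, every not-yet-aromatic ring whose atoms are all sp2 (or sp3
#' with a delocalisable lone pair) is locally kekulised and its double
#' bonds plus contributed lone pairs counted; the ring is aromatic when the
#' sum is odd. Aromatic rings mark their atoms and bonds aromatic and
#' promote donor lone pairs to p orbitals (new hybridisation sp2), which
#' can make further rings evaluable in the next round. Iteration stops when
#' the number of aromatic cycles no longer changes. Aromatic cycles sharing
#' a bond are merged into aromatic systems holding the pooled pi electrons.
#'
#' @param s a Structure with hybridisation assigned and SSSR available.
#' @return the updated Structure (fields `rings`, `aromatic_systems`,
#'   per-atom/bond aromatic flags).
#' @export
detect_aromaticity <- function(s) {
  sssr <- s$rings$sssr
  n_r <- length(sssr)
  is_arom_cycle <- logical(n_r)
  contribution <- new.env(parent = emptyenv())  # atom key -> electrons given

  repeat {
    changed <- FALSE
    for (ci in seq_len(n_r)) {
      if (n_r == 0 || is_arom_cycle[ci]) next
      res <- .evaluate_cycle(s, sssr[[ci]])
      if (!res$aromatic) next
      is_arom_cycle[ci] <- TRUE
      changed <- TRUE
      cyc <- sssr[[ci]]
      m <- length(cyc)
      for (i in seq_len(m)) {
        k <- ak(cyc[[i]])
        a <- s$atoms[[k]]
        if (is.null(contribution[[k]])) {
          contribution[[k]] <- res$contribution[[i]]
        }
        s$atoms[[k]]$aromatic <- TRUE
        if (identical(a$hybridisation, "sp3")) {
          # promote the delocalised lone pair to a p orbital
          s$atoms[[k]]$hybridisation <- "sp2"
        }
        b <- bond_between(s, cyc[[i]], cyc[[i %% m + 1L]])
        s$bonds[[ak(b$index)]]$type <- "aromatic"
        s$bonds[[ak(b$index)]]$stereo <- NULL
      }
    }
    if (!changed) break
  }

  # leftover aromatic marks from lowercase SMILES that no aromatic cycle
  # confirms are chemically invalid (non-kekulisable input)
  arom_cycles <- sssr[is_arom_cycle]
  in_arom <- unique(unlist(arom_cycles))
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    if (a$aromatic && !(a$index %in% in_arom)) {
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
  }
  arom_bond_sets <- lapply(arom_cycles, function(cyc) .cycle_bond_set(s, cyc))
  arom_bonds <- unique(unlist(arom_bond_sets))
  for (bk in names(s$bonds)) {
    if (s$bonds[[bk]]$type == "aromatic" &&
        !(s$bonds[[bk]]$index %in% arom_bonds)) {
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
  }

  # aromatic systems: union of aromatic cycles sharing at least one bond
  n_a <- length(arom_cycles)
  parent <- seq_len(max(n_a, 1L))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n_a > 1) {
    for (i in seq_len(n_a - 1L)) {
      for (j in (i + 1L):n_a) {
        if (length(intersect(arom_bond_sets[[i]], arom_bond_sets[[j]]))) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  systems <- list()
  if (n_a > 0) {
    roots <- vapply(seq_len(n_a), find, integer(1))
    for (r in unique(roots)) {
      members <- which(roots == r)
      atoms_in <- sort(unique(unlist(arom_cycles[members])))
      bonds_in <- sort(unique(unlist(arom_bond_sets[members])))
      pool <- sum(vapply(atoms_in, function(i) {
        v <- contribution[[ak(i)]]
        if (is.null(v)) 0L else v
      }, integer(1)))
      systems[[length(systems) + 1L]] <- list(
        atoms = atoms_in, bonds = bonds_in, pi_electrons = pool,
        contribution = stats::setNames(
          vapply(atoms_in, function(i) contribution[[ak(i)]], integer(1)),
          as.character(atoms_in))
      )
    }
  }
  s$rings$aromatic <- arom_cycles
  s$aromatic_systems <- systems
  s$aromaticity_done <- TRUE
  s
}

# full ring + aromaticity pipeline used by parse/refresh
perceive_rings_and_aromaticity <- function(s) {
  cycles <- enumerate_simple_cycles(s)
  sssr <- find_sssr(s, cycles)
  s$rings <- list(all_cycles = cycles, sssr = sssr, aromatic = list())
  detect_aromaticity(s)
}

#' Kekulise the aromatic systems of a structure
#'
#' Within each aromatic system, a maximum matching (Edmonds' blossom
#' algorithm) over the atoms that surrendered one pi electron assigns
#' alternating double bonds: matched bonds become double, all other
#' aromatic bonds single. Lone-pair donors stay unmatched. A system whose
#' pi-contributing atoms cannot all be covered is malformed and raises a
#' StructureError.
#'
#' @param s a perceived Structure.
#' @return a Structure with single/double bond types only.
#' @export
kekulise <- function(s) {
  if (!s$aromaticity_done) s <- perceive_rings_and_aromaticity(s)
  for (sys in s$aromatic_systems) {
    matchable <- as.integer(names(sys$contribution)[sys$contribution == 1L])
    verts <- matchable
    nv <- length(verts)
    edges <- list()
    for (bi in sys$bonds) {
      b <- s$bonds[[ak(bi)]]
      u <- match(b$a, verts)
      v <- match(b$b, verts)
      if (!is.na(u) && !is.na(v)) edges[[length(edges) + 1L]] <- c(u, v)
    }
    mm <- maximum_matching(nv, edges)
    if (any(mm == 0L)) {
      structure_error("bonding-law violation",
                      "aromatic system cannot be kekulised")
    }
    for (bi in sys$bonds) {
      b <- s$bonds[[ak(bi)]]
      u <- match(b$a, verts)
      v <- match(b$b, verts)
      if (!is.na(u) && !is.na(v) && mm[u] == v) {
        s$bonds[[ak(bi)]]$type <- "double"
      } else {
        s$bonds[[ak(bi)]]$type <- "single"
      }
    }
  }
  s$kekulised <- TRUE
  s
}
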