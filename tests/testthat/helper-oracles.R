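# Independent oracles used by the suite. These deliberately use different
# algorithms (subset enumeration, exhaustive backtracking, external
# canonicalisation) from the package implementations they check.

# canonical key of a cycle given as a vertex sequence: rotate the smallest
# vertex to the front, then take the lexicographically smaller direction
canonical_cycle_key <- function(seq_atoms) {
  n <- length(seq_atoms)
  i <- which.min(seq_atoms)
  fwd <- seq_atoms[((i - 1L + seq_len(n) - 1L) %% n) + 1L]
  rev_seq <- rev(seq_atoms)
  j <- which.min(rev_seq)
  bwd <- rev_seq[((j - 1L + seq_len(n) - 1L) %% n) + 1L]
  paste(if (paste(fwd, collapse = ",") <= paste(bwd, collapse = ",")) fwd
        else bwd, collapse = ",")
}

# --- brute-force simple cycles: every elementary cycle on a vertex subset
# is a Hamiltonian cycle of that induced subgraph; enumerate them all by
# DFS from the subset's smallest vertex, deduplicating direction
oracle_cycles <- function(s) {
  verts <- Filter(function(i) s$atoms[[as.character(i)]]$element != "H",
                  vapply(s$atoms, function(a) a$index, integer(1)))
  verts <- sort(unname(verts))
  n <- length(verts)
  adj <- lapply(verts, function(v) intersect(neighbours(s, v), verts))
  names(adj) <- as.character(verts)
  out <- list()
  if (n < 3) return(out)
  for (mask in seq_len(2^n - 1)) {
    subset <- verts[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    if (length(subset) < 3) next
    degs <- vapply(subset, function(v) {
      length(intersect(adj[[as.character(v)]], subset))
    }, integer(1))
    if (any(degs < 2)) next
    root <- subset[[1]]
    path <- root
    dfs <- function(v) {
      nbs <- intersect(adj[[as.character(v)]], subset)
      for (w in nbs) {
        if (w == root && length(path) == length(subset)) {
          if (path[[2]] < path[[length(path)]]) {
            out[[length(out) + 1L]] <<- path
          }
        } else if (!(w %in% path)) {
          path <<- c(path, w)
          dfs(w)
          path <<- path[-length(path)]
        }
      }
    }
    dfs(root)
  }
  out
}

# --- brute-force maximum matching by edge-subset recursion
oracle_max_matching_size <- function(n, edges) {
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (length(edges) - i + 1L) <= best) return(invisible())
    if (i > length(edges)) {
      if (count > best) best <<- count
      return(invisible())
    }
    e <- edges[[i]]
    if (!used[e[[1]]] && !used[e[[2]]]) {
      used[e[[1]]] <- TRUE; used[e[[2]]] <- TRUE
      recurse(i + 1L, used, count + 1L)
      used[e[[1]]] <- FALSE; used[e[[2]]] <- FALSE
    }
    recurse(i + 1L, used, count)
  }
  recurse(1L, logical(n), 0L)
  best
}

# --- exhaustive substructure embeddings (no prefilters, no seeding):
# plain backtracking in substructure atom-index order
oracle_embeddings <- function(sub, super) {
  heavy <- function(s) {
    sort(Filter(function(i) s$atoms[[as.character(i)]]$element != "H",
                vapply(s$atoms, function(a) a$index, integer(1))))
  }
  sub_h <- heavy(sub)
  sup_h <- heavy(super)
  results <- list()
  assign_next <- function(pos, mapping) {
    if (pos > length(sub_h)) {
      results[[length(results) + 1L]] <<- mapping
      return(invisible())
    }
    v <- sub_h[[pos]]
    for (cand in setdiff(sup_h, unlist(mapping))) {
      if (sub$atoms[[as.character(v)]]$element !=
          super$atoms[[as.character(cand)]]$element) next
      ok <- TRUE
      for (w in sub_h[seq_len(pos - 1L)]) {
        sb <- bond_between(sub, v, w)
        pb <- bond_between(super, cand, mapping[[as.character(w)]])
        if (is.null(sb)) next
        if (is.null(pb) || pb$type != sb$type) { ok <- FALSE; break }
      }
      if (!ok) next
      mapping[[as.character(v)]] <- cand
      assign_next(pos + 1L, mapping)
      mapping[[as.character(v)]] <- NULL
    }
  }
  assign_next(1L, list())
  # collapse to matched atom sets (matching the package's deduplication)
  unique(lapply(results, function(m) sort(unname(unlist(m)))))
}

# --- labelled graph isomorphism through igraph VF2 (element+charge as
# vertex colours, bond type as edge colours)
structures_isomorphic <- function(s1, s2) {
  enc <- function(s) {
    idx <- sort(vapply(s$atoms, function(a) a$index, integer(1)))
    vcol <- vapply(idx, function(i) {
      a <- s$atoms[[as.character(i)]]
      h <- sum(vapply(neighbours(s, i), function(j)
        s$atoms[[as.character(j)]]$element == "H", logical(1)))
      paste(a$element, a$charge, h)
    }, character(1))
    heavy <- idx[vapply(idx, function(i)
      s$atoms[[as.character(i)]]$element != "H", logical(1))]
    el <- matrix(0L, 0, 2)
    ecol <- character()
    for (b in s$bonds) {
      if (b$a %in% heavy && b$b %in% heavy) {
        el <- rbind(el, c(match(b$a, heavy), match(b$b, heavy)))
        ecol <- c(ecol, b$type)
      }
    }
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (igraph::vcount(g) < length(heavy)) {
      g <- igraph::add_vertices(g, length(heavy) - igraph::vcount(g))
    }
    list(g = g, vcol = vcol[match(heavy, idx)], ecol = ecol)
  }
  a <- enc(s1); b <- enc(s2)
  if (igraph::vcount(a$g) != igraph::vcount(b$g) ||
      igraph::ecount(a$g) != igraph::ecount(b$g)) return(FALSE)
  lv <- union(a$vcol, b$vcol); le <- union(a$ecol, b$ecol)
  igraph::isomorphic(a$g, b$g, method = "vf2",
                     vertex.color1 = match(a$vcol, lv),
                     vertex.color2 = match(b$vcol, lv),
                     edge.color1 = match(a$ecol, le),
                     edge.color2 = match(b$ecol, le))
}

# --- external canonicaliser (RDKit via python), batched in one call
rdkit_canon <- function(smiles) {
  inp <- tempfile(fileext = ".smi")
  writeLines(smiles, inp)
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import sys\n",
      "from rdkit import Chem\n",
      "from rdkit import RDLogger\n",
      "RDLogger.DisableLog('rdApp.*')\n",
      "for line in open(sys.argv[1]):\n",
      "    line = line.strip()\n",
      "    try:\n",
      "        print(Chem.CanonSmiles(line))\n",
      "    except Exception:\n",
      "        print('<error>')\n")), inp),
    stdout = TRUE))
  out
}

# RDKit reads MOL files and reports isomeric canonical SMILES
rdkit_mol_to_smiles <- function(paths) {
  inp <- tempfile(fileext = ".txt")
  writeLines(paths, inp)
  suppressWarnings(system2(
    "python",
    c("-c", shQuote(paste0(
      "import sys\n",
      "from rdkit import Chem\n",
      "from rdkit import RDLogger\n",
      "RDLogger.DisableLog('rdApp.*')\n",
      "for line in open(sys.argv[1]):\n",
      "    try:\n",
      "        m = Chem.MolFromMolFile(line.strip())\n",
      "        print(Chem.MolToSmiles(m))\n",
      "    except Exception:\n",
      "        print('<error>')\n")), inp),
    stdout = TRUE))
}

# --- seeded random connected graphs as Structures (all-carbon skeletons
# are not valence-legal in general, so these bypass parsing and are used
# only for pure graph algorithms: cycles, SSSR)
random_graph_structure <- function(n, extra_edges, seed) {
  set.seed(seed)
  atoms <- lapply(seq_len(n) - 1L, function(i) new_atom(i, "C"))
  bonds <- list()
  bi <- 0L
  for (v in seq_len(n - 1L)) {
    u <- sample(v, 1) - 1L
    bonds[[length(bonds) + 1L]] <- new_bond(bi, u, v)
    bi <- bi + 1L
  }
  present <- vapply(bonds, function(b) paste(sort(c(b$a, b$b)), collapse = "-"),
                    character(1))
  avail <- list()
  for (u in 0:(n - 2L)) {
    for (v in (u + 1L):(n - 1L)) {
      if (!(paste(u, v, sep = "-") %in% present)) {
        avail[[length(avail) + 1L]] <- c(u, v)
      }
    }
  }
  if (length(avail) && extra_edges > 0) {
    for (e in sample(avail, min(extra_edges, length(avail)))) {
      bonds[[length(bonds) + 1L]] <- new_bond(bi, e[[1]], e[[2]])
      bi <- bi + 1L
    }
  }
  build_structure(atoms, bonds)
}

# GF(2) rank of a set of cycles in bond space (independent elimination
# implementation used to verify minimum-cycle-basis sizes)
gf2_rank <- function(vectors) {
  if (length(vectors) == 0) return(0L)
  m <- do.call(rbind, vectors)
  rank <- 0L
  col <- 1L
  while (col <= ncol(m) && rank < nrow(m)) {
    piv <- which(m[, col] & seq_len(nrow(m)) > rank)[1]
    if (!is.na(piv)) {
      rank <- rank + 1L
      if (piv != rank) m[c(piv, rank), ] <- m[c(rank, piv), ]
      for (r in seq_len(nrow(m))) {
        if (r != rank && m[r, col]) m[r, ] <- xor(m[r, ], m[rank, ])
      }
    }
    col <- col + 1L
  }
  rank
}

cycle_bond_vector <- function(s, cyc_seq, all_bonds) {
  # the cycle is an atom sequence; its bonds are the consecutive pairs
  m <- length(cyc_seq)
  ids <- vapply(seq_len(m), function(i) {
    bond_between(s, cyc_seq[[i]], cyc_seq[[i %% m + 1L]])$index
  }, integer(1))
  all_bonds %in% ids
}

# curated molecule set covering rings, aromatics, charges, stereocentres
# and bond stereochemistry (plus alternative spellings of some)
curated_smiles <- function() {
  c("C", "CC", "CCO", "CC(C)C", "CC(C)(C)C", "C=C", "C#N", "CC#CC",
    "c1ccccc1", "C1=CC=CC=C1", "Cc1ccccc1", "c1ccc2ccccc2c1",
    "c1cc[nH]c1", "c1ccncc1", "c1ccsc1", "c1ccoc1", "c1cnc[nH]1",
    "C1CCCCC1", "C1CCC1", "C1CC2CCC1C2", "C12C3C4C1C5C2C3C45",
    "CC(=O)O", "CC(=O)[O-]", "C[N+](C)(C)C", "[NH4+]", "CN(=O)=O",
    "O=S(=O)(O)O", "OP(=O)(O)O", "CCS", "CSC", "CBr", "CCl", "CI", "CF",
    "N[C@@H](C)C(=O)O", "N[C@H](C)C(=O)O", "C[C@H](N)C(=O)O",
    "OC[C@@H](N)C(=O)O", "N[C@@H](Cc1ccccc1)C(=O)O", "C[C@H]1CCCO1",
    "CC[C@H](C)[C@@H](C)CC", "C/C=C/C", "C/C=C\\C", "F/C=C/F",
    "F/C=C\\F", "C/C=C(\\N)/C", "c1ccc(cc1)/C=C/c1ccccc1",
    "CC(=O)Oc1ccccc1C(=O)O", "CC(=O)NC", "O=C1CCCCC1", "C[C@@H](N)c1ccccc1")
}
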