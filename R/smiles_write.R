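# SMILES writer: kekulised output, deterministic depth-first atom ordering,
# charges, tetrahedral chirality and cis/trans marks re-emitted.

# parity (+1 even / -1 odd) of the permutation taking `from` to `to`
permutation_parity <- function(from, to) {
  perm <- match(to, from)
  if (anyNA(perm)) return(NA_integer_)
  sign <- 1L
  perm <- as.integer(perm)
  n <- length(perm)
  seen <- logical(n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    j <- i
    clen <- 0L
    while (!seen[j]) {
      seen[j] <- TRUE
      j <- perm[j]
      clen <- clen + 1L
    }
    if (clen %% 2L == 0L) sign <- -sign
  }
  sign
}

.bond_symbol <- function(type) {
  switch(type, single = "", double = "=", triple = "#", quadruple = "$",
         aromatic = ":")
}

# Can this atom be written as a bare organic-subset symbol?
.organic_writable <- function(s, a, h_count) {
  if (!(a$element %in% .organic_subset)) return(FALSE)
  if (a$charge != 0L || a$chiral != "none") return(FALSE)
  heavy_sum <- 0
  for (bi in s$adj[[ak(a$index)]]) {
    b <- s$bonds[[ak(bi)]]
    other <- if (b$a == a$index) b$b else b$a
    if (s$atoms[[ak(other)]]$element != "H") {
      heavy_sum <- heavy_sum + bond_order(b$type)
    }
  }
  av <- allowed_valences(a$element, 0L)
  fit <- av[av >= heavy_sum]
  length(fit) > 0 && (fit[[1]] - heavy_sum) == h_count
}

.atom_token <- function(s, a, h_count, chiral_sym) {
  if (chiral_sym == "" && .organic_writable(s, a, h_count)) {
    return(a$element)
  }
  hc <- if (h_count == 0) "" else if (h_count == 1) "H" else paste0("H", h_count)
  ch <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else
    if (a$charge == -1L) "-" else sprintf("%+d", a$charge)
  paste0("[", a$element, chiral_sym, hc, ch, "]")
}

# Solve directional-bond orientations for all stereo double bonds.
# Returns named list bond_key -> +1/-1, the "side" of the canonically
# higher-indexed endpoint relative to the lower one (+1 = up); NULL entries
# mean the bond carries no mark.
.solve_directions <- function(s) {
  # variables: single bonds that act as reference substituent bonds
  cons <- list()   # list of (b1, o1, b2, o2, rel): f1*o1 * f2*o2 == rel
  var_bonds <- character()
  side_fun <- function(db_atom, sub) {
    b <- bond_between(s, db_atom, sub)
    key <- ak(b$index)
    orient <- if (min(b$a, b$b) == db_atom) 1L else -1L
    list(key = key, orient = orient)
  }
  for (bk in names(s$bonds)) {
    b <- s$bonds[[bk]]
    if (b$type != "double" || is.null(b$stereo)) next
    st <- b$stereo
    ra <- side_fun(b$a, st$ref_a)
    rb <- side_fun(b$b, st$ref_b)
    rel <- if (st$config == "cis") 1L else -1L
    cons[[length(cons) + 1L]] <- list(k1 = ra$key, o1 = ra$orient,
                                      k2 = rb$key, o2 = rb$orient, rel = rel)
    var_bonds <- union(var_bonds, c(ra$key, rb$key))
    # opposite-side constraints for sibling substituents on each end, so a
    # reader never sees two marks implying the same side
    for (end in c(b$a, b$b)) {
      subs <- setdiff(neighbours(s, end, heavy_only = TRUE), c(b$a, b$b))
      if (length(subs) == 2) {
        s1 <- side_fun(end, subs[[1]])
        s2 <- side_fun(end, subs[[2]])
        b1 <- s$bonds[[s1$key]]; b2 <- s$bonds[[s2$key]]
        if (b1$type == "single" && b2$type == "single") {
          cons[[length(cons) + 1L]] <- list(k1 = s1$key, o1 = s1$orient,
                                            k2 = s2$key, o2 = s2$orient,
                                            rel = -1L)
          var_bonds <- union(var_bonds, c(s1$key, s2$key))
        }
      }
    }
  }
  if (length(var_bonds) == 0) return(list())
  val <- stats::setNames(rep(NA_integer_, length(var_bonds)), var_bonds)
  # propagate constraints (union of +/- relations); BFS per component
  adj <- stats::setNames(vector("list", length(var_bonds)), var_bonds)
  for (cn in cons) {
    adj[[cn$k1]] <- c(adj[[cn$k1]], list(cn))
    adj[[cn$k2]] <- c(adj[[cn$k2]],
                      list(list(k1 = cn$k2, o1 = cn$o2, k2 = cn$k1,
                                o2 = cn$o1, rel = cn$rel)))
  }
  for (seed in var_bonds) {
    if (!is.na(val[[seed]])) next
    val[[seed]] <- 1L
    queue <- seed
    while (length(queue)) {
      k <- queue[[1]]; queue <- queue[-1]
      for (cn in adj[[k]]) {
        # f(k)*o1 * f(k2)*o2 == rel  =>  f(k2) = rel * o1 * o2 * f(k)
        want <- cn$rel * cn$o1 * cn$o2 * val[[k]]
        if (is.na(val[[cn$k2]])) {
          val[[cn$k2]] <- want
          queue <- c(queue, cn$k2)
        } else if (val[[cn$k2]] != want) {
          chirality_error(
            "cis/trans marks cannot be assigned consistently for output")
        }
      }
    }
  }
  as.list(val)
}

#' Write a structure as a SMILES string
#'
#' Output is kekulised (uppercase symbols), uses a deterministic
#' depth-first walk from the lowest-index heavy atom of each component,
#' and re-emits formal charges, tetrahedral chirality and cis/trans marks.
#' No canonicalisation is claimed: equivalent structures may yield
#' different but chemically identical strings.
#'
#' @param s a validated Structure.
#' @param root optional atom index to start the walk from (spelling
#'   variation; the default is the lowest heavy atom index).
#' @return a SMILES string whose parse is graph-isomorphic to `s`.
#' @export
write_smiles <- function(s, root = NULL) {
  s <- kekulise(s)
  dirs <- .solve_directions(s)
  heavy <- sort(atom_indices(s)[vapply(s$atoms, function(a) a$element != "H",
                                       logical(1))])
  if (length(heavy) == 0) {
    # hydrogen(-only) molecule
    return(paste(rep("[H]", length(s$atoms)), collapse = "."))
  }
  visited <- new.env(parent = emptyenv())
  out_parts <- character()

  for (comp_root in heavy) {
    if (!is.null(visited[[ak(comp_root)]])) next
    start <- if (!is.null(root) && is.null(visited[[ak(root)]]) &&
                 length(shortest_path_atoms(s, comp_root, root))) {
      root
    } else {
      comp_root
    }

    # pass 1: discover tree order and ring-closure (back) edges
    tree_children <- new.env(parent = emptyenv())
    back_edges <- list()
    seen <- new.env(parent = emptyenv())
    walk <- function(v, parent) {
      seen[[ak(v)]] <- TRUE
      kids <- integer()
      for (w in sort(neighbours(s, v, heavy_only = TRUE))) {
        if (!is.na(parent) && w == parent) next
        if (!is.null(seen[[ak(w)]])) {
          key <- paste(sort(c(v, w)), collapse = "-")
          if (!any(vapply(back_edges, function(e) e$key == key, logical(1)))) {
            back_edges[[length(back_edges) + 1L]] <<-
              list(key = key, open = w, close = v)
          }
        } else {
          kids <- c(kids, w)
          walk(w, v)
        }
      }
      tree_children[[ak(v)]] <- kids
    }
    walk(start, NA_integer_)

    # ring-closure labels per atom, in stable order
    labels_at <- new.env(parent = emptyenv())
    label_of <- list()
    next_label <- 1L
    for (e in back_edges) {
      label_of[[e$key]] <- next_label
      for (at in c(e$open, e$close)) {
        labels_at[[ak(at)]] <- c(labels_at[[ak(at)]], list(
          list(label = next_label, other = setdiff(c(e$open, e$close), at))))
      }
      next_label <- next_label + 1L
    }

    dir_symbol <- function(from, to) {
      b <- bond_between(s, from, to)
      v <- dirs[[ak(b$index)]]
      if (is.null(v) || is.na(v)) return("")
      side_to <- if (min(b$a, b$b) == from) v else -v
      if (side_to == 1L) "/" else "\\"
    }
    bond_token <- function(from, to) {
      b <- bond_between(s, from, to)
      if (b$type == "single") dir_symbol(from, to) else .bond_symbol(b$type)
    }

    emit <- function(v, parent) {
      visited[[ak(v)]] <- TRUE
      a <- s$atoms[[ak(v)]]
      h_nb <- neighbours(s, v)[vapply(neighbours(s, v), function(j)
        s$atoms[[ak(j)]]$element == "H", logical(1))]
      closures <- labels_at[[ak(v)]]
      kids <- tree_children[[ak(v)]]

      chiral_sym <- ""
      if (a$chiral != "none") {
        written <- c(
          if (!is.na(parent)) parent,
          if (length(h_nb)) h_nb[[1]],
          vapply(closures, function(cl) cl$other, integer(1)),
          kids
        )
        par <- permutation_parity(a$chiral_order, written)
        eff <- a$chiral
        if (!is.na(par) && par == -1L) {
          eff <- if (eff == "clockwise") "counterclockwise" else "clockwise"
        }
        chiral_sym <- if (eff == "counterclockwise") "@" else "@@"
      }
      h_count <- length(h_nb)
      token <- .atom_token(s, a, h_count, chiral_sym)
      for (cl in closures) {
        lab <- if (cl$label < 10) as.character(cl$label) else
          sprintf("%%%02d", cl$label)
        # emit a direction mark only at the opening digit
        sym <- if (is.null(visited[[ak(cl$other)]])) {
          bond_token(v, cl$other)
        } else {
          b <- bond_between(s, v, cl$other)
          if (b$type == "single") "" else .bond_symbol(b$type)
        }
        token <- paste0(token, sym, lab)
      }
      n_k <- length(kids)
      for (i in seq_along(kids)) {
        w <- kids[[i]]
        sub <- paste0(bond_token(v, w), emit(w, v))
        token <- if (i < n_k) paste0(token, "(", sub, ")") else
          paste0(token, sub)
      }
      token
    }
    out_parts <- c(out_parts, emit(start, NA_integer_))
  }
  paste(out_parts, collapse = ".")
}
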