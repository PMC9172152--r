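# 2D structure diagram layout.
#
# Ring systems are placed as units: simple and overlapping rings by
# regular-polygon geometry, bridged systems by a Kamada-Kawai force-spring
# start-on-a-circle refinement. Chain atoms follow at one bond length with
# angles set by neighbour count and branch depth; stereo-restricted double
# bonds are forced into their declared cis/trans arrangement. Coordinates
# use mathematical axes (y up) in bond-length units (1.0 = one bond).

#' Drawing options
#'
#' @param finetune rotate acyclic bonds to resolve steric clashes.
#' @param rotation_step candidate rotation increment in degrees (must
#'   divide 360; 12 rotations at 30 degrees by default).
#' @param clash_threshold clash distance as a fraction of the mean bond
#'   length (strict less-than).
#' @param show_hydrogens draw hydrogens as explicit atoms.
#' @param scale pixels per bond length at render time.
#' @return a `chemkit_draw_options` list.
#' @export
draw_options <- function(finetune = TRUE, rotation_step = 30,
                         clash_threshold = 0.5, show_hydrogens = FALSE,
                         scale = 50) {
  stopifnot(360 %% rotation_step == 0)
  structure(list(finetune = finetune, rotation_step = rotation_step,
                 clash_threshold = clash_threshold,
                 show_hydrogens = show_hydrogens, scale = scale),
            class = "chemkit_draw_options")
}

#' Classify SSSR rings as simple, overlapping or bridged
#'
#' Simple rings share no atoms with any other ring. Overlapping rings
#' share atoms with other rings, where any pairwise overlap is at most two
#' atoms, every overlap atom is in at most two rings, and no overlap
#' touches a bridged ring. All remaining rings -- sharing more than two
#' atoms with another ring, containing an atom in three or more rings, or
#' sharing atoms with another bridged ring -- are bridged; bridged rings
#' sharing atoms are merged into bridged ring systems.
#'
#' @param s a Structure (ring caches are computed if absent).
#' @return list with `labels` (per SSSR ring), `rings` (the SSSR), and
#'   `systems` (merged atom sets of bridged ring systems).
#' @export
classify_rings <- function(s) {
  if (is.null(s$rings)) s <- perceive_rings_and_aromaticity(s)
  rings <- s$rings$sssr
  n <- length(rings)
  if (n == 0) return(list(labels = character(), rings = rings, systems = list()))
  atom_ring_count <- table(unlist(rings))
  overlap <- function(i, j) intersect(rings[[i]], rings[[j]])
  bridged <- logical(n)
  for (i in seq_len(n)) {
    if (any(atom_ring_count[as.character(rings[[i]])] >= 3)) bridged[i] <- TRUE
    for (j in seq_len(n)) {
      if (i != j && length(overlap(i, j)) > 2) bridged[i] <- TRUE
    }
  }
  repeat {
    changed <- FALSE
    for (i in which(!bridged)) {
      for (j in which(bridged)) {
        if (length(overlap(i, j))) { bridged[i] <- TRUE; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  labels <- rep("simple", n)
  labels[bridged] <- "bridged"
  for (i in which(!bridged)) {
    if (any(vapply(seq_len(n), function(j) i != j && length(overlap(i, j)) > 0,
                   logical(1)))) {
      labels[i] <- "overlapping"
    }
  }
  # merge bridged rings sharing atoms into systems
  systems <- list()
  todo <- which(bridged)
  while (length(todo)) {
    grp <- todo[[1]]
    repeat {
      grown <- FALSE
      for (j in setdiff(todo, grp)) {
        if (any(vapply(grp, function(i) length(overlap(i, j)) > 0,
                       logical(1)))) {
          grp <- c(grp, j)
          grown <- TRUE
        }
      }
      if (!grown) break
    }
    systems[[length(systems) + 1L]] <- sort(unique(unlist(rings[grp])))
    todo <- setdiff(todo, grp)
  }
  list(labels = labels, rings = rings, systems = systems)
}

# ---- geometry helpers ------------------------------------------------------

.rot <- function(p, theta) {
  c(cos(theta) * p[1] - sin(theta) * p[2],
    sin(theta) * p[1] + cos(theta) * p[2])
}
.ang <- function(v) atan2(v[2], v[1])
.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) c(1, 0) else v / n
}
.cross_sign <- function(a, b) sign(a[1] * b[2] - a[2] * b[1])

# reflect point p across the line through q with direction d
.reflect <- function(p, q, d) {
  d <- .unit(d)
  v <- p - q
  par <- sum(v * d) * d
  q + 2 * par - v
}

# heavy-atom subtree size behind bond from -> to (to-side), for branch
# depth/priority decisions
.subtree_atoms <- function(s, from, to) {
  seen <- c(from, to)
  queue <- to
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    for (w in neighbours(s, v, heavy_only = TRUE)) {
      if (!(w %in% seen)) {
        seen <- c(seen, w)
        queue <- c(queue, w)
      }
    }
  }
  setdiff(seen, from)
}

# longest-path depth of the branch entered by bond from -> to
.branch_depth <- function(s, from, to) {
  best <- 0L
  depth <- function(v, seen, d) {
    if (d > best) best <<- d
    for (w in neighbours(s, v, heavy_only = TRUE)) {
      if (!(w %in% seen)) depth(w, c(seen, w), d + 1L)
    }
  }
  depth(to, c(from, to), 1L)
  best
}

# ---- ring system local coordinates ----------------------------------------

# order the atoms of one ring as they appear around the cycle
.ring_polygon <- function(m) {
  r <- 0.5 / sin(pi / m)
  t(vapply(seq_len(m) - 1L, function(k) {
    c(r * cos(2 * pi * k / m + pi / 2), r * sin(2 * pi * k / m + pi / 2))
  }, numeric(2)))
}

# local coordinates for a polygon-composable ring system; NULL when the
# composition rules do not apply (caller falls back to Kamada-Kawai)
.polygon_system_coords <- function(s, rings) {
  coords <- list()
  centres <- list()
  place_first <- function(ri) {
    cyc <- rings[[ri]]
    poly <- .ring_polygon(length(cyc))
    for (i in seq_along(cyc)) coords[[ak(cyc[[i]])]] <<- poly[i, ]
    centres[[ri]] <<- c(0, 0)
  }
  place_fused <- function(ri, placed_set) {
    cyc <- rings[[ri]]
    m <- length(cyc)
    shared <- cyc[vapply(cyc, function(a) !is.null(coords[[ak(a)]]),
                         logical(1))]
    if (length(shared) == 1) {
      # spiro: polygon on the far side of the shared atom
      u <- shared[[1]]
      pu <- coords[[ak(u)]]
      prev_centre <- NULL
      for (cj in seq_along(centres)) {
        if (!is.null(centres[[cj]]) && u %in% rings[[cj]]) {
          prev_centre <- centres[[cj]]
        }
      }
      dir <- .unit(pu - (prev_centre %||% (pu - c(1, 0))))
      r <- 0.5 / sin(pi / m)
      centre <- pu + dir * r
      # vertices around centre starting at u
      start <- .ang(pu - centre)
      pos <- match(u, cyc)
      for (k in seq_len(m) - 1L) {
        at <- cyc[[(pos - 1L + k) %% m + 1L]]
        theta <- start + 2 * pi * k / m
        coords[[ak(at)]] <<- centre + r * c(cos(theta), sin(theta))
      }
      centres[[ri]] <<- centre
      return(TRUE)
    }
    if (length(shared) != 2) return(FALSE)
    u <- shared[[1]]; v <- shared[[2]]
    if (is.null(bond_between(s, u, v))) return(FALSE)
    pu <- coords[[ak(u)]]; pv <- coords[[ak(v)]]
    # centre on the opposite side of uv from the neighbour ring's centre
    prev_centre <- NULL
    for (cj in seq_along(centres)) {
      if (cj != ri && !is.null(centres[[cj]]) && u %in% rings[[cj]] &&
          v %in% rings[[cj]]) {
        prev_centre <- centres[[cj]]
      }
    }
    mid <- (pu + pv) / 2
    r <- 0.5 / sin(pi / m)
    apo <- sqrt(max(r^2 - 0.25, 0))
    n1 <- .unit(.rot(pv - pu, pi / 2))
    side <- if (!is.null(prev_centre)) -.cross_sign(pv - pu, prev_centre - pu) else 1
    if (side == 0) side <- 1
    centre <- mid + n1 * apo * side
    # walk the ring from u towards v the long way round, placing vertices
    pos_u <- match(u, cyc)
    step <- if (cyc[[pos_u %% m + 1L]] == v) -1L else 1L
    theta_u <- .ang(pu - centre)
    theta_v <- .ang(pv - centre)
    # angular direction from u consistent with going the long way to v
    dtheta <- 2 * pi / m
    rot_dir <- -.cross_sign(pu - centre, pv - centre)
    if (rot_dir == 0) rot_dir <- 1
    idx <- pos_u
    theta <- theta_u
    for (k in seq_len(m - 1L)) {
      idx <- (idx - 1L + step) %% m + 1L
      theta <- theta + rot_dir * dtheta
      at <- cyc[[idx]]
      if (is.null(coords[[ak(at)]])) {
        coords[[ak(at)]] <<- centre + r * c(cos(theta), sin(theta))
      }
    }
    centres[[ri]] <<- centre
    TRUE
  }

  n <- length(rings)
  placed <- logical(n)
  place_first(1L)
  placed[1] <- TRUE
  while (!all(placed)) {
    progressed <- FALSE
    for (ri in which(!placed)) {
      shared_any <- any(vapply(rings[[ri]], function(a)
        !is.null(coords[[ak(a)]]), logical(1)))
      if (!shared_any) next
      if (!place_fused(ri, placed)) return(NULL)
      placed[ri] <- TRUE
      progressed <- TRUE
    }
    if (!progressed) return(NULL)
  }
  coords
}

# Kamada-Kawai coordinates for a bridged system: atoms start on a circle
# and are pulled to their optimal positions (igraph implementation);
# rescaled so the mean bond length is 1.
.kk_system_coords <- function(s, atoms) {
  n <- length(atoms)
  el <- matrix(0L, nrow = 0, ncol = 2)
  for (bk in names(s$bonds)) {
    b <- s$bonds[[bk]]
    u <- match(b$a, atoms); v <- match(b$b, atoms)
    if (!is.na(u) && !is.na(v)) el <- rbind(el, c(u, v))
  }
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  start <- cbind(cos(2 * pi * seq_len(n) / n), sin(2 * pi * seq_len(n) / n))
  xy <- igraph::layout_with_kk(g, coords = start, dim = 2)
  lens <- sqrt(rowSums((xy[el[, 1], , drop = FALSE] -
                          xy[el[, 2], , drop = FALSE])^2))
  xy <- xy / mean(lens)
  out <- list()
  for (i in seq_len(n)) out[[ak(atoms[[i]])]] <- xy[i, ]
  out
}

# ---- the main layout -------------------------------------------------------

#' Compute 2D coordinates for a structure
#'
#' @param structure a validated Structure (it is kekulised internally; the
#'   drawing shows alternating single/double bonds).
#' @param options a [draw_options()] list.
#' @return an object of class `chemkit_drawing`: the kekulised structure,
#'   a coordinate matrix (bond-length units, y up), wedge assignments, and
#'   colour maps.
#' @examples
#' d <- layout_molecule(parse_smiles("CCO"))
#' nrow(d$coords)
#' @export
layout_molecule <- function(structure, options = draw_options()) {
  ks <- kekulise(structure)
  rc <- classify_rings(ks)
  rings <- rc$rings
  # ring systems: connected components of SSSR rings sharing atoms
  nr <- length(rings)
  sys_id <- seq_len(nr)
  if (nr > 1) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nr - 1)) {
        for (j in (i + 1):nr) {
          if (length(intersect(rings[[i]], rings[[j]])) &&
              sys_id[i] != sys_id[j]) {
            sys_id[sys_id == sys_id[j]] <- sys_id[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  ring_systems <- lapply(unique(sys_id), function(g) {
    list(rings = rings[sys_id == g],
         atoms = sort(unique(unlist(rings[sys_id == g]))),
         bridged = any(rc$labels[sys_id == g] == "bridged"))
  })
  system_of_atom <- list()
  for (si in seq_along(ring_systems)) {
    for (a in ring_systems[[si]]$atoms) system_of_atom[[ak(a)]] <- si
  }

  heavy <- .heavy_atoms(ks)
  coords <- list()
  placed_sys <- logical(length(ring_systems))

  system_local <- function(si) {
    sys <- ring_systems[[si]]
    if (!sys$bridged) {
      loc <- .polygon_system_coords(ks, sys$rings)
      if (!is.null(loc)) return(loc)
    }
    .kk_system_coords(ks, sys$atoms)
  }

  place_system <- function(si, anchor_atom, target_pos, dir) {
    loc <- system_local(si)
    keys <- names(loc)
    if (is.null(anchor_atom)) {
      for (k in keys) coords[[k]] <<- loc[[k]]
    } else {
      origin <- loc[[ak(anchor_atom)]]
      centroid <- Reduce(`+`, loc) / length(loc)
      cur <- centroid - origin
      theta <- .ang(dir) - .ang(cur)
      for (k in keys) {
        coords[[k]] <<- target_pos + .rot(loc[[k]] - origin, theta)
      }
    }
    placed_sys[si] <<- TRUE
  }

  # ring substituent directions: outside the ring along the bisector
  ring_substituent_dirs <- function(v, n_needed) {
    nb_ring <- intersect(neighbours(ks, v, heavy_only = TRUE),
                         ring_systems[[system_of_atom[[ak(v)]]]]$atoms)
    nb_ring <- nb_ring[vapply(nb_ring, function(w)
      !is.null(coords[[ak(w)]]), logical(1))]
    p <- coords[[ak(v)]]
    if (length(nb_ring) >= 2) {
      d <- -.unit(.unit(coords[[ak(nb_ring[[1]])]] - p) +
                    .unit(coords[[ak(nb_ring[[2]])]] - p))
    } else if (length(nb_ring) == 1) {
      d <- -.unit(coords[[ak(nb_ring[[1]])]] - p)
    } else {
      d <- c(1, 0)
    }
    if (n_needed == 1) return(list(d))
    base <- .ang(d)
    lapply(seq_len(n_needed), function(i) {
      off <- (i - (n_needed + 1) / 2) * pi / 3
      c(cos(base + off), sin(base + off))
    })
  }

  place_atom <- function(v, pos) coords[[ak(v)]] <<- pos

  # depth-first placement; child directions for all children are fixed
  # before recursion so stereo references always have coordinates
  descend <- function(v, parent, zig) {
    in_ring <- !is.null(system_of_atom[[ak(v)]])
    kids <- setdiff(neighbours(ks, v, heavy_only = TRUE),
                    if (is.null(parent)) integer() else parent)
    kids <- kids[vapply(kids, function(w) is.null(coords[[ak(w)]]),
                        logical(1))]
    if (length(kids) == 0) return(invisible())

    if (in_ring) {
      sys_atoms <- ring_systems[[system_of_atom[[ak(v)]]]]$atoms
      kids <- setdiff(kids, sys_atoms)  # ring atoms already placed
      if (length(kids) == 0) return(invisible())
      dirs <- ring_substituent_dirs(v, length(kids))
      # deeper branches get the straighter (more central) direction
      depths <- vapply(kids, function(w) .branch_depth(ks, v, w), integer(1))
      kids <- kids[order(-depths)]
      mid <- order(vapply(dirs, function(d) {
        abs(.ang(d) - .ang(dirs[[ceiling(length(dirs) / 2)]]))
      }, numeric(1)))
      for (i in seq_along(kids)) {
        assign_child(v, kids[[i]], dirs[[mid[[i]]]], zig)
      }
      for (w in kids) descend(w, v, -zig)
      return(invisible())
    }

    p <- coords[[ak(v)]]
    incoming <- if (!is.null(parent)) .ang(p - coords[[ak(parent)]]) else pi / 6
    n_heavy <- length(neighbours(ks, v, heavy_only = TRUE))
    depths <- vapply(kids, function(w) .branch_depth(ks, v, w), integer(1))
    ord <- order(-depths, kids)
    kids <- kids[ord]
    depths <- depths[ord]

    sp_linear <- identical(ks$atoms[[ak(v)]]$hybridisation, "sp")
    angles <- if (is.null(parent)) {
      # root atom: spread children evenly
      incoming + (seq_along(kids) - 1L) * 2 * pi / max(length(kids), 1)
    } else if (sp_linear) {
      incoming + c(0, pi / 2, -pi / 2)[seq_along(kids)]
    } else if (n_heavy <= 3) {
      # 120-degree geometry: zigzag continuation
      switch(length(kids),
             incoming + zig * pi / 3,
             incoming + c(zig * pi / 3, -zig * pi / 3))
    } else {
      n_short <- sum(depths == 1L)
      if (length(kids) == 3 && n_short == 2 && any(depths > 1L)) {
        # 120 between the two longest branches (the parent branch and the
        # deepest child), 90 between short and long, 60 between the shorts
        incoming + pi - zig * c(2 * pi / 3, 2 * pi / 3 + pi / 2,
                                2 * pi / 3 + pi / 2 + pi / 3)
      } else {
        # four neighbours: default 90-degree geometry, deepest child
        # straight on (opposite the parent branch)
        incoming + c(0, pi / 2, -pi / 2)[seq_along(kids)]
      }
    }
    for (i in seq_along(kids)) {
      assign_child(v, kids[[i]], c(cos(angles[[i]]), sin(angles[[i]])), zig)
    }
    # stereo-restricted double bonds: force declared cis/trans by
    # mirroring the freshly assigned child directions when needed
    if (!is.null(parent)) {
      b <- bond_between(ks, parent, v)
      if (!is.null(b) && b$type == "double" && !is.null(b$stereo)) {
        enforce_stereo(b, parent, v, kids)
      }
    }
    for (w in kids) descend(w, v, -zig)
  }

  assign_child <- function(v, w, dir, zig) {
    if (!is.null(system_of_atom[[ak(w)]]) &&
        !placed_sys[[system_of_atom[[ak(w)]]]]) {
      place_system(system_of_atom[[ak(w)]], w,
                   coords[[ak(v)]] + dir, dir)
    } else {
      place_atom(w, coords[[ak(v)]] + dir)
    }
  }

  enforce_stereo <- function(b, a_atom, b_atom, b_kids) {
    st <- b$stereo
    ref_a <- if (b$a == a_atom) st$ref_a else st$ref_b
    ref_b <- if (b$a == a_atom) st$ref_b else st$ref_a
    pa <- coords[[ak(a_atom)]]; pb <- coords[[ak(b_atom)]]
    if (is.null(coords[[ak(ref_a)]]) || is.null(coords[[ak(ref_b)]])) {
      return(invisible())
    }
    axis <- pb - pa
    sa <- .cross_sign(axis, coords[[ak(ref_a)]] - pa)
    sb <- .cross_sign(axis, coords[[ak(ref_b)]] - pb)
    want <- if (st$config == "cis") sa else -sa
    if (sb != want) {
      for (w in b_kids) {
        coords[[ak(w)]] <<- .reflect(coords[[ak(w)]], pb, axis)
      }
    }
  }

  # one component at a time, offset along x
  offset_x <- 0
  comps <- graph_components(ks)
  for (comp in comps) {
    comp_heavy <- intersect(comp, heavy)
    if (length(comp_heavy) == 0) {
      # hydrogen-only component
      for (a in comp) coords[[ak(a)]] <- c(offset_x, 0)
      offset_x <- offset_x + 2
      next
    }
    # start in a ring when there is one, prioritising bridged systems
    comp_sys <- unique(unlist(lapply(comp_heavy, function(a)
      system_of_atom[[ak(a)]])))
    comp_sys <- comp_sys[!vapply(comp_sys, is.null, logical(1))]
    start <- if (length(comp_sys)) {
      csys <- unlist(comp_sys)
      pick <- csys[order(!vapply(csys, function(si)
        ring_systems[[si]]$bridged, logical(1)))][[1]]
      ring_systems[[pick]]$atoms[[1]]
    } else {
      min(comp_heavy)
    }
    if (!is.null(system_of_atom[[ak(start)]])) {
      place_system(system_of_atom[[ak(start)]], NULL, NULL, NULL)
    } else {
      place_atom(start, c(0, 0))
    }
    descend(start, NULL, 1)
    # visit ring atoms' substituents too (descend only walks unplaced
    # children; ring systems place many atoms at once, so sweep again)
    repeat {
      grown <- FALSE
      for (a in comp_heavy) {
        if (is.null(coords[[ak(a)]])) next
        un <- Filter(function(w) is.null(coords[[ak(w)]]),
                     neighbours(ks, a, heavy_only = TRUE))
        if (length(un)) {
          descend(a, NULL, 1)
          grown <- TRUE
        }
      }
      if (!grown) break
    }
    # translate component into place
    xs <- vapply(comp_heavy, function(a) coords[[ak(a)]][1], numeric(1))
    shift <- offset_x - min(xs)
    for (a in comp_heavy) {
      coords[[ak(a)]][1] <- coords[[ak(a)]][1] + shift
    }
    offset_x <- max(xs) + shift + 2
  }

  # hydrogens (drawn only on demand): place on a free direction
  for (k in names(ks$atoms)) {
    a <- ks$atoms[[k]]
    if (a$element != "H" || !is.null(coords[[k]])) next
    nb <- neighbours(ks, a$index)[[1]]
    if (is.null(coords[[ak(nb)]])) { coords[[k]] <- c(0, 0); next }
    placed_nb <- Filter(function(w) !is.null(coords[[ak(w)]]),
                        neighbours(ks, nb, heavy_only = TRUE))
    d <- if (length(placed_nb)) {
      -.unit(Reduce(`+`, lapply(placed_nb, function(w)
        .unit(coords[[ak(w)]] - coords[[ak(nb)]]))))
    } else {
      c(1, 0)
    }
    coords[[k]] <- coords[[ak(nb)]] + d * 0.8
  }

  mat <- do.call(rbind, coords)
  rownames(mat) <- names(coords)
  d <- structure(list(
    structure = ks, coords = mat, options = options,
    ring_atoms = unlist(lapply(ring_systems, function(x) x$atoms)),
    bond_style = list(), atom_colour = list(), bond_colour = list()
  ), class = "chemkit_drawing")
  d <- .fix_ring_stereo(d)
  if (isTRUE(options$finetune)) d <- finetune(d)
  d <- assign_wedges(d)
  d
}

#' @rdname layout_molecule
#' @export
layout <- function(structure, options = draw_options()) {
  layout_molecule(structure, options)
}

# mirror wrongly depicted ring stereobonds: the neighbour with the
# smallest protruding side chain is reflected across the bond axis;
# consecutive stereobonds are adjusted in order, never moving the same
# bond's neighbour twice
.fix_ring_stereo <- function(d) {
  ks <- d$structure
  moved <- character()
  for (bk in names(ks$bonds)) {
    b <- ks$bonds[[bk]]
    if (b$type != "double" || is.null(b$stereo)) next
    pa <- d$coords[ak(b$a), ]; pb <- d$coords[ak(b$b), ]
    ra <- d$coords[ak(b$stereo$ref_a), ]; rb <- d$coords[ak(b$stereo$ref_b), ]
    axis <- pb - pa
    sa <- .cross_sign(axis, ra - pa)
    sb <- .cross_sign(axis, rb - pb)
    ok <- if (b$stereo$config == "cis") sa == sb else sa != sb
    if (ok) next
    # candidates: the two reference substituents; mirror the one with the
    # smaller protruding subtree that has not been moved yet
    cand <- list(list(ref = b$stereo$ref_a, end = b$a),
                 list(ref = b$stereo$ref_b, end = b$b))
    sizes <- vapply(cand, function(cn) {
      length(.subtree_atoms(ks, cn$end, cn$ref))
    }, integer(1))
    fixed <- FALSE
    for (ci in order(sizes)) {
      cn <- cand[[ci]]
      key <- paste(cn$end, cn$ref)
      if (key %in% moved) next
      sub <- .subtree_atoms(ks, cn$end, cn$ref)
      sub <- sub[vapply(sub, function(w) ak(w) %in% rownames(d$coords),
                        logical(1))]
      for (w in sub) {
        d$coords[ak(w), ] <- .reflect(d$coords[ak(w), ],
                                      d$coords[ak(cn$end), ], axis)
      }
      moved <- c(moved, key)
      fixed <- TRUE
      break
    }
    if (!fixed) {
      chirality_error(paste0("cannot depict the declared cis/trans ",
                             "configuration of bond ", b$index))
    }
  }
  d
}

.drawn_atoms <- function(d) {
  ks <- d$structure
  keys <- rownames(d$coords)
  if (isTRUE(d$options$show_hydrogens)) return(keys)
  keys[vapply(keys, function(k) ks$atoms[[k]]$element != "H", logical(1))]
}

.mean_bond_length <- function(d) {
  ks <- d$structure
  keys <- .drawn_atoms(d)
  lens <- numeric()
  for (bk in names(ks$bonds)) {
    b <- ks$bonds[[bk]]
    if (ak(b$a) %in% keys && ak(b$b) %in% keys) {
      lens <- c(lens, sqrt(sum((d$coords[ak(b$a), ] -
                                  d$coords[ak(b$b), ])^2)))
    }
  }
  if (length(lens) == 0) 1 else mean(lens)
}

#' Detect steric clashes in a drawing
#'
#' A clash is a pair of non-neighbouring (not directly bonded) drawn atoms
#' whose Euclidean distance is strictly less than `clash_threshold` (0.5
#' by default) times the mean bond length.
#'
#' @param d a Drawing from [layout_molecule()].
#' @return a data.frame with columns `a`, `b` (atom indices, `a < b`,
#'   sorted) and `distance`.
#' @export
detect_clashes <- function(d) {
  keys <- .drawn_atoms(d)
  thr <- d$options$clash_threshold * .mean_bond_length(d)
  ks <- d$structure
  out <- list()
  n <- length(keys)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- as.integer(keys[[i]]); b <- as.integer(keys[[j]])
        if (!is.null(bond_between(ks, a, b))) next
        dist <- sqrt(sum((d$coords[keys[[i]], ] - d$coords[keys[[j]], ])^2))
        if (dist < thr) {
          out[[length(out) + 1L]] <- data.frame(
            a = min(a, b), b = max(a, b), distance = dist)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a = integer(), b = integer(), distance = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$a, res$b), , drop = FALSE]
}

# rotatable = not a stereo-restricted double bond, not adjacent to one,
# not in a cycle
.rotatable_bonds <- function(ks) {
  ring_bonds <- unique(unlist(lapply(ks$rings$sssr, function(cyc)
    .cycle_bond_set(ks, cyc))))
  is_chiral_bond <- function(b) b$type == "double" && !is.null(b$stereo)
  out <- integer()
  for (bk in names(ks$bonds)) {
    b <- ks$bonds[[bk]]
    if (ks$atoms[[ak(b$a)]]$element == "H" ||
        ks$atoms[[ak(b$b)]]$element == "H") next
    if (b$index %in% ring_bonds) next
    if (is_chiral_bond(b)) next
    adj_chiral <- FALSE
    for (end in c(b$a, b$b)) {
      for (bi in ks$adj[[ak(end)]]) {
        if (bi != b$index && is_chiral_bond(ks$bonds[[ak(bi)]])) {
          adj_chiral <- TRUE
        }
      }
    }
    if (!adj_chiral) out <- c(out, b$index)
  }
  out
}

# rotate the subtree on the far side of bond (pivot_end -> far_end) by
# theta around the far end's position
.rotate_subtree <- function(d, pivot_end, far_end, theta) {
  ks <- d$structure
  sub <- setdiff(.subtree_atoms(ks, pivot_end, far_end), far_end)
  centre <- d$coords[ak(far_end), ]
  for (w in sub) {
    k <- ak(w)
    if (k %in% rownames(d$coords)) {
      d$coords[k, ] <- centre + .rot(d$coords[k, ] - centre, theta)
    }
  }
  d
}

#' Resolve clashes by rotating acyclic bonds
#'
#' For every clashing atom pair, the shortest path between the two atoms
#' is computed and the rotatable bond closest to the path centre selected
#' (bonds are unrotatable when they are a stereo-restricted double bond,
#' adjacent to one, or in a cycle). Each selected bond is evaluated at
#' every multiple of `rotation_step` degrees (12 positions at the default
#' 30 degrees) and the angle minimising the total clash count is kept;
#' ties break toward the smallest rotation magnitude, so the clash count
#' never increases.
#'
#' @param d a Drawing.
#' @return the adjusted Drawing.
#' @export
finetune <- function(d) {
  ks <- d$structure
  clashes <- detect_clashes(d)
  if (nrow(clashes) == 0) return(d)
  rotatable <- .rotatable_bonds(ks)
  if (length(rotatable) == 0) return(d)

  chosen <- integer()
  for (ci in seq_len(nrow(clashes))) {
    path <- shortest_path_atoms(ks, clashes$a[ci], clashes$b[ci],
                                heavy_only = TRUE)
    if (length(path) < 2) next
    path_bonds <- vapply(seq_len(length(path) - 1), function(i) {
      bond_between(ks, path[[i]], path[[i + 1]])$index
    }, integer(1))
    cand <- intersect(path_bonds, rotatable)
    if (length(cand) == 0) next
    centre_pos <- (length(path_bonds) + 1) / 2
    dist_to_centre <- abs(match(cand, path_bonds) - centre_pos)
    chosen <- c(chosen, cand[order(dist_to_centre)][[1]])
  }
  chosen <- unique(chosen)

  step <- d$options$rotation_step * pi / 180
  n_steps <- as.integer(round(2 * pi / step))
  angles <- (seq_len(n_steps) - 1L) * step
  angles <- angles[order(pmin(angles, 2 * pi - angles))]  # smallest first

  for (bi in chosen) {
    b <- ks$bonds[[ak(bi)]]
    # rotate the smaller side
    side_a <- .subtree_atoms(ks, b$b, b$a)
    side_b <- .subtree_atoms(ks, b$a, b$b)
    if (length(side_a) < length(side_b)) {
      pivot <- b$b; far <- b$a
    } else {
      pivot <- b$a; far <- b$b
    }
    best <- d
    best_n <- nrow(detect_clashes(d))
    for (theta in angles[-1]) {
      trial <- .rotate_subtree(d, pivot, far, theta)
      n <- nrow(detect_clashes(trial))
      if (n < best_n) {
        best <- trial
        best_n <- n
      }
    }
    d <- best
    if (best_n == 0) break
  }
  d
}

#' Assign stereo wedges at tetrahedral centres
#'
#' Every chiral atom receives at least one wedge bond, chosen by priority:
#' prefer bonds whose far atom neighbours at most one chiral centre, then
#' bonds not in a ring, then the bond toward the shortest branch. The
#' wedge direction (up = toward the viewer, down = away) is derived from
#' the stored @/@@ parity and the 2D arrangement of the remaining
#' neighbours.
#'
#' @param d a Drawing.
#' @return the Drawing with `bond_style` entries `"wedge_up"` /
#'   `"wedge_down"` (plus `wedge_from`, the narrow-end atom).
#' @export
assign_wedges <- function(d) {
  ks <- d$structure
  ring_bonds <- unique(unlist(lapply(ks$rings$sssr, function(cyc)
    .cycle_bond_set(ks, cyc))))
  chiral_atoms <- Filter(function(k) ks$atoms[[k]]$chiral != "none",
                         names(ks$atoms))
  for (k in chiral_atoms) {
    v <- ks$atoms[[k]]$index
    nb <- neighbours(ks, v, heavy_only = !isTRUE(d$options$show_hydrogens))
    if (length(nb) == 0) next
    n_chiral_near <- vapply(nb, function(w) {
      sum(vapply(neighbours(ks, w), function(u)
        ks$atoms[[ak(u)]]$chiral != "none", logical(1)))
    }, integer(1))
    in_ring <- vapply(nb, function(w)
      bond_between(ks, v, w)$index %in% ring_bonds, logical(1))
    branch <- vapply(nb, function(w) length(.subtree_atoms(ks, v, w)),
                     integer(1))
    pick <- nb[order(n_chiral_near > 1, in_ring, branch, nb)][[1]]
    bond <- bond_between(ks, v, pick)

    # parity via signed volume: in-plane neighbours at z = 0, the wedge
    # neighbour at z = +1 (up); an undrawn (implicit) hydrogen sits
    # opposite the wedge, which is also how a MOL reader reconstructs it.
    # Calibration: det[n2-n1, n3-n1, n4-n1] < 0 for an @ centre.
    p_v <- d$coords[k, ]
    pos3 <- function(w, wedge_z) {
      kk <- ak(w)
      if (w == pick) return(c(d$coords[kk, ] - p_v, wedge_z))
      if (ks$atoms[[kk]]$element == "H" && !isTRUE(d$options$show_hydrogens)) {
        return(c(0, 0, -wedge_z))
      }
      c(d$coords[kk, ] - p_v, 0)
    }
    det_for <- function(wedge_z) {
      ps <- lapply(ks$atoms[[k]]$chiral_order, pos3, wedge_z = wedge_z)
      m <- cbind(ps[[2]] - ps[[1]], ps[[3]] - ps[[1]], ps[[4]] - ps[[1]])
      det(m)
    }
    flag_up <- if (det_for(1) < 0) "counterclockwise" else "clockwise"
    up <- identical(flag_up, ks$atoms[[k]]$chiral)
    d$bond_style[[ak(bond$index)]] <- if (up) "wedge_up" else "wedge_down"
    d$wedge_from[[ak(bond$index)]] <- v
  }
  d
}
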