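# SMILES reader.
#
# Grammar supported: organic subset B C N O P S F Cl Br I (+ aromatic
# b c n o p s), bracket atoms for any element with isotope (accepted,
# ignored), chirality @/@@, explicit H count, charge (+, -, ++, +2, ...)
# and atom class (ignored); bond symbols - = # $ : / \ ; ring closures
# 0-9 and %nn; branches; '.' for disconnected components.

.token_scan <- function(smiles) {
  n <- nchar(smiles)
  pos <- 1L
  tokens <- list()
  push <- function(kind, ...) {
    tokens[[length(tokens) + 1L]] <<- list(kind = kind, ...)
  }
  while (pos <= n) {
    ch <- substr(smiles, pos, pos)
    two <- substr(smiles, pos, pos + 1L)
    if (ch == "[") {
      close <- regexpr("]", substr(smiles, pos, n), fixed = TRUE)
      if (close < 0) {
        structure_error("syntax error", "unclosed bracket atom")
      }
      body <- substr(smiles, pos + 1L, pos + close - 2L)
      push("bracket", body = body)
      pos <- pos + close
    } else if (two %in% c("Cl", "Br")) {
      push("atom", element = two, aromatic = FALSE)
      pos <- pos + 2L
    } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      push("atom", element = ch, aromatic = FALSE)
      pos <- pos + 1L
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      push("atom", element = toupper(ch), aromatic = TRUE)
      pos <- pos + 1L
    } else if (ch %in% c("-", "=", "#", "$", ":", "/", "\\")) {
      push("bond", symbol = ch)
      pos <- pos + 1L
    } else if (ch == "%") {
      lab <- substr(smiles, pos + 1L, pos + 2L)
      if (!grepl("^[0-9]{2}$", lab)) {
        structure_error("syntax error", "malformed %nn ring closure")
      }
      push("ring", label = as.integer(lab))
      pos <- pos + 3L
    } else if (grepl("^[0-9]$", ch)) {
      push("ring", label = as.integer(ch))
      pos <- pos + 1L
    } else if (ch == "(") {
      push("open"); pos <- pos + 1L
    } else if (ch == ")") {
      push("close"); pos <- pos + 1L
    } else if (ch == ".") {
      push("dot"); pos <- pos + 1L
    } else {
      structure_error("syntax error", paste0("unexpected character '", ch, "'"))
    }
  }
  tokens
}

.parse_bracket_body <- function(body) {
  m <- regmatches(body, regexec(
    "^([0-9]+)?([A-Z][a-z]?|as|se|b|c|n|o|p|s|\\*)(@@|@)?(H[0-9]*)?(\\+[0-9]+|-[0-9]+|\\++|-+)?(:[0-9]+)?$",
    body))[[1]]
  if (length(m) == 0) {
    structure_error("syntax error", paste0("malformed bracket atom [", body, "]"))
  }
  sym <- m[3]
  aromatic <- FALSE
  if (sym %in% names(.aromatic_symbols)) {
    aromatic <- TRUE
    sym <- .aromatic_symbols[[sym]]
  }
  hc <- 0L
  if (nzchar(m[5])) {
    hc <- if (m[5] == "H") 1L else as.integer(substr(m[5], 2L, nchar(m[5])))
  }
  charge <- 0L
  if (nzchar(m[6])) {
    cs <- m[6]
    charge <- if (grepl("^[+-][0-9]+$", cs)) {
      as.integer(cs)
    } else {
      nchar(cs) * (if (substr(cs, 1L, 1L) == "+") 1L else -1L)
    }
  }
  chiral <- if (!nzchar(m[4])) "none" else if (m[4] == "@") {
    "counterclockwise"
  } else {
    "clockwise"
  }
  # isotope digits (m[2]) are accepted and ignored: the kit does not
  # distinguish isotopes.
  list(element = sym, aromatic = aromatic, explicit_h = hc,
       charge = charge, chiral = chiral)
}

# Build the raw molecular graph (atoms, bonds, directional marks) from
# tokens. Returns list(structure, directions) where directions is a list of
# (bond_index, from, to, symbol).
.graph_from_tokens <- function(tokens) {
  atoms <- list()
  bonds <- list()
  directions <- list()
  ring_open <- list()
  stack <- integer()
  prev <- NA_integer_
  pending <- NULL   # list(symbol)
  next_atom <- 0L
  next_bond <- 0L
  fresh_component <- TRUE

  default_bond <- function(a_idx, b_idx) {
    if (atoms[[ak(a_idx)]]$aromatic && atoms[[ak(b_idx)]]$aromatic) {
      "aromatic"
    } else {
      "single"
    }
  }
  bond_type_of <- function(symbol, a_idx, b_idx) {
    switch(symbol,
           "-" = "single", "=" = "double", "#" = "triple", "$" = "quadruple",
           ":" = "aromatic", "/" = "single", "\\" = "single",
           default_bond(a_idx, b_idx))
  }

  add_bond_local <- function(a_idx, b_idx, symbol) {
    type <- bond_type_of(symbol, a_idx, b_idx)
    b <- new_bond(next_bond, a_idx, b_idx, type)
    bonds[[length(bonds) + 1L]] <<- b
    if (symbol %in% c("/", "\\")) {
      directions[[length(directions) + 1L]] <<-
        list(bond = next_bond, from = a_idx, to = b_idx, symbol = symbol)
    }
    next_bond <<- next_bond + 1L
  }

  for (tk in tokens) {
    kind <- tk$kind
    if (kind %in% c("atom", "bracket")) {
      info <- if (kind == "atom") {
        list(element = tk$element, aromatic = tk$aromatic,
             explicit_h = NA_integer_, charge = 0L, chiral = "none")
      } else {
        .parse_bracket_body(tk$body)
      }
      a <- new_atom(next_atom, info$element, charge = info$charge,
                    chiral = info$chiral, aromatic = info$aromatic,
                    explicit_h = info$explicit_h)
      # SMILES neighbour order: preceding atom, then bracket hydrogen
      # (NA placeholder), then following neighbours in written order.
      if (!fresh_component && !is.na(prev)) {
        a$chiral_order <- prev
      }
      if (kind == "bracket" && info$explicit_h > 0L) {
        a$chiral_order <- c(a$chiral_order, NA_integer_)
      }
      atoms[[ak(next_atom)]] <- a
      if (!fresh_component && !is.na(prev)) {
        atoms[[ak(prev)]]$chiral_order <-
          c(atoms[[ak(prev)]]$chiral_order, next_atom)
        add_bond_local(prev, next_atom,
                       if (is.null(pending)) "" else pending$symbol)
      }
      prev <- next_atom
      next_atom <- next_atom + 1L
      pending <- NULL
      fresh_component <- FALSE
    } else if (kind == "bond") {
      if (is.na(prev)) structure_error("syntax error", "bond symbol without preceding atom")
      pending <- list(symbol = tk$symbol)
    } else if (kind == "ring") {
      if (is.na(prev)) structure_error("syntax error", "ring closure without preceding atom")
      lab <- ak(tk$label)
      sym <- if (is.null(pending)) "" else pending$symbol
      pending <- NULL
      if (is.null(ring_open[[lab]])) {
        ring_open[[lab]] <- list(atom = prev, symbol = sym)
        # placeholder in neighbour order, patched at closure
        atoms[[ak(prev)]]$chiral_order <-
          c(atoms[[ak(prev)]]$chiral_order, -(tk$label + 1L))
      } else {
        op <- ring_open[[lab]]
        ring_open[[lab]] <- NULL
        if (op$atom == prev) {
          structure_error("syntax error", "ring closure bonds an atom to itself")
        }
        sym1 <- op$symbol; sym2 <- sym
        if (nzchar(sym1) && nzchar(sym2) &&
            !(sym1 == sym2 ||
              (sym1 %in% c("/", "\\") && sym2 %in% c("/", "\\")))) {
          structure_error("syntax error", "conflicting ring closure bond symbols")
        }
        use_sym <- if (nzchar(sym1)) sym1 else sym2
        add_bond_local(op$atom, prev, use_sym)
        if (sym2 %in% c("/", "\\") && !(sym1 %in% c("/", "\\"))) {
          # direction written at the closing end: orientation is from the
          # closing atom towards the opening atom
          directions[[length(directions)]] <-
            list(bond = next_bond - 1L, from = prev, to = op$atom, symbol = sym2)
        }
        co <- atoms[[ak(op$atom)]]$chiral_order
        co[match(-(tk$label + 1L), co)] <- prev
        atoms[[ak(op$atom)]]$chiral_order <- co
        atoms[[ak(prev)]]$chiral_order <-
          c(atoms[[ak(prev)]]$chiral_order, op$atom)
      }
    } else if (kind == "open") {
      if (is.na(prev)) structure_error("syntax error", "branch before any atom")
      stack <- c(stack, prev)
    } else if (kind == "close") {
      if (length(stack) == 0) structure_error("syntax error", "unbalanced parentheses")
      prev <- stack[[length(stack)]]
      stack <- stack[-length(stack)]
    } else if (kind == "dot") {
      prev <- NA_integer_
      pending <- NULL
      fresh_component <- TRUE
    }
  }
  if (length(stack)) structure_error("syntax error", "unbalanced parentheses")
  if (length(ring_open)) structure_error("syntax error", "unmatched ring closure")
  if (!is.null(pending)) structure_error("syntax error", "dangling bond symbol")
  if (length(atoms) == 0) structure_error("syntax error", "no atoms in SMILES")

  s <- build_structure(atoms, bonds)
  list(structure = s, directions = directions)
}

#' Smallest achievable valency for an atom
#'
#' Given the bond-order sum of an atom's non-hydrogen bonds plus its
#' explicit hydrogens, selects the smallest tabulated valency that is equal
#' to or higher than the sum ([allowed_valences()]); elements without a
#' valence table are assigned the sum itself.
#'
#' @param atom an atom record.
#' @param bond_sum numeric bond-order sum (aromatic bonds already resolved).
#' @param explicit_h explicit hydrogen count to include.
#' @return integer valency.
#' @export
assign_valency <- function(atom, bond_sum, explicit_h = 0L) {
  total <- ceiling(bond_sum + explicit_h)
  av <- allowed_valences(atom$element, atom$charge)
  if (is.null(av)) return(as.integer(total))
  fit <- av[av >= total]
  if (length(fit) == 0) {
    structure_error("bonding-law violation",
                    "Basic bonding laws have been violated")
  }
  as.integer(fit[[1]])
}

.assign_all_valencies <- function(s) {
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    if (a$element == "H") { s$atoms[[k]]$valency <- 1L; next }
    eh <- if (is.na(a$explicit_h)) 0L else a$explicit_h
    s$atoms[[k]]$valency <- assign_valency(a, bond_order_sum(s, a$index), eh)
  }
  s
}

#' Nitro-group tolerance for pentavalent nitrogen
#'
#' Neutral nitrogen written with valency 5 is not chemically possible
#' (nitrogen has only four bonding orbitals), but occurs in SMILES of nitro
#' groups such as `CN(=O)=O`. When such a nitrogen carries at least one
#' doubly bonded oxygen, that double bond is reinterpreted as single, the
#' oxygen's charge set to -1 and the nitrogen's to +1, so the nitrogen's
#' valency becomes 4. Without a doubly bonded oxygen a bonding-law
#' StructureError is raised.
#'
#' @param s a Structure with valencies assigned.
#' @return the corrected Structure.
#' @export
correct_pentavalent_nitrogen <- function(s) {
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    if (a$element != "N" || a$charge != 0L || is.na(a$valency) ||
        a$valency != 5L) {
      next
    }
    o_bond <- NULL
    for (bi in s$adj[[k]]) {
      b <- s$bonds[[ak(bi)]]
      other <- if (b$a == a$index) b$b else b$a
      if (b$type == "double" && s$atoms[[ak(other)]]$element == "O") {
        if (is.null(o_bond) || other < (if (o_bond$a == a$index) o_bond$b else o_bond$a)) {
          o_bond <- b
        }
      }
    }
    if (is.null(o_bond)) {
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
    o_idx <- if (o_bond$a == a$index) o_bond$b else o_bond$a
    s$bonds[[ak(o_bond$index)]]$type <- "single"
    s$atoms[[ak(o_idx)]]$charge <- -1L
    s$atoms[[ak(o_idx)]]$valency <- 1L
    s$atoms[[k]]$charge <- 1L
    s$atoms[[k]]$valency <- 4L
  }
  s
}

#' Materialise implicit hydrogens as graph atoms
#'
#' Adds hydrogen nodes so that each atom's bonds reach its assigned
#' valency. Organic-subset atoms receive `valency - bond-order sum`
#' hydrogens; bracket atoms receive exactly their declared hydrogen count.
#'
#' @param s a Structure with valencies assigned.
#' @return the Structure with hydrogens added.
#' @export
add_implicit_hydrogens <- function(s) {
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    if (a$element == "H") next
    n_h <- if (!is.na(a$explicit_h)) {
      a$explicit_h
    } else if (is.null(allowed_valences(a$element, a$charge))) {
      0L
    } else {
      as.integer(a$valency - ceiling(bond_order_sum(s, a$index)))
    }
    if (n_h < 0) {
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
    if (n_h > 0) {
      for (j in seq_len(n_h)) {
        h <- new_atom(s$next_atom_index, "H")
        h$valency <- 1L
        h$chiral_order <- a$index
        s$atoms[[ak(h$index)]] <- h
        s$adj[[ak(h$index)]] <- integer()
        s$next_atom_index <- s$next_atom_index + 1L
        s <- add_bond_edge(s, new_bond(s$next_bond_index, a$index, h$index))
        co <- s$atoms[[k]]$chiral_order
        slot <- which(is.na(co))
        if (length(slot)) {
          co[slot[[1]]] <- h$index
        } else {
          co <- c(co, h$index)
        }
        s$atoms[[k]]$chiral_order <- co
      }
    }
    s$atoms[[k]]$explicit_h <- NA_integer_
  }
  # any unfilled bracket-H placeholders (bracket said H but count was 0)
  for (k in names(s$atoms)) {
    co <- s$atoms[[k]]$chiral_order
    s$atoms[[k]]$chiral_order <- co[!is.na(co)]
  }
  s
}

#' Hybridisation label from steric number
#'
#' Steric number = sigma-bonded neighbours + lone pairs, mapped
#' 1 -> s, 2 -> sp, 3 -> sp2, 4 -> sp3, 5 -> sp3d, 6 -> sp3d2.
#'
#' @param atom an atom record with `lone_pairs` filled in.
#' @param sigma number of sigma-bonded neighbours.
#' @return hybridisation label.
#' @export
determine_hybridisation <- function(atom, sigma) {
  lp <- atom$lone_pairs
  if (is.na(lp)) return(NA_character_)
  steric <- sigma + lp
  if (steric < 1 || steric > 6) {
    structure_error("bonding-law violation",
                    paste0("steric number ", steric, " outside 1-6"))
  }
  c("s", "sp", "sp2", "sp3", "sp3d", "sp3d2")[[steric]]
}

# Electron bookkeeping: lone pairs, hybridisation and shell construction for
# every atom of a structure whose valencies are final.
.allocate_electrons <- function(s) {
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    ve <- valence_electron_count(a$element)
    if (is.na(ve)) {  # untabulated element: no electron model
      s$atoms[[k]]$lone_pairs <- 0L
      s$atoms[[k]]$hybridisation <- NA_character_
      next
    }
    ve_eff <- ve - a$charge
    rest <- ve_eff - a$valency
    if (rest < 0 || rest %% 2 != 0) {
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
    lp <- rest %/% 2
    if (a$valency + lp > bonding_orbital_count(a$element)) {
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
    s$atoms[[k]]$lone_pairs <- as.integer(lp)
    sigma <- atom_degree(s, a$index)
    pi_e <- 0
    for (bi in s$adj[[k]]) {
      t <- s$bonds[[ak(bi)]]$type
      if (t %in% c("double", "triple", "quadruple")) {
        pi_e <- pi_e + (bond_order(t) - 1)
      }
    }
    s$atoms[[k]]$pi_electrons <- as.integer(pi_e)
    if (a$element == "H") {
      s$atoms[[k]]$hybridisation <- "s"
    } else {
      s$atoms[[k]]$hybridisation <-
        determine_hybridisation(s$atoms[[k]], sigma)
    }
    s$atoms[[k]]$shells <- build_shells(a$element, ve_eff, a$valency, lp,
                                        sigma, as.integer(pi_e))
  }
  s
}

#' Electron shell construction
#'
#' Builds a per-atom orbital table for the valence shell: lone pairs occupy
#' the lowest-energy orbitals pairwise, then one electron per bond is
#' promoted ("excited") into singly occupied orbitals, expanding into d
#' orbitals for third-period elements when required. Any electron that
#' would remain unpaired in a higher orbital while a lower orbital has a
#' vacancy is dropped back, so the returned configuration is relaxed.
#'
#' @param element chemical symbol.
#' @param ve_eff valence electrons adjusted for formal charge.
#' @param valency assigned valency (number of bonding electrons).
#' @param lone_pairs lone pair count.
#' @param sigma sigma bond count; `pi` pi electron count.
#' @param pi pi electron count.
#' @return data.frame of orbitals with columns `subshell`, `electrons`,
#'   `role` (`"lone pair"`, `"sigma"`, `"pi"`, `"empty"`).
#' @export
build_shells <- function(element, ve_eff, valency, lone_pairs, sigma, pi) {
  n_orb <- bonding_orbital_count(element)
  subshell <- c("s", "p", "p", "p", "d", "d", "d", "d", "d")[seq_len(n_orb)]
  electrons <- integer(n_orb)
  role <- rep("empty", n_orb)
  o <- 1L
  for (i in seq_len(lone_pairs)) {
    electrons[o] <- 2L; role[o] <- "lone pair"; o <- o + 1L
  }
  n_sigma <- min(sigma, valency)
  n_pi <- valency - n_sigma
  for (i in seq_len(n_sigma)) {
    electrons[o] <- 1L; role[o] <- "sigma"; o <- o + 1L
  }
  for (i in seq_len(n_pi)) {
    electrons[o] <- 1L; role[o] <- "pi"; o <- o + 1L
  }
  data.frame(subshell = subshell, electrons = electrons, role = role,
             stringsAsFactors = FALSE)
}

# cis/trans perception from directional single-bond marks.
# side convention: orientation from -> to with '/' places `to` up; the
# substituent's side relative to its double-bond atom is +1 (up) or -1.
.perceive_cis_trans <- function(s, directions) {
  if (length(directions) == 0) return(s)
  # side of the *substituent* end of each directional bond, relative to the
  # double-bond atom it attaches to
  side_of <- function(d, db_atom) {
    sub <- if (d$from == db_atom) d$to else d$from
    up <- (d$symbol == "/")
    if (d$to == sub) {
      if (up) 1L else -1L
    } else {
      if (up) -1L else 1L
    }
  }
  for (bk in names(s$bonds)) {
    b <- s$bonds[[bk]]
    if (b$type != "double") next
    ends <- c(b$a, b$b)
    refs <- vector("list", 2)
    for (ei in 1:2) {
      at <- ends[[ei]]
      marked <- list()
      for (d in directions) {
        d_other <- setdiff(c(d$from, d$to), at)
        if (at %in% c(d$from, d$to) &&
            length(d_other) == 1 && !(d_other %in% ends)) {
          marked[[length(marked) + 1L]] <-
            list(sub = d_other, side = side_of(d, at))
        }
      }
      if (length(marked) == 2) {
        if (marked[[1]]$side == marked[[2]]$side) {
          structure_error("conflicting double-bond stereochemistry",
                          "Conflicting double bond stereochemistry")
        }
      }
      if (length(marked) >= 1) {
        ord <- order(vapply(marked, function(m) m$sub, integer(1)))
        refs[[ei]] <- marked[[ord[[1]]]]
      }
    }
    if (!is.null(refs[[1]]) && !is.null(refs[[2]])) {
      config <- if (refs[[1]]$side == refs[[2]]$side) "cis" else "trans"
      s$bonds[[bk]]$stereo <- list(ref_a = refs[[1]]$sub,
                                   ref_b = refs[[2]]$sub,
                                   config = config)
    }
  }
  s
}

.validate_chirality <- function(s) {
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    if (a$chiral == "none") next
    nb <- neighbours(s, a$index)
    if (length(nb) != 4 || anyDuplicated(nb)) {
      # tolerated: the mark cannot be interpreted as tetrahedral, drop it
      s$atoms[[k]]$chiral <- "none"
      s$atoms[[k]]$chiral_order <- integer()
    }
  }
  s
}

#' Parse a SMILES string into a validated Structure
#'
#' Builds the molecular graph, assigns valencies (applying the nitro-group
#' tolerance for pentavalent nitrogen), materialises implicit hydrogens as
#' graph atoms, allocates electrons and hybridisation, perceives rings and
#' aromaticity, and validates stereo marks. On any chemical or syntactic
#' fault a StructureError condition is raised with message
#' `Error parsing "<smiles>": <reason>`.
#'
#' @param smiles a non-empty SMILES string.
#' @return a validated Structure.
#' @examples
#' s <- parse_smiles("CC(=O)O")   # acetic acid
#' length(s$atoms)                # 8 including hydrogens
#' @export
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1 || !nzchar(smiles)) {
    stop("smiles must be a single non-empty string")
  }
  withCallingHandlers(
    {
      g <- .graph_from_tokens(.token_scan(smiles))
      s <- g$structure
      s <- .assign_all_valencies(s)
      s <- correct_pentavalent_nitrogen(s)
      s <- add_implicit_hydrogens(s)
      s <- .allocate_electrons(s)
      s <- .perceive_cis_trans(s, g$directions)
      s <- .validate_chirality(s)
      s <- perceive_rings_and_aromaticity(s)
      s$smiles <- smiles
      s
    },
    chemkit_structure_error = function(e) {
      if (!grepl("^Error parsing", conditionMessage(e))) {
        stop(structure(
          class = class(e),
          list(message = sprintf('Error parsing "%s": %s', smiles,
                                 conditionMessage(e)),
               call = NULL, category = e$category)
        ))
      }
    }
  )
}

#' Revalidate a structure after editing
#'
#' Recomputes valencies (which must be achievable for the current bonds --
#' otherwise a bonding-law StructureError is raised), electron shells,
#' hybridisation, ring caches and aromaticity flags.
#'
#' @param s a Structure whose connectivity is final for this step.
#' @return the refreshed Structure.
#' @export
refresh_structure <- function(s) {
  for (k in names(s$atoms)) {
    a <- s$atoms[[k]]
    if (a$element == "H") {
      if (bond_order_sum(s, a$index) > 1) {
        structure_error("bonding-law violation",
                        "Basic bonding laws have been violated")
      }
      s$atoms[[k]]$valency <- 1L
      next
    }
    bs <- bond_order_sum(s, a$index)
    v <- assign_valency(a, bs, 0L)
    if (v != ceiling(bs) && !is.null(allowed_valences(a$element, a$charge))) {
      # hydrogens are explicit after parsing: bonds must meet the valency
      structure_error("bonding-law violation",
                      "Basic bonding laws have been violated")
    }
    s$atoms[[k]]$valency <- v
  }
  s <- .allocate_electrons(s)
  # aromatic flags are a perception cache: clear and re-derive (aromatic
  # bond *types* stay, and fail validation if no aromatic cycle confirms
  # them -- e.g. after an edit chemically destroyed the ring system)
  for (k in names(s$atoms)) s$atoms[[k]]$aromatic <- FALSE
  s$aromaticity_done <- FALSE
  s <- perceive_rings_and_aromaticity(s)
  s
}
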