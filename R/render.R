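# Output backends: SVG (primary, bit-stable), PNG (grDevices raster of the
# same primitives), MDL MOL V2000.

.atom_label <- function(ks, i, show_h) {
  a <- ks$atoms[[ak(i)]]
  if (a$element == "C" && a$charge == 0L) return("")
  h <- hydrogen_count(ks, i)
  lab <- a$element
  if (!show_h && h > 0) {
    lab <- paste0(lab, "H", if (h > 1) h else "")
  }
  if (a$charge != 0L) {
    lab <- paste0(lab, if (a$charge == 1L) "+" else if (a$charge == -1L) "-"
                  else sprintf("%+d", a$charge))
  }
  lab
}

# collect drawing primitives (in pixel space, y down) shared by the SVG
# and PNG backends
.render_primitives <- function(d) {
  ks <- d$structure
  opts <- d$options
  scale <- opts$scale
  keys <- .drawn_atoms(d)
  xy <- d$coords[keys, , drop = FALSE]
  pad <- 0.8
  xmin <- min(xy[, 1]) - pad; xmax <- max(xy[, 1]) + pad
  ymin <- min(xy[, 2]) - pad; ymax <- max(xy[, 2]) + pad
  W <- (xmax - xmin) * scale
  H <- (ymax - ymin) * scale
  px <- function(p) c((p[1] - xmin) * scale, (ymax - p[2]) * scale)
  font <- 0.42 * scale
  lw <- 0.06 * scale
  prims <- list()
  add <- function(...) prims[[length(prims) + 1L]] <<- list(...)

  labels <- stats::setNames(
    vapply(keys, function(k) {
      .atom_label(ks, as.integer(k), isTRUE(opts$show_hydrogens))
    }, character(1)), keys)

  bond_colour <- function(bi) d$bond_colour[[ak(bi)]] %||% "#000000"
  atom_colour <- function(k) d$atom_colour[[k]] %||% "#000000"

  # shorten bond ends at labelled atoms so lines do not strike the text
  endpoint <- function(from_k, to_k) {
    p <- px(d$coords[from_k, ]); q <- px(d$coords[to_k, ])
    if (nzchar(labels[[from_k]])) {
      p <- p + .unit(q - p) * font * 0.62
    }
    p
  }

  for (bk in names(ks$bonds)) {
    b <- ks$bonds[[bk]]
    ka <- ak(b$a); kb <- ak(b$b)
    if (!(ka %in% keys) || !(kb %in% keys)) next
    p <- endpoint(ka, kb); q <- endpoint(kb, ka)
    col <- bond_colour(b$index)
    style <- d$bond_style[[ak(b$index)]] %||% b$type
    dir <- .unit(q - p)
    nrm <- c(-dir[2], dir[1])
    if (style == "wedge_up" || style == "wedge_down") {
      narrow <- d$wedge_from[[ak(b$index)]]
      if (!is.null(narrow) && narrow == b$b) { tmp <- p; p <- q; q <- tmp }
      half <- 0.14 * scale
      if (style == "wedge_up") {
        add(kind = "polygon", pts = list(p, q + nrm * half, q - nrm * half),
            col = col)
      } else {
        n_h <- 5
        for (i in seq_len(n_h)) {
          f <- i / n_h
          m0 <- p + (q - p) * f
          add(kind = "line", p = m0 - nrm * half * f, q = m0 + nrm * half * f,
              col = col, lw = lw)
        }
      }
    } else if (style %in% c("double", "aromatic")) {
      off <- nrm * 0.07 * scale
      add(kind = "line", p = p + off, q = q + off, col = col, lw = lw)
      add(kind = "line", p = p - off, q = q - off, col = col, lw = lw)
    } else if (style == "triple") {
      off <- nrm * 0.12 * scale
      add(kind = "line", p = p, q = q, col = col, lw = lw)
      add(kind = "line", p = p + off, q = q + off, col = col, lw = lw)
      add(kind = "line", p = p - off, q = q - off, col = col, lw = lw)
    } else if (style == "quadruple") {
      for (mfac in c(-1.5, -0.5, 0.5, 1.5)) {
        off <- nrm * 0.08 * scale * mfac
        add(kind = "line", p = p + off, q = q + off, col = col, lw = lw)
      }
    } else {
      add(kind = "line", p = p, q = q, col = col, lw = lw)
    }
  }
  for (k in keys) {
    if (nzchar(labels[[k]])) {
      add(kind = "text", p = px(d$coords[k, ]), text = labels[[k]],
          col = atom_colour(k), font = font)
    }
  }
  list(prims = prims, width = ceiling(W), height = ceiling(H), font = font)
}

#' Render a drawing to SVG or PNG
#'
#' The canvas is auto-sized to the molecule's extent; font size, bond
#' length and line width keep a constant ratio across drawings. Carbon
#' atoms are drawn as unlabelled vertices; heteroatoms carry element +
#' implicit-hydrogen labels. Per-atom and per-bond colours (hex codes or
#' colour names) are honoured.
#'
#' @param d a Drawing from [layout_molecule()] or [highlight_matches()].
#' @param path output file path.
#' @param format `"svg"` (default, inferred from the path extension) or
#'   `"png"`.
#' @return `path`, invisibly.
#' @export
render <- function(d, path, format = c("auto", "svg", "png")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.png$", path, ignore.case = TRUE)) "png" else "svg"
  }
  rp <- .render_primitives(d)
  if (format == "svg") {
    out <- c(sprintf(
      paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
             'height="%d" viewBox="0 0 %d %d">'),
      rp$width, rp$height, rp$width, rp$height),
      '<rect width="100%" height="100%" fill="#ffffff"/>')
    for (pr in rp$prims) {
      out <- c(out, switch(
        pr$kind,
        line = sprintf(
          paste0('<line x1="%.2f" y1="%.2f" x2="%.2f" y2="%.2f" ',
                 'stroke="%s" stroke-width="%.2f" stroke-linecap="round"/>'),
          pr$p[1], pr$p[2], pr$q[1], pr$q[2], pr$col, pr$lw),
        polygon = sprintf(
          '<polygon points="%s" fill="%s"/>',
          paste(vapply(pr$pts, function(p) sprintf("%.2f,%.2f", p[1], p[2]),
                       character(1)), collapse = " "), pr$col),
        text = sprintf(
          paste0('<text x="%.2f" y="%.2f" fill="%s" font-size="%.2f" ',
                 'font-family="Helvetica, sans-serif" text-anchor="middle" ',
                 'dominant-baseline="central">%s</text>'),
          pr$p[1], pr$p[2], pr$col, pr$font, pr$text)))
    }
    out <- c(out, "</svg>")
    writeLines(out, path)
  } else {
    grDevices::png(path, width = max(rp$width, 2), height = max(rp$height, 2))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit({ graphics::par(op); grDevices::dev.off() })
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, rp$width), ylim = c(rp$height, 0),
                          xaxs = "i", yaxs = "i")
    graphics::rect(0, rp$height, rp$width, 0, col = "#ffffff", border = NA)
    for (pr in rp$prims) {
      if (pr$kind == "line") {
        graphics::segments(pr$p[1], pr$p[2], pr$q[1], pr$q[2], col = pr$col,
                           lwd = max(1, pr$lw / 2))
      } else if (pr$kind == "polygon") {
        graphics::polygon(vapply(pr$pts, `[`, numeric(1), 1),
                          vapply(pr$pts, `[`, numeric(1), 2),
                          col = pr$col, border = pr$col)
      } else {
        graphics::text(pr$p[1], pr$p[2], pr$text, col = pr$col,
                       cex = pr$font / 12)
      }
    }
  }
  invisible(path)
}

#' Draw a molecule in one call
#'
#' Convenience wrapper: parse (if needed), lay out, render.
#'
#' @param x a Structure or SMILES string.
#' @param path output file (`.svg` or `.png`).
#' @param options [draw_options()].
#' @return the Drawing, invisibly.
#' @export
draw_molecule <- function(x, path = NULL, options = draw_options()) {
  s <- if (is.character(x)) parse_smiles(x) else x
  d <- layout_molecule(s, options)
  if (!is.null(path)) render(d, path)
  invisible(d)
}

#' Write a drawing as an MDL MOL V2000 file
#'
#' Heavy atoms only (hydrogens are folded into the connection table's
#' implicit counts); 1-based indices, bond types 1/2/3, wedge stereo flags
#' 1 (up) and 6 (down) with the narrow end first, charges in `M  CHG`
#' lines. Structures above the V2000 limit of 999 atoms are rejected.
#'
#' @param d a Drawing.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_molfile <- function(d, path) {
  ks <- d$structure
  keys <- .drawn_atoms(d)
  if (length(keys) > 999) stop("V2000 MOL files support at most 999 atoms")
  serial <- stats::setNames(seq_along(keys), keys)
  bonds <- Filter(function(b) ak(b$a) %in% keys && ak(b$b) %in% keys,
                  ks$bonds)
  lines <- c("chemkit", "", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     length(keys), length(bonds)))
  for (k in keys) {
    p <- d$coords[k, ]
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              p[1], p[2], 0, ks$atoms[[k]]$element))
  }
  type_code <- c(single = 1L, double = 2L, triple = 3L, quadruple = 4L,
                 aromatic = 4L)
  for (b in bonds) {
    a1 <- serial[[ak(b$a)]]; a2 <- serial[[ak(b$b)]]
    stereo <- 0L
    style <- d$bond_style[[ak(b$index)]]
    if (!is.null(style) && style %in% c("wedge_up", "wedge_down")) {
      narrow <- d$wedge_from[[ak(b$index)]]
      if (!is.null(narrow) && narrow == b$b) { tmp <- a1; a1 <- a2; a2 <- tmp }
      stereo <- if (style == "wedge_up") 1L else 6L
    }
    lines <- c(lines, sprintf("%3d%3d%3d%3d  0  0  0", a1, a2,
                              type_code[[b$type]], stereo))
  }
  charged <- keys[vapply(keys, function(k) ks$atoms[[k]]$charge != 0L,
                         logical(1))]
  if (length(charged)) {
    for (grp in split(charged, ceiling(seq_along(charged) / 8))) {
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(grp)),
        paste(vapply(grp, function(k) {
          sprintf("%4d%4d", serial[[k]], ks$atoms[[k]]$charge)
        }, character(1)), collapse = "")))
    }
  }
  lines <- c(lines, "M  END")
  writeLines(lines, path)
  invisible(path)
}
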