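# Maximum matching in a general graph: Edmonds' blossom algorithm.
# Classic O(V^3) formulation with BFS augmenting paths and blossom
# contraction via base[] pointers. Used by kekulisation.

#' Maximum matching in a general graph
#'
#' @param n number of vertices (labelled 1..n).
#' @param edges list of length-2 integer vectors (1-based endpoints).
#' @return integer vector `match` of length `n`; `match[v]` is the partner
#'   of `v`, or 0 when `v` is unmatched.
#' @export
maximum_matching <- function(n, edges) {
  g <- vector("list", n)
  for (e in edges) {
    u <- e[[1]]; v <- e[[2]]
    if (u == v) next
    g[[u]] <- c(g[[u]], v)
    g[[v]] <- c(g[[v]], u)
  }
  match <- integer(n)
  p <- integer(n)
  base <- integer(n)

  lca <- function(a, b) {
    used <- logical(n)
    repeat {
      a <- base[a]
      used[a] <- TRUE
      if (match[a] == 0L) break
      a <- p[match[a]]
    }
    repeat {
      b <- base[b]
      if (used[b]) return(b)
      b <- p[match[b]]
    }
  }

  find_path <- function(root) {
    used <- logical(n)
    p[] <<- 0L
    base[] <<- seq_len(n)
    used[root] <- TRUE
    queue <- root

    mark_path <- function(v, b, child) {
      while (base[v] != b) {
        blossom[base[v]] <<- TRUE
        blossom[base[match[v]]] <<- TRUE
        p[v] <<- child
        child <- match[v]
        v <- p[match[v]]
      }
    }

    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      for (to in g[[v]]) {
        if (base[v] == base[to] || match[v] == to) next
        if (to == root || (match[to] != 0L && p[match[to]] != 0L)) {
          # blossom found: contract
          curbase <- lca(v, to)
          blossom <<- logical(n)
          mark_path(v, curbase, to)
          mark_path(to, curbase, v)
          for (i in seq_len(n)) {
            if (blossom[base[i]]) {
              base[i] <<- curbase
              if (!used[i]) {
                used[i] <- TRUE
                queue <- c(queue, i)
              }
            }
          }
        } else if (p[to] == 0L) {
          p[to] <<- v
          if (match[to] == 0L) {
            # augmenting path found: flip it
            u <- to
            while (u != 0L) {
              pv <- p[u]
              ppv <- match[pv]
              match[u] <<- pv
              match[pv] <<- u
              u <- ppv
            }
            return(TRUE)
          } else {
            used[match[to]] <- TRUE
            queue <- c(queue, match[to])
          }
        }
      }
    }
    FALSE
  }

  blossom <- logical(n)
  for (v in seq_len(n)) {
    if (match[v] == 0L) find_path(v)
  }
  match
}
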