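# Independent oracles used across the suite.

# Supercell-growth oracle for the closed-symmetry rule: lift the engaged
# subgraph onto nodes (v, offset) with offsets in {-1,0,1}^3 (no wrapping);
# the engaged set is invalid iff some lifted component anchored at offset
# (0,0,0) collects more members than its quotient component (a finite
# assembly picks up each quotient node exactly once; a fiber keeps growing
# through the supercell).
oracle_rule4_supercell <- function(g, engaged) {
  rows <- which(g$edges$type %in% engaged)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  key <- function(v, o) paste(v, o[1], o[2], o[3])
  # adjacency in the lifted block
  nodes <- character(0)
  for (v in g$nodes$id) for (i in seq_len(nrow(offs)))
    nodes <- c(nodes, key(v, offs[i, ]))
  adj <- new.env(parent = emptyenv())
  add <- function(k1, k2) {
    assign(k1, c(get0(k1, envir = adj), k2), envir = adj)
    assign(k2, c(get0(k2, envir = adj), k1), envir = adj)
  }
  for (r in rows) {
    d <- c(g$edges$hx[r], g$edges$hy[r], g$edges$hz[r])
    for (i in seq_len(nrow(offs))) {
      o1 <- as.integer(offs[i, ]); o2 <- o1 + d
      if (any(abs(o2) > 1)) next
      add(key(g$edges$src[r], o1), key(g$edges$dst[r], o2))
    }
  }
  lifted_comp_size <- function(v) {
    start <- key(v, c(0L, 0L, 0L))
    seen <- start; queue <- start
    while (length(queue) > 0) {
      x <- queue[1]; queue <- queue[-1]
      for (w in get0(x, envir = adj)) {
        if (!(w %in% seen)) { seen <- c(seen, w); queue <- c(queue, w) }
      }
    }
    length(seen)
  }
  # quotient component sizes via plain union-find
  n <- nrow(g$nodes)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pos <- function(id) match(id, g$nodes$id)
  for (r in rows) {
    a <- find(pos(g$edges$src[r])); b <- find(pos(g$edges$dst[r]))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  for (v in seq_len(n)) {
    qsize <- sum(roots == roots[v])
    if (lifted_comp_size(g$nodes$id[v]) > qsize) return(FALSE)  # invalid
  }
  TRUE
}

# igraph-based connected components of an engaged subgraph (independent of
# the package's union-find/BFS machinery)
oracle_components_igraph <- function(g, engaged) {
  rows <- which(g$edges$type %in% engaged)
  el <- cbind(match(g$edges$src[rows], g$nodes$id),
              match(g$edges$dst[rows], g$nodes$id))
  ig <- igraph::graph_from_edgelist(el, directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0, nrow(g$nodes) -
                                       igraph::vcount(ig)))
  comp <- igraph::components(ig)$membership
  match(comp, unique(comp))
}

# igraph VF2 isomorphism of two assemblies via a simple-graph encoding:
# multi-edges collapse to a single edge coloured by the sorted type
# multiset; self-loop types fold into the vertex colour
oracle_iso_igraph <- function(a1, a2) {
  encode <- function(a) {
    pos <- match(c(a$edges$src, a$edges$dst), a$members$node)
    m <- nrow(a$edges)
    pairs <- list()
    vloop <- rep("", a$size)
    if (m > 0) {
      for (i in seq_len(m)) {
        u <- pos[i]; v <- pos[m + i]
        if (u == v) {
          vloop[u] <- paste(sort(c(vloop[u], a$edges$type[i])),
                            collapse = "+")
        } else {
          k <- paste(sort(c(u, v)), collapse = "-")
          pairs[[k]] <- sort(c(pairs[[k]], a$edges$type[i]))
        }
      }
    }
    vcol_str <- paste(a$members$entity, vloop)
    el <- do.call(rbind, lapply(names(pairs), function(k)
      as.integer(strsplit(k, "-", fixed = TRUE)[[1]])))
    ecol_str <- vapply(names(pairs), function(k)
      paste(pairs[[k]], collapse = ","), character(1))
    list(el = el, vcol = vcol_str, ecol = ecol_str, n = a$size)
  }
  e1 <- encode(a1); e2 <- encode(a2)
  if (e1$n != e2$n) return(FALSE)
  if (!identical(sort(e1$vcol), sort(e2$vcol))) return(FALSE)
  if (!identical(sort(e1$ecol), sort(e2$ecol))) return(FALSE)
  lev <- unique(c(e1$vcol, e2$vcol))
  elev <- unique(c(e1$ecol, e2$ecol))
  mk <- function(e) {
    ig <- igraph::make_empty_graph(e$n, directed = FALSE)
    if (!is.null(e$el)) ig <- igraph::add_edges(ig, t(e$el))
    ig
  }
  igraph::isomorphic(
    mk(e1), mk(e2), method = "vf2",
    vertex.color1 = match(e1$vcol, lev), vertex.color2 = match(e2$vcol, lev),
    edge.color1 = match(e1$ecol, elev), edge.color2 = match(e2$ecol, elev))
}

# brute-force all-pairs contact scan over a 3x3x3 supercell: returns the
# set of contact orbits as canonical strings, independent of the package's
# anchored-scan + dedup logic
oracle_contacts_supercell <- function(s, cutoff = 5.5) {
  chains <- protein_chains(s)
  ids <- names(chains)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  placed <- list()
  for (cid in ids) for (g in seq_along(s$ops)) {
    for (i in seq_len(nrow(shifts))) {
      t <- as.integer(shifts[i, ])
      key <- paste(cid, g, paste(t, collapse = ","))
      placed[[key]] <- list(chain = cid, op = g, shift = t,
                            xyz = apply_operator(chains[[cid]], s$ops[[g]],
                                                 t, s$cell)$xyz)
    }
  }
  keys <- names(placed)
  hits <- character(0)
  # contacts of identity-placed chains against everything
  for (cid in ids) {
    k0 <- paste(cid, 1, "0,0,0")
    for (k in keys) {
      if (k == k0) next
      p <- placed[[k]]
      dd <- min(sqrt(outer(rowSums(placed[[k0]]$xyz^2),
                           rowSums(p$xyz^2), "+") -
                       2 * placed[[k0]]$xyz %*% t(p$xyz)))
      if (dd < cutoff) {
        pair <- sort(c(k0, k))
        hits <- c(hits, paste(pair, collapse = " :: "))
      }
    }
  }
  unique(hits)
}

# all valid engaged sets as a canonical sorted character vector
engaged_set_keys <- function(sets) {
  sort(vapply(sets, function(s) {
    e <- if (is.list(s) && !is.null(s$engaged)) s$engaged else s
    paste(sort(e), collapse = ",")
  }, character(1)))
}
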