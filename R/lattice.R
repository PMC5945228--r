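# The periodic lattice graph (quotient graph / crystal net).
#
# Nodes are (chain x space-group operator) pairs, one per chain copy in the
# unit cell; labelled edges carry the interface instance, its type, and an
# integer translation vector giving the Miller-index difference between the
# two participating chains. The finite multigraph represents the infinite
# crystal: edges with non-zero translations reach into neighbouring cells.

#' Construct a quotient graph
#'
#' @param nodes Data frame with columns `id`, `chain`, `op`, `entity`
#'   (and optionally `label`).
#' @param edges Data frame with columns `src`, `dst` (node ids), `iface`,
#'   `type`, `hx`, `hy`, `hz` (integer translation), `area`.
#' @param types Data frame with columns `type`, `p`, `mean_area`,
#'   `isologous`.
#' @return An object of class `quotient_graph`.
#' @export
quotient_graph <- function(nodes, edges, types) {
  if (is.null(nodes$label))
    nodes$label <- paste(nodes$chain, nodes$op, sep = "_")
  if (nrow(edges) > 0) {
    stopifnot(all(edges$src %in% nodes$id), all(edges$dst %in% nodes$id))
  }
  structure(list(nodes = nodes, edges = edges, types = types),
            class = "quotient_graph")
}

#' @export
print.quotient_graph <- function(x, ...) {
  cat(sprintf("<quotient_graph> %d nodes, %d edges, %d interface types\n",
              nrow(x$nodes), nrow(x$edges), nrow(x$types)))
  invisible(x)
}

.empty_edges <- function() {
  data.frame(src = integer(0), dst = integer(0), iface = integer(0),
             type = integer(0), hx = integer(0), hy = integer(0),
             hz = integer(0), area = numeric(0))
}

.empty_types <- function() {
  data.frame(type = integer(0), p = numeric(0), mean_area = numeric(0),
             isologous = logical(0))
}

# canonical orientation: lower (chain, op) endpoint is the source; for
# self-loops the translation's first non-zero component is positive
.canon_edge <- function(src, dst, h, nodes) {
  flip <- FALSE
  if (src > dst) flip <- TRUE
  else if (src == dst) {
    nz <- which(h != 0)
    if (length(nz) > 0 && h[nz[1]] < 0) flip <- TRUE
  }
  if (flip) list(src = dst, dst = src, h = -h) else
    list(src = src, dst = dst, h = h)
}

#' Build the lattice graph from detected interfaces
#'
#' Lifts each detected interface instance (a contact between an
#' asymmetric-unit chain under the identity and a symmetry image) to the
#' whole unit cell: for every space-group operator the contact is mapped to
#' an edge between unit-cell nodes, with the translation vector adjusted by
#' operator composition. The resulting multigraph is closed under the group
#' action.
#'
#' @param s The `xtal_structure`.
#' @param interfaces Interfaces from [find_interfaces()], with `type_id`
#'   filled by [cluster_interface_types()].
#' @param types Optional list of `interface_type` (to carry probabilities).
#' @return A `quotient_graph` whose node count is
#'   `n_chains * n_operators`.
#' @export
build_lattice_graph <- function(s, interfaces, types = NULL) {
  chains <- protein_chains(s)
  ids <- names(chains)
  nops <- length(s$ops)
  nodes <- data.frame(
    id = seq_len(length(ids) * nops),
    chain = rep(ids, each = nops),
    op = rep(seq_len(nops), length(ids)),
    entity = rep(vapply(chains, function(ch) ch$entity_id, integer(1)),
                 each = nops),
    stringsAsFactors = FALSE
  )
  nodes$label <- paste(nodes$chain, nodes$op, sep = "_")
  nid <- function(chain, op) nodes$id[nodes$chain == chain & nodes$op == op]
  rows <- list()
  for (f in interfaces) {
    g <- f$chain_b$op_id
    t <- f$chain_b$shift
    for (h in seq_len(nops)) {
      # endpoint A: chain_a under h (zero shift by node identity)
      # endpoint B: compose h with (g, t)
      comp <- symop_compose(s$ops[[h]],
                            symop(NA, s$ops[[g]]$rot, s$ops[[g]]$trans + t))
      m <- symop_match(comp, s$ops)
      ce <- .canon_edge(nid(f$chain_a$chain, h),
                        nid(f$chain_b$chain, m$op_id),
                        m$shift, nodes)
      rows[[length(rows) + 1L]] <- data.frame(
        src = ce$src, dst = ce$dst, iface = f$id, type = f$type_id,
        hx = ce$h[1], hy = ce$h[2], hz = ce$h[3], area = f$area)
    }
  }
  edges <- if (length(rows) > 0) unique(do.call(rbind, rows)) else
    .empty_edges()
  rownames(edges) <- NULL
  tdf <- if (!is.null(types) && length(types) > 0) {
    data.frame(
      type = vapply(types, function(tt) tt$type_id, integer(1)),
      p = vapply(types, function(tt) tt$p, numeric(1)),
      mean_area = vapply(types, function(tt) tt$mean_area, numeric(1)),
      isologous = vapply(types, function(tt) tt$isologous, logical(1)))
  } else if (nrow(edges) > 0) {
    stats::aggregate(list(mean_area = edges$area),
                     by = list(type = edges$type), FUN = mean) |>
      transform(p = NA_real_, isologous = NA)
  } else .empty_types()
  quotient_graph(nodes, edges, tdf)
}

#' Image of a quotient graph under a space-group operator
#'
#' Relabels every node `(chain, op)` by left-composition with operator `h`
#' and maps edge translations accordingly. For a correctly lifted lattice
#' graph the result equals the original graph (group-action invariance).
#'
#' @param g A `quotient_graph` built from a structure.
#' @param s The originating `xtal_structure`.
#' @param h_id Operator index to act with.
#' @return A `quotient_graph`.
#' @export
apply_group_action <- function(g, s, h_id) {
  h <- s$ops[[h_id]]
  nops <- length(s$ops)
  # node (chain, o) -> (chain, o') with integer shift s'
  maps <- lapply(seq_len(nops), function(o) {
    symop_match(symop_compose(h, s$ops[[o]]), s$ops)
  })
  rh <- h$rot
  edges <- g$edges
  if (nrow(edges) > 0) {
    new_rows <- lapply(seq_len(nrow(edges)), function(i) {
      e <- edges[i, ]
      src <- g$nodes[g$nodes$id == e$src, ]
      dst <- g$nodes[g$nodes$id == e$dst, ]
      ms <- maps[[src$op]]; md <- maps[[dst$op]]
      d <- c(e$hx, e$hy, e$hz)
      dnew <- md$shift + as.integer(round(rh %*% d)) - ms$shift
      nsrc <- g$nodes$id[g$nodes$chain == src$chain &
                           g$nodes$op == ms$op_id]
      ndst <- g$nodes$id[g$nodes$chain == dst$chain &
                           g$nodes$op == md$op_id]
      ce <- .canon_edge(nsrc, ndst, dnew, g$nodes)
      data.frame(src = ce$src, dst = ce$dst, iface = e$iface, type = e$type,
                 hx = ce$h[1], hy = ce$h[2], hz = ce$h[3], area = e$area)
    })
    edges <- do.call(rbind, new_rows)
    rownames(edges) <- NULL
  }
  quotient_graph(g$nodes, edges, g$types)
}

## ---- engaged subgraphs and cycles ----------------------------------------

#' Row indices of the edges engaged by a set of interface types
#'
#' @param g A `quotient_graph`.
#' @param engaged Integer vector of engaged type ids.
#' @return Integer vector of row indices into `g$edges`.
#' @export
engaged_edges <- function(g, engaged) {
  which(g$edges$type %in% engaged)
}

# connected components of the subgraph with the given edge rows;
# returns list(membership = int vector over nodes (by position in nodes df))
.components <- function(g, edge_rows) {
  n <- nrow(g$nodes)
  idx <- match(g$nodes$id, g$nodes$id)  # identity; nodes$id may be any ints
  pos <- function(id) match(id, g$nodes$id)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (r in edge_rows) {
    a <- find(pos(g$edges$src[r])); b <- find(pos(g$edges$dst[r]))
    if (a != b) parent[b] <- a
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Fundamental cycle basis of an engaged subgraph (Paton)
#'
#' Grows a spanning tree per connected component (Paton's method) and emits
#' one fundamental cycle per non-tree edge; self-loops are cycles of
#' length 1. The basis has size `|E| - |V_touched| + #components(touched)`.
#'
#' @param g A `quotient_graph`.
#' @param edge_rows Row indices into `g$edges` (default: all edges).
#' @return List of cycles; each cycle is a data frame with columns `edge`
#'   (row index) and `dir` (+1 traversed src->dst, -1 reversed).
#' @export
cycle_basis <- function(g, edge_rows = seq_len(nrow(g$edges))) {
  pos <- function(id) match(id, g$nodes$id)
  n <- nrow(g$nodes)
  # adjacency over the selected edges
  adj <- vector("list", n)
  loops <- integer(0)
  for (r in edge_rows) {
    a <- pos(g$edges$src[r]); b <- pos(g$edges$dst[r])
    if (a == b) { loops <- c(loops, r); next }
    adj[[a]] <- rbind(adj[[a]], c(r, b, 1L))
    adj[[b]] <- rbind(adj[[b]], c(r, a, -1L))
  }
  visited <- rep(FALSE, n)
  parent_edge <- rep(NA_integer_, n)   # edge row used to reach node
  parent_dir <- rep(NA_integer_, n)
  parent_node <- rep(NA_integer_, n)
  depth <- rep(0L, n)
  cycles <- lapply(loops, function(r) data.frame(edge = r, dir = 1L))
  # edge status: 0 unexplored, 1 tree edge, 2 chord already consumed
  estatus <- integer(length(g$edges$src))
  touched <- unique(c(vapply(edge_rows, function(r) pos(g$edges$src[r]),
                             integer(1)),
                      vapply(edge_rows, function(r) pos(g$edges$dst[r]),
                             integer(1))))
  for (root in touched) {
    if (visited[root]) next
    visited[root] <- TRUE
    stack <- root
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      av <- adj[[v]]
      if (is.null(av)) next
      for (k in seq_len(nrow(av))) {
        r <- av[k, 1]; w <- av[k, 2]; dr <- av[k, 3]
        if (estatus[r] != 0L) next
        if (!visited[w]) {
          visited[w] <- TRUE
          estatus[r] <- 1L
          parent_edge[w] <- r; parent_dir[w] <- dr; parent_node[w] <- v
          depth[w] <- depth[v] + 1L
          stack <- c(stack, w)
        } else {
          # chord (v -> w): fundamental cycle = chord + tree path w..v
          # cycle: chord v->w, then w up to the LCA (against each tree
          # edge's parent->child direction), then LCA down to v (with it)
          cyc <- data.frame(edge = r, dir = dr)
          x <- v; y <- w
          up_x <- NULL; up_y <- NULL
          while (depth[x] > depth[y]) {
            up_x <- rbind(up_x, c(parent_edge[x], parent_dir[x]))
            x <- parent_node[x]
          }
          while (depth[y] > depth[x]) {
            up_y <- rbind(up_y, c(parent_edge[y], -parent_dir[y]))
            y <- parent_node[y]
          }
          while (x != y) {
            up_x <- rbind(up_x, c(parent_edge[x], parent_dir[x]))
            x <- parent_node[x]
            up_y <- rbind(up_y, c(parent_edge[y], -parent_dir[y]))
            y <- parent_node[y]
          }
          # cycle: chord v->w, then w up to LCA, then LCA down to v
          path <- rbind(up_y,
                        if (is.null(up_x)) NULL else
                          up_x[rev(seq_len(nrow(up_x))), , drop = FALSE])
          if (!is.null(path))
            cyc <- rbind(cyc, data.frame(edge = path[, 1], dir = path[, 2]))
          # mark chord as used so the reverse adjacency copy is skipped
          estatus[r] <- 2L
          cycles[[length(cycles) + 1L]] <- cyc
        }
      }
    }
  }
  cycles
}

#' Net translation of a cycle
#'
#' Signed sum of the edge translation vectors along a cycle.
#'
#' @param g A `quotient_graph`.
#' @param cycle A cycle as returned by [cycle_basis()].
#' @return Integer 3-vector.
#' @export
cycle_translation <- function(g, cycle) {
  h <- c(0L, 0L, 0L)
  for (i in seq_len(nrow(cycle))) {
    r <- cycle$edge[i]
    h <- h + cycle$dir[i] * c(g$edges$hx[r], g$edges$hy[r], g$edges$hz[r])
  }
  as.integer(h)
}

## ---- import / export ------------------------------------------------------

#' Export a quotient graph
#'
#' Writes the lattice graph losslessly as JSON (the package's lattice-graph
#' dialect, re-importable with [read_graph_json()]) or as GraphML.
#'
#' @param g A `quotient_graph`.
#' @param path Output path.
#' @param format `"json"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(g, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") .write_graph_json(g, path) else
    .write_graphml(g, path)
  invisible(path)
}

.write_graph_json <- function(g, path) {
  nodes <- lapply(seq_len(nrow(g$nodes)), function(i) {
    list(chain = g$nodes$chain[i], op = g$nodes$op[i],
         entity = g$nodes$entity[i])
  })
  p_of <- function(tp) {
    v <- g$types$p[g$types$type == tp]
    if (length(v) == 1 && !is.na(v)) v else NULL
  }
  edges <- lapply(seq_len(nrow(g$edges)), function(i) {
    e <- g$edges[i, ]
    lab <- function(id) g$nodes$label[g$nodes$id == id]
    out <- list(src = lab(e$src), dst = lab(e$dst), type = e$type,
                xtal = c(e$hx, e$hy, e$hz), area = e$area)
    pv <- p_of(e$type)
    if (!is.null(pv)) out$p <- pv
    out
  })
  types <- lapply(seq_len(nrow(g$types)), function(i) {
    tt <- g$types[i, ]
    list(type = tt$type, p = if (is.na(tt$p)) NULL else tt$p,
         mean_area = tt$mean_area,
         isologous = if (is.na(tt$isologous)) NULL else tt$isologous)
  })
  jsonlite::write_json(list(nodes = nodes, edges = edges, types = types),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
}

#' Read a lattice graph from JSON
#'
#' Reads the documented lattice-graph JSON dialect:
#' `{"nodes": [{"chain","op","entity"}], "edges": [{"src","dst","type",
#' "xtal":[h,k,l],"area","p"}], "types": [...]}`. `src`/`dst` reference
#' nodes by their `chain_op` label. This is the abstract entry point that
#' bypasses geometry: per-type probabilities in the file feed scoring
#' directly.
#'
#' @param path JSON file path.
#' @return A `quotient_graph`.
#' @export
read_graph_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  nodes <- do.call(rbind, lapply(seq_along(j$nodes), function(i) {
    nd <- j$nodes[[i]]
    data.frame(id = i, chain = nd$chain, op = as.integer(nd$op),
               entity = as.integer(nd$entity), stringsAsFactors = FALSE)
  }))
  nodes$label <- paste(nodes$chain, nodes$op, sep = "_")
  edges <- if (length(j$edges) > 0) {
    do.call(rbind, lapply(j$edges, function(e) {
      src <- nodes$id[nodes$label == e$src]
      dst <- nodes$id[nodes$label == e$dst]
      if (length(src) != 1 || length(dst) != 1)
        stop("edge references unknown node: ", e$src, " -> ", e$dst)
      x <- unlist(e$xtal)
      data.frame(src = src, dst = dst,
                 iface = if (is.null(e$iface)) NA_integer_ else
                   as.integer(e$iface),
                 type = as.integer(e$type),
                 hx = as.integer(x[1]), hy = as.integer(x[2]),
                 hz = as.integer(x[3]),
                 area = if (is.null(e$area)) NA_real_ else
                   as.numeric(e$area),
                 p = if (is.null(e$p)) NA_real_ else as.numeric(e$p))
    }))
  } else cbind(.empty_edges(), p = numeric(0))
  if (nrow(edges) > 0 && any(is.na(edges$iface)))
    edges$iface <- seq_len(nrow(edges))
  types <- if (!is.null(j$types) && length(j$types) > 0) {
    do.call(rbind, lapply(j$types, function(tt) {
      data.frame(type = as.integer(tt$type),
                 p = if (is.null(tt$p)) NA_real_ else as.numeric(tt$p),
                 mean_area = if (is.null(tt$mean_area)) NA_real_ else
                   as.numeric(tt$mean_area),
                 isologous = if (is.null(tt$isologous)) NA else
                   as.logical(tt$isologous))
    }))
  } else if (nrow(edges) > 0) {
    agg <- stats::aggregate(
      list(p = edges$p, mean_area = edges$area),
      by = list(type = edges$type), FUN = function(v) mean(v, na.rm = TRUE))
    agg$p[is.nan(agg$p)] <- NA_real_
    agg$isologous <- NA
    agg
  } else .empty_types()
  edges$p <- NULL
  quotient_graph(nodes, edges, types)
}

.write_graphml <- function(g, path) {
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  keys <- c(chain = "string", op = "int", entity = "int")
  for (k in names(keys))
    w('  <key id="%s" for="node" attr.name="%s" attr.type="%s"/>',
      k, k, keys[k])
  ekeys <- c(iface = "int", type = "int", hx = "int", hy = "int",
             hz = "int", area = "double")
  for (k in names(ekeys))
    w('  <key id="%s" for="edge" attr.name="%s" attr.type="%s"/>',
      k, k, ekeys[k])
  w('  <graph id="lattice" edgedefault="directed">')
  for (i in seq_len(nrow(g$nodes))) {
    nd <- g$nodes[i, ]
    w('    <node id="%s">', esc(nd$label))
    w('      <data key="chain">%s</data>', esc(nd$chain))
    w('      <data key="op">%d</data>', nd$op)
    w('      <data key="entity">%d</data>', nd$entity)
    w('    </node>')
  }
  lab <- function(id) g$nodes$label[g$nodes$id == id]
  for (i in seq_len(nrow(g$edges))) {
    e <- g$edges[i, ]
    w('    <edge source="%s" target="%s">', esc(lab(e$src)), esc(lab(e$dst)))
    w('      <data key="iface">%d</data>', e$iface)
    w('      <data key="type">%d</data>', e$type)
    w('      <data key="hx">%d</data>', e$hx)
    w('      <data key="hy">%d</data>', e$hy)
    w('      <data key="hz">%d</data>', e$hz)
    w('      <data key="area">%.6f</data>', e$area)
    w('    </edge>')
  }
  w('  </graph>')
  w('</graphml>')
}

#' Read a GraphML lattice graph written by [export_graph()]
#'
#' @param path GraphML file.
#' @return A `quotient_graph` (type table rebuilt from edges).
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  nodes_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
  get_data <- function(x, key) {
    v <- xml2::xml_text(xml2::xml_find_first(
      x, sprintf(".//g:data[@key='%s']", key), ns))
    v
  }
  nodes <- do.call(rbind, lapply(seq_along(nodes_xml), function(i) {
    x <- nodes_xml[[i]]
    data.frame(id = i, chain = get_data(x, "chain"),
               op = as.integer(get_data(x, "op")),
               entity = as.integer(get_data(x, "entity")),
               label = xml2::xml_attr(x, "id"), stringsAsFactors = FALSE)
  }))
  edges_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
  edges <- if (length(edges_xml) > 0) {
    do.call(rbind, lapply(edges_xml, function(x) {
      data.frame(
        src = nodes$id[nodes$label == xml2::xml_attr(x, "source")],
        dst = nodes$id[nodes$label == xml2::xml_attr(x, "target")],
        iface = as.integer(get_data(x, "iface")),
        type = as.integer(get_data(x, "type")),
        hx = as.integer(get_data(x, "hx")),
        hy = as.integer(get_data(x, "hy")),
        hz = as.integer(get_data(x, "hz")),
        area = as.numeric(get_data(x, "area")))
    }))
  } else .empty_edges()
  types <- if (nrow(edges) > 0) {
    agg <- stats::aggregate(list(mean_area = edges$area),
                            by = list(type = edges$type), FUN = mean)
    agg$p <- NA_real_; agg$isologous <- NA
    agg
  } else .empty_types()
  quotient_graph(nodes, edges, types)
}
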