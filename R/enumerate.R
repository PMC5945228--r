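# Assembly enumeration under the four validity rules.
#
# A superassembly is a choice of engaged interface types. Validity:
#   1. full coverage   — every chain in exactly one assembly (automatic:
#                        assemblies are the connected components),
#   2. uniform composition — all instances of a type engaged together
#                        (by construction: engagement is per type),
#   3. isomorphism     — non-orthogonal assemblies must be isomorphic as
#                        entity/type-labelled graphs,
#   4. closed symmetry — no engaged cycle may carry a net lattice
#                        translation (no infinite fibers).
# Rule-4 failures are monotone under adding interface types, which prunes
# the power-set traversal; rule 3 is re-evaluated per subset and never
# prunes.

#' Check the closed-symmetry rule (rule 4)
#'
#' Computes the Paton fundamental cycle basis of the engaged subgraph and
#' verifies that every basis cycle has zero net translation. A failing
#' cycle is returned as witness.
#'
#' @param g A `quotient_graph`.
#' @param engaged Integer vector of engaged type ids.
#' @return List: `valid`, `failed_rule` (`"closure"` or `NA`), `witness`
#'   (a failing cycle, or `NULL`).
#' @export
check_closed_symmetry <- function(g, engaged) {
  rows <- engaged_edges(g, engaged)
  for (cyc in cycle_basis(g, rows)) {
    if (any(cycle_translation(g, cyc) != 0L))
      return(list(valid = FALSE, failed_rule = "closure", witness = cyc))
  }
  list(valid = TRUE, failed_rule = NA_character_, witness = NULL)
}

# fast internal engaged-subgraph analysis via node potentials:
# components + cell offsets + rule-4 verdict in one sweep
.engaged_analysis <- function(g, rows) {
  n <- nrow(g$nodes)
  src <- match(g$edges$src, g$nodes$id)
  dst <- match(g$edges$dst, g$nodes$id)
  adj <- vector("list", n)
  for (r in rows) {
    a <- src[r]; b <- dst[r]
    adj[[a]] <- c(adj[[a]], r)
    if (b != a) adj[[b]] <- c(adj[[b]], r)
  }
  comp <- rep(NA_integer_, n)
  off <- matrix(0L, n, 3)
  nc <- 0L
  for (start in seq_len(n)) {
    if (!is.na(comp[start])) next
    nc <- nc + 1L
    comp[start] <- nc
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (r in adj[[v]]) {
        d <- c(g$edges$hx[r], g$edges$hy[r], g$edges$hz[r])
        ends <- if (src[r] == v) list(w = dst[r], dd = d) else
          list(w = src[r], dd = -d)
        w <- ends$w
        target_off <- off[v, ] + ends$dd
        if (src[r] == dst[r]) {
          # self-loop: valid only with zero translation
          if (any(d != 0L))
            return(list(valid = FALSE, edge = r, comp = comp, off = off))
          next
        }
        if (is.na(comp[w])) {
          comp[w] <- nc
          off[w, ] <- target_off
          queue <- c(queue, w)
        } else if (any(off[w, ] != target_off)) {
          return(list(valid = FALSE, edge = r, comp = comp, off = off))
        }
      }
    }
  }
  list(valid = TRUE, comp = comp, off = off, n_comp = nc)
}

#' Extract assemblies from an engaged interface-type set
#'
#' Assemblies are the connected components of the engaged subgraph, lifted
#' to concrete cell offsets along a spanning tree (root at offset 0); one
#' representative per lattice-translation orbit is returned.
#'
#' @param g A `quotient_graph`.
#' @param engaged Integer vector of engaged type ids.
#' @return List of `assembly` objects: `members` (node, chain, op, entity,
#'   ox, oy, oz), `stoich` (named entity count vector), `size`, `edges`
#'   (local engaged edge table), `engaged`.
#' @export
extract_assemblies <- function(g, engaged) {
  rows <- engaged_edges(g, engaged)
  an <- .engaged_analysis(g, rows)
  if (!an$valid)
    stop("engaged set violates the closed-symmetry rule; check rule 4 first")
  src <- match(g$edges$src, g$nodes$id)
  dst <- match(g$edges$dst, g$nodes$id)
  ents <- sort(unique(g$nodes$entity))
  lapply(seq_len(an$n_comp), function(ci) {
    nodes_i <- which(an$comp == ci)
    members <- data.frame(
      node = g$nodes$id[nodes_i],
      chain = g$nodes$chain[nodes_i],
      op = g$nodes$op[nodes_i],
      entity = g$nodes$entity[nodes_i],
      ox = an$off[nodes_i, 1], oy = an$off[nodes_i, 2],
      oz = an$off[nodes_i, 3],
      stringsAsFactors = FALSE)
    stoich <- vapply(ents, function(e) sum(members$entity == e), integer(1))
    names(stoich) <- as.character(ents)
    local_rows <- rows[src[rows] %in% nodes_i]
    structure(list(
      members = members,
      stoich = stoich,
      size = nrow(members),
      edges = g$edges[local_rows, , drop = FALSE],
      engaged = engaged,
      point_group = NA_character_
    ), class = "assembly")
  })
}

#' @export
print.assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s (%d chains)%s\n", format_stoich(x$stoich),
              x$size,
              if (is.na(x$point_group)) "" else paste0(" ", x$point_group)))
  invisible(x)
}

#' Format a stoichiometry vector as a formula string
#'
#' @param stoich Named entity-count vector.
#' @return String such as `"A2B2"` (entities lettered in id order).
#' @export
format_stoich <- function(stoich) {
  nz <- which(stoich > 0)
  paste(vapply(nz, function(i) {
    paste0(LETTERS[(as.integer(names(stoich)[i]) - 1) %% 26 + 1],
           if (stoich[i] > 1) stoich[i] else "")
  }, character(1)), collapse = "")
}

## ---- labelled multigraph isomorphism -------------------------------------

# adjacency signature: for each unordered node pair, the sorted multiset of
# edge types; self-loops keyed to the node itself
.assembly_adj <- function(a) {
  pos <- match(c(a$edges$src, a$edges$dst), a$members$node)
  m <- nrow(a$edges)
  adj <- list()
  if (m > 0) {
    for (i in seq_len(m)) {
      u <- pos[i]; v <- pos[m + i]
      key <- paste(sort(c(u, v)), collapse = "-")
      adj[[key]] <- sort(c(adj[[key]], a$edges$type[i]))
    }
  }
  adj
}

# exact isomorphism of two entity/type-labelled multigraphs by backtracking
.assembly_isomorphic <- function(a1, a2) {
  n <- a1$size
  if (n != a2$size) return(FALSE)
  if (!identical(sort(a1$members$entity), sort(a2$members$entity)))
    return(FALSE)
  if (!identical(sort(a1$edges$type), sort(a2$edges$type)))
    return(FALSE)
  adj1 <- .assembly_adj(a1)
  adj2 <- .assembly_adj(a2)
  ent1 <- a1$members$entity
  ent2 <- a2$members$entity
  # per-node invariant: entity + sorted incident type multiset
  inv <- function(adj, nn) {
    out <- vector("list", nn)
    for (key in names(adj)) {
      uv <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
      for (x in unique(uv)) out[[x]] <- c(out[[x]], adj[[key]])
    }
    vapply(seq_len(nn), function(i)
      paste(sort(out[[i]]), collapse = ","), character(1))
  }
  inv1 <- paste(ent1, inv(adj1, n)); inv2 <- paste(ent2, inv(adj2, n))
  if (!identical(sort(inv1), sort(inv2))) return(FALSE)
  mapped <- rep(NA_integer_, n)   # node i of a1 -> mapped[i] of a2
  used <- rep(FALSE, n)
  pair_key <- function(u, v) paste(sort(c(u, v)), collapse = "-")
  ok_edge <- function(u, v, mu, mv) {
    identical(adj1[[pair_key(u, v)]], adj2[[pair_key(mu, mv)]])
  }
  bt <- function(i) {
    if (i > n) return(TRUE)
    for (cand in which(!used & inv2 == inv1[i])) {
      fine <- TRUE
      for (j in seq_len(i - 1)) {
        k1 <- adj1[[pair_key(i, j)]]
        k2 <- adj2[[pair_key(cand, mapped[j])]]
        if (!identical(k1, k2)) { fine <- FALSE; break }
      }
      if (!identical(adj1[[pair_key(i, i)]], adj2[[pair_key(cand, cand)]]))
        fine <- FALSE
      if (fine) {
        mapped[i] <<- cand; used[cand] <<- TRUE
        if (bt(i + 1)) return(TRUE)
        used[cand] <<- FALSE; mapped[i] <<- NA_integer_
      }
    }
    FALSE
  }
  bt(1)
}

#' Check the isomorphism rule (rule 3)
#'
#' Assemblies with non-orthogonal stoichiometries (sharing at least one
#' entity) must be isomorphic as labelled graphs (node label = entity,
#' edge label = interface type). Orthogonal assemblies are exempt
#' (co-crystals of unrelated entities).
#'
#' @param assemblies List of `assembly` objects from one engaged set.
#' @return List: `valid`, `failed_rule` (`"isomorphism"` or `NA`),
#'   `witness` (indices of the first failing pair, or `NULL`).
#' @export
check_isomorphism <- function(assemblies) {
  k <- length(assemblies)
  if (k <= 1)
    return(list(valid = TRUE, failed_rule = NA_character_, witness = NULL))
  # group by stoichiometry: identical stoichiometries need a single
  # representative comparison each; differing non-orthogonal ones fail on
  # the cheap stoichiometry test already
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    si <- assemblies[[i]]$stoich; sj <- assemblies[[j]]$stoich
    if (sum(si * sj) == 0) next  # orthogonal: exempt
    if (!identical(si, sj) ||
        !.assembly_isomorphic(assemblies[[i]], assemblies[[j]]))
      return(list(valid = FALSE, failed_rule = "isomorphism",
                  witness = c(i, j)))
  }
  list(valid = TRUE, failed_rule = NA_character_, witness = NULL)
}

## ---- enumeration ----------------------------------------------------------

.validate_engaged <- function(g, engaged) {
  rows <- engaged_edges(g, engaged)
  an <- .engaged_analysis(g, rows)
  if (!an$valid) return(list(valid = FALSE, rule4 = FALSE))
  asms <- extract_assemblies(g, engaged)
  iso <- check_isomorphism(asms)
  list(valid = iso$valid, rule4 = TRUE, assemblies = asms)
}

#' Enumerate all valid superassemblies
#'
#' Depth-first traversal of the power set of interface types (ordered by
#' descending area, i.e. ascending type id). Any set violating the
#' closed-symmetry rule prunes its whole subtree (supersets inherit the
#' offending cycle); the isomorphism rule is evaluated per subset. The
#' empty set (all-monomer superassembly) is always valid.
#'
#' @param g A `quotient_graph`.
#' @param max_types Guard on the number of interface types (default 32).
#' @return List of `superassembly` objects: `engaged` (sorted type ids),
#'   `assemblies` (list of `assembly`).
#' @export
enumerate_superassemblies <- function(g, max_types = 32) {
  type_ids <- sort(g$types$type)
  n <- length(type_ids)
  if (n > max_types)
    stop("crystal has ", n, " interface types (> max_types = ", max_types,
         "); consider entity contraction or raising the limit")
  out <- list()
  recurse <- function(engaged, start) {
    v <- .validate_engaged(g, engaged)
    if (!v$rule4) return(invisible())   # prune subtree
    if (v$valid) {
      out[[length(out) + 1L]] <<- structure(
        list(engaged = engaged, assemblies = v$assemblies),
        class = "superassembly")
    }
    for (k in seq_len(n)) {
      if (k < start) next
      recurse(c(engaged, type_ids[k]), k + 1L)
    }
  }
  recurse(integer(0), 1L)
  out
}

#' @export
print.superassembly <- function(x, ...) {
  st <- table(vapply(x$assemblies, function(a) format_stoich(a$stoich),
                     character(1)))
  cat(sprintf("<superassembly> engaged {%s}: %s\n",
              paste(x$engaged, collapse = ","),
              paste(sprintf("%s x%d", names(st), st), collapse = " + ")))
  invisible(x)
}

#' Unpruned brute-force enumeration over all subsets
#'
#' Evaluates every one of the `2^n` engaged sets independently. Used as the
#' reference against which the pruned traversal is validated.
#'
#' @param g A `quotient_graph`.
#' @return List of valid engaged sets (integer vectors).
#' @export
brute_force_valid_sets <- function(g) {
  type_ids <- sort(g$types$type)
  n <- length(type_ids)
  out <- list()
  for (mask in 0:(2^n - 1)) {
    engaged <- type_ids[bitwAnd(mask, 2^(seq_len(n) - 1)) != 0]
    v <- .validate_engaged(g, engaged)
    if (v$valid) out[[length(out) + 1L]] <- engaged
  }
  out
}

## ---- entity contraction ---------------------------------------------------

# contract all edges of one interface type; pre: solo engagement of `t`
# passes rules 3+4
.contract_type <- function(g, t) {
  rows <- engaged_edges(g, t)
  an <- .engaged_analysis(g, rows)
  if (!an$valid) stop("cannot contract a type violating rule 4")
  comp <- an$comp
  # meta entity: one label per distinct member-entity multiset
  sig <- vapply(seq_len(max(comp)), function(ci)
    paste(sort(g$nodes$entity[comp == ci]), collapse = "+"), character(1))
  meta_ent <- match(sig, unique(sig))
  nodes <- data.frame(
    id = seq_len(max(comp)),
    chain = vapply(seq_len(max(comp)), function(ci)
      paste(sort(g$nodes$label[comp == ci]), collapse = "+"), character(1)),
    op = 1L,
    entity = meta_ent,
    stringsAsFactors = FALSE)
  nodes$label <- nodes$chain
  keep <- setdiff(seq_len(nrow(g$edges)), rows)
  src_pos <- match(g$edges$src, g$nodes$id)
  dst_pos <- match(g$edges$dst, g$nodes$id)
  edges <- if (length(keep) > 0) {
    do.call(rbind, lapply(keep, function(r) {
      u <- src_pos[r]; v <- dst_pos[r]
      d <- c(g$edges$hx[r], g$edges$hy[r], g$edges$hz[r]) +
        an$off[u, ] - an$off[v, ]
      ce <- .canon_edge(comp[u], comp[v], d, nodes)
      data.frame(src = ce$src, dst = ce$dst, iface = g$edges$iface[r],
                 type = g$edges$type[r], hx = ce$h[1], hy = ce$h[2],
                 hz = ce$h[3], area = g$edges$area[r])
    }))
  } else .empty_edges()
  mapping <- data.frame(
    meta = comp,
    node = g$nodes$id,
    chain = g$nodes$chain,
    op = g$nodes$op,
    entity = g$nodes$entity,
    ox = an$off[, 1], oy = an$off[, 2], oz = an$off[, 3])
  gq <- quotient_graph(nodes, edges, g$types[g$types$type != t, ,
                                             drop = FALSE])
  list(graph = gq, mapping = mapping, contracted_type = t)
}

# greedy choice among inter-entity types: highest p, tie-break mean area
.pick_inter_entity_type <- function(g) {
  if (nrow(g$edges) == 0) return(integer(0))
  src_e <- g$nodes$entity[match(g$edges$src, g$nodes$id)]
  dst_e <- g$nodes$entity[match(g$edges$dst, g$nodes$id)]
  cand <- unique(g$edges$type[src_e != dst_e])
  if (length(cand) == 0) return(integer(0))
  tt <- g$types[g$types$type %in% cand, , drop = FALSE]
  p <- ifelse(is.na(tt$p), -1, tt$p)
  tt$type[order(-p, -tt$mean_area)]
}

#' Contract entities of a heteromeric lattice graph
#'
#' Repeatedly selects the inter-entity interface type with the highest
#' probability (tie-break: largest mean area), contracts its edges merging
#' the joined entities into a meta-entity, and iterates until no
#' contractible inter-entity type remains (one meta-entity per connected
#' entity block). Only types whose solo engagement passes rules 3 and 4
#' are contracted, which preserves validity verdicts and relative scores.
#'
#' @param g A `quotient_graph`.
#' @return List: `graph` (contracted `quotient_graph`), `steps` (list of
#'   per-step mappings: contracted type plus meta-node composition with
#'   cell offsets), `forced` (types engaged by the contraction).
#' @export
contract_entities <- function(g) {
  steps <- list()
  forced <- integer(0)
  repeat {
    cand <- .pick_inter_entity_type(g)
    done <- TRUE
    for (t in cand) {
      v4 <- .engaged_analysis(g, engaged_edges(g, t))
      if (!v4$valid) next
      iso <- check_isomorphism(extract_assemblies(g, t))
      if (!iso$valid) next
      ct <- .contract_type(g, t)
      steps[[length(steps) + 1L]] <- ct["mapping"]
      steps[[length(steps)]]$contracted_type <- t
      forced <- c(forced, t)
      g <- ct$graph
      done <- FALSE
      break
    }
    if (done) break
  }
  list(graph = g, steps = steps, forced = forced)
}

#' Enumerate superassemblies through entity contraction
#'
#' Recursive enumeration for heteromers: the greedy inter-entity type is
#' either engaged (the graph is contracted and the smaller problem solved)
#' or disengaged (the type is deleted and the recursion continues). Both
#' branches are exact, so the returned engaged sets equal those of
#' [enumerate_superassemblies()] run directly; assemblies are extracted on
#' the original graph.
#'
#' @param g A `quotient_graph`.
#' @param max_types Guard passed to the base enumerator.
#' @return Same structure as [enumerate_superassemblies()].
#' @export
enumerate_with_contraction <- function(g, max_types = 32) {
  sets <- .enum_contract_sets(g, max_types)
  # dedup + order, then rebuild assemblies on the original graph
  keys <- vapply(sets, function(s) paste(sort(s), collapse = ","),
                 character(1))
  sets <- sets[!duplicated(keys)]
  ord <- order(vapply(sets, length, integer(1)),
               vapply(sets, function(s) paste(sprintf("%04d", s),
                                              collapse = ","), character(1)))
  lapply(sets[ord], function(s) {
    structure(list(engaged = s, assemblies = extract_assemblies(g, s)),
              class = "superassembly")
  })
}

.enum_contract_sets <- function(g, max_types) {
  n_ent <- length(unique(g$nodes$entity))
  cand <- .pick_inter_entity_type(g)
  if (n_ent <= 1 || length(cand) == 0) {
    return(lapply(enumerate_superassemblies(g, max_types),
                  function(sa) sa$engaged))
  }
  t <- cand[1]
  v4 <- .engaged_analysis(g, engaged_edges(g, t))
  res <- list()
  if (v4$valid && check_isomorphism(extract_assemblies(g, t))$valid) {
    ct <- .contract_type(g, t)
    sub <- .enum_contract_sets(ct$graph, max_types)
    res <- c(res, lapply(sub, function(s) sort(c(s, t))))
  } else if (v4$valid) {
    # solo engagement breaks isomorphism only: supersets may still be
    # valid, so fall back to direct enumeration for the engaged branch
    direct <- enumerate_superassemblies(g, max_types)
    res <- c(res, Filter(Negate(is.null),
                         lapply(direct, function(sa)
                           if (t %in% sa$engaged) sa$engaged)))
  } # rule-4-invalid solo: every superset containing t is invalid
  # disengaged branch: delete the type and recurse
  gB <- g
  gB$edges <- gB$edges[gB$edges$type != t, , drop = FALSE]
  gB$types <- gB$types[gB$types$type != t, , drop = FALSE]
  c(res, .enum_contract_sets(gB, max_types))
}

## ---- point groups ---------------------------------------------------------

#' Detect the point group of an assembly
#'
#' With a structure available, collects all crystal isometries (proper
#' space-group rotation plus integer lattice shift) that map the
#' assembly's chain set onto itself entity-preservingly within an RMSD
#' tolerance, and classifies the resulting rotation group: cyclic `Cn`,
#' dihedral `Dn`, tetrahedral `T`, octahedral `O` or icosahedral `I`.
#' Without coordinates (abstract lattice-graph input) a topological
#' heuristic is used: single (meta-)chain C1; a single engaged constitutive
#' type gives a cyclic group; multiple types with an even chain count give
#' a dihedral group.
#'
#' @param a An `assembly`.
#' @param s The `xtal_structure`, or `NULL` for the topological heuristic.
#' @param tol Per-chain RMSD tolerance in Angstrom (default 2.0).
#' @return Point-group label (`"C1"`, `"C2"`, ..., `"D3"`, `"T"`, `"O"`,
#'   `"I"`) or `"none"` when a multi-chain assembly admits no
#'   self-isometry beyond the identity.
#' @export
detect_point_group <- function(a, s = NULL, tol = 2.0) {
  if (is.null(s)) return(.point_group_topology(a))
  if (a$size == 1) return("C1")
  mem <- a$members
  placed <- lapply(seq_len(nrow(mem)), function(i) {
    ch <- s$chains[[mem$chain[i]]]
    apply_operator(ch, s$ops[[mem$op[i]]],
                   c(mem$ox[i], mem$oy[i], mem$oz[i]), s$cell)
  })
  cent_frac <- t(vapply(placed, function(ch)
    fractionalize(s$cell, colMeans(ch$xyz)), numeric(3)))
  rots <- list()
  for (op in s$ops) {
    if (det(op$rot) < 0) next  # protein crystals: proper rotations only
    # candidate lattice shifts from mapping member 1 onto each same-entity
    # member
    img1 <- as.numeric(op$rot %*% cent_frac[1, ]) + op$trans
    cands <- which(mem$entity == mem$entity[1])
    for (j in cands) {
      tv <- cent_frac[j, ] - img1
      ti <- round(tv)
      if (max(abs(tv - ti)) > 0.25) next
      # verify the full mapping under (op, ti)
      perm <- integer(nrow(mem)); ok <- TRUE
      for (i in seq_len(nrow(mem))) {
        xi <- t(op$rot %*% t(fractionalize(s$cell, placed[[i]]$xyz))) +
          matrix(op$trans + ti, nrow(placed[[i]]$xyz), 3, byrow = TRUE)
        xi <- orthogonalize(s$cell, xi)
        best <- NA_integer_; best_rmsd <- Inf
        for (k in which(mem$entity == mem$entity[i])) {
          yk <- placed[[k]]$xyz
          if (nrow(yk) == nrow(xi)) {
            rmsd <- sqrt(mean(rowSums((xi - yk)^2)))
          } else {
            rmsd <- sqrt(sum((colMeans(xi) - colMeans(yk))^2))
          }
          if (rmsd < best_rmsd) { best_rmsd <- rmsd; best <- k }
        }
        if (is.na(best) || best_rmsd > tol || best %in% perm[seq_len(i - 1)]) {
          ok <- FALSE; break
        }
        perm[i] <- best
      }
      if (ok) {
        rc <- s$cell$orth %*% op$rot %*% s$cell$frac
        rots[[length(rots) + 1L]] <- rc
        break  # one lattice shift per operator suffices
      }
    }
  }
  if (length(rots) <= 1) {
    # heteromer with one chain per entity: fusing entities leaves a single
    # meta-chain, i.e. C1 (no isometry beyond the identity is expected)
    if (all(a$stoich[a$stoich > 0] == 1)) return("C1")
    warning("multi-chain assembly with no self-isometry beyond the ",
            "identity; labelling point group 'none'")
    return("none")
  }
  .classify_rotation_group(rots)
}

.rotation_order <- function(r) {
  tr <- max(min((sum(diag(r)) - 1) / 2, 1), -1)
  ang <- acos(tr)
  if (ang < 1e-6) return(1L)
  as.integer(round(2 * pi / ang))
}

.rotation_axis <- function(r) {
  ev <- eigen(r)
  i <- which.min(abs(ev$values - 1))
  ax <- Re(ev$vectors[, i])
  ax <- ax / sqrt(sum(ax^2))
  # canonical sign
  nz <- which(abs(ax) > 1e-8)
  if (length(nz) > 0 && ax[nz[1]] < 0) ax <- -ax
  ax
}

.classify_rotation_group <- function(rots) {
  n <- length(rots)
  orders <- vapply(rots, .rotation_order, integer(1))
  nonid <- which(orders > 1)
  if (length(nonid) == 0) return("C1")
  axes <- t(vapply(rots[nonid], .rotation_axis, numeric(3)))
  same_axis <- all(abs(abs(axes %*% axes[1, ]) - 1) < 1e-4)
  kmax <- max(orders)
  if (same_axis) return(paste0("C", n))
  if (n == 12 && kmax == 3) return("T")
  if (n == 24 && kmax == 4) return("O")
  if (n == 60 && kmax == 5) return("I")
  if (n == 2 * kmax) return(paste0("D", kmax))
  "none"
}

.point_group_topology <- function(a) {
  ents <- unique(a$members$entity)
  per <- a$stoich[a$stoich > 0]
  if (length(unique(per)) > 1) return("none")  # uneven heteromer
  k <- unname(per[1])  # chains per entity = meta-chain count
  if (k == 1) return("C1")
  n_types <- length(unique(a$edges$type))
  if (n_types <= 1) return(paste0("C", k))
  if (k %% 2 == 0) return(paste0("D", k / 2))
  paste0("C", k)
}
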