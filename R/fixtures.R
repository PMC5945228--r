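# Deterministic synthetic fixtures.
#
# Canned abstract lattice graphs and small geometric crystals covering the
# topological regimes the method must distinguish: a crystallographic C2
# dimer, an infinite fiber (closed-symmetry violation, built both as a bare
# self-contact and as the deceptive "capped" arrangement where the
# asymmetric-unit dimer looks like an isolated block), a lattice whose C2
# dimer is not isomorphic throughout the crystal, a D3 hexamer with an
# induced interface, and an A-B heterodimer for contraction. Pseudo-chains
# are small rigid clouds of 1.9-Angstrom pseudo-atoms: large enough for
# meaningful buried areas, small enough for instant ASA.

.GRAPH_TEMPLATES <- c("c2_dimer", "fiber", "fiber_capped", "non_isomorphic",
                      "d3_hexamer", "heterodimer_ab")

.gf_nodes <- function(chain, op, entity) {
  data.frame(id = seq_along(chain), chain = chain, op = as.integer(op),
             entity = as.integer(entity),
             label = paste(chain, op, sep = "_"), stringsAsFactors = FALSE)
}

.gf_edges <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(seq_along(rows), function(i) {
    r <- rows[[i]]
    data.frame(src = r[[1]], dst = r[[2]], iface = i, type = r[[3]],
               hx = r[[4]][1], hy = r[[4]][2], hz = r[[4]][3],
               area = r[[5]])
  }))
}

.gf_types <- function(type, p, mean_area, isologous) {
  data.frame(type = as.integer(type), p = p, mean_area = mean_area,
             isologous = isologous)
}

#' Canned abstract lattice-graph fixtures
#'
#' Deterministic quotient graphs for each topological regime:
#' \describe{
#'   \item{c2_dimer}{one entity, one isologous type; `{}` and `{1}` valid.}
#'   \item{fiber}{one heterologous self-contact with translation (1,0,0);
#'     engaging it builds an infinite fiber, so only `{}` is valid.}
#'   \item{fiber_capped}{two chains joined face-to-back; the asymmetric-unit
#'     dimer looks like an isolated block but uniform composition chains
#'     the instances into a fiber: only `{}` is valid.}
#'   \item{non_isomorphic}{three chains of one entity; the C2 dimer type
#'     leaves a monomer behind and fails the isomorphism rule.}
#'   \item{d3_hexamer}{six chains, three interface types (2-folds,
#'     trimerization, induced diagonals) forming a D3 hexamer.}
#'   \item{heterodimer_ab}{two entities joined by one inter-entity type;
#'     used for contraction.}
#' }
#'
#' @param name Template name (see above).
#' @return A `quotient_graph`.
#' @export
graph_fixture <- function(name = .GRAPH_TEMPLATES) {
  name <- match.arg(name)
  switch(name,
    c2_dimer = quotient_graph(
      .gf_nodes(c("A", "A"), c(1, 2), c(1, 1)),
      .gf_edges(list(1, 2, 1L, c(0, 0, 0), 800)),
      .gf_types(1L, 0.9, 800, TRUE)),
    fiber = quotient_graph(
      .gf_nodes("A", 1, 1),
      .gf_edges(list(1, 1, 1L, c(1, 0, 0), 600)),
      .gf_types(1L, 0.8, 600, FALSE)),
    fiber_capped = quotient_graph(
      .gf_nodes(c("A", "B"), c(1, 1), c(1, 1)),
      .gf_edges(list(1, 2, 1L, c(0, 0, 0), 600),
                list(2, 1, 1L, c(1, 0, 0), 600)),
      .gf_types(1L, 0.8, 600, FALSE)),
    non_isomorphic = quotient_graph(
      .gf_nodes(c("A", "B", "C"), c(1, 1, 1), c(1, 1, 1)),
      .gf_edges(list(1, 2, 1L, c(0, 0, 0), 900)),
      .gf_types(1L, 0.6, 900, TRUE)),
    d3_hexamer = quotient_graph(
      .gf_nodes(rep("A", 6), 1:6, rep(1, 6)),
      .gf_edges(
        # type 1: isologous 2-folds pairing the two trimer rings
        list(1, 4, 1L, c(0, 0, 0), 1000),
        list(2, 5, 1L, c(0, 0, 0), 1000),
        list(3, 6, 1L, c(0, 0, 0), 1000),
        # type 2: heterologous trimerization rings
        list(1, 2, 2L, c(0, 0, 0), 800),
        list(2, 3, 2L, c(0, 0, 0), 800),
        list(3, 1, 2L, c(0, 0, 0), 800),
        list(4, 5, 2L, c(0, 0, 0), 800),
        list(5, 6, 2L, c(0, 0, 0), 800),
        list(6, 4, 2L, c(0, 0, 0), 800),
        # type 3: induced inter-ring diagonals
        list(1, 5, 3L, c(0, 0, 0), 500),
        list(2, 6, 3L, c(0, 0, 0), 500),
        list(3, 4, 3L, c(0, 0, 0), 500)),
      .gf_types(1:3, c(0.95, 0.9, 0.8), c(1000, 800, 500),
                c(TRUE, FALSE, TRUE))),
    heterodimer_ab = quotient_graph(
      .gf_nodes(c("A", "B"), c(1, 1), c(1, 2)),
      .gf_edges(list(1, 2, 1L, c(0, 0, 0), 700)),
      .gf_types(1L, 0.9, 700, FALSE))
  )
}

#' Random abstract lattice-graph fixture
#'
#' Generates a random quotient graph with `n_types` interface types for
#' oracle testing. `mode = "free"` draws unconstrained translation vectors
#' in `{-1,0,1}^3` (rule-4 violations occur naturally); `mode = "closed"`
#' forces all translations to zero, making every subset pass the
#' closed-symmetry rule by construction.
#'
#' @param n_types Number of interface types (each gets >= 1 edge).
#' @param seed RNG seed; the same spec and seed give an identical graph.
#' @param n_chains Number of chains (default: drawn in 2..4).
#' @param n_entities Number of entities (default: drawn in 1..2).
#' @param mode `"free"` or `"closed"`.
#' @return A `quotient_graph` with per-type probabilities filled.
#' @export
random_graph_fixture <- function(n_types, seed, n_chains = NULL,
                                 n_entities = NULL,
                                 mode = c("free", "closed")) {
  mode <- match.arg(mode)
  .with_seed(seed, {
    if (is.null(n_chains)) n_chains <- sample(2:4, 1)
    if (is.null(n_entities)) n_entities <- sample(1:2, 1)
    n_entities <- min(n_entities, n_chains)
    chains <- LETTERS[seq_len(n_chains)]
    # every entity represented at least once
    entity <- c(seq_len(n_entities),
                sample(seq_len(n_entities), n_chains - n_entities,
                       replace = TRUE))
    nodes <- .gf_nodes(chains, rep(1, n_chains), entity)
    rows <- list()
    iface <- 0L
    for (t in seq_len(n_types)) {
      for (k in seq_len(sample(1:2, 1))) {
        iface <- iface + 1L
        src <- sample(n_chains, 1)
        dst <- sample(n_chains, 1)
        if (mode == "closed" && src == dst && n_chains > 1)
          dst <- src %% n_chains + 1L   # keep closed graphs loop-free
        h <- if (mode == "closed") c(0L, 0L, 0L) else
          sample(c(-1L, 0L, 0L, 0L, 1L), 3, replace = TRUE)
        if (src == dst && all(h == 0L)) h[1] <- 1L  # no self-contact at 0
        ce <- .canon_edge(src, dst, h, nodes)
        rows[[iface]] <- data.frame(
          src = ce$src, dst = ce$dst, iface = iface, type = t,
          hx = ce$h[1], hy = ce$h[2], hz = ce$h[3],
          area = 1000 - 50 * t + round(stats::runif(1, 0, 10), 1))
      }
    }
    edges <- do.call(rbind, rows)
    types <- .gf_types(seq_len(n_types),
                       round(stats::runif(n_types, 0.05, 0.95), 3),
                       vapply(seq_len(n_types), function(t)
                         mean(edges$area[edges$type == t]), numeric(1)),
                       FALSE)
    quotient_graph(nodes, edges, types)
  })
}

## ---- geometric fixtures ---------------------------------------------------

# rigid pseudo-atom cloud: grid in the y-z plane at fixed x, one residue
# per atom (resname determines the entity sequence)
.blob_chain <- function(chain_id, entity_id, x, y0, z0, resname = "ALA",
                        n = 3, spacing = 2) {
  ys <- y0 + spacing * (seq_len(n) - (n + 1) / 2)
  zs <- z0 + spacing * (seq_len(n) - (n + 1) / 2)
  g <- expand.grid(y = ys, z = zs)
  k <- nrow(g)
  list(chain_id = chain_id, entity_id = entity_id,
       xyz = cbind(x = rep(x, k), y = g$y, z = g$z),
       resno = seq_len(k), resname = rep(resname, k),
       atom = rep("CA", k), elem = rep("X", k),
       radius = rep(1.9, k),
       sequence = paste(rep(.AA3TO1[resname], k), collapse = ""),
       is_protein = TRUE)
}

.line_chain <- function(chain_id, entity_id, xs, y, z, resname = "ALA") {
  k <- length(xs)
  list(chain_id = chain_id, entity_id = entity_id,
       xyz = cbind(x = xs, y = rep(y, k), z = rep(z, k)),
       resno = seq_len(k), resname = rep(resname, k),
       atom = rep("CA", k), elem = rep("X", k),
       radius = rep(1.9, k),
       sequence = paste(rep(.AA3TO1[resname], k), collapse = ""),
       is_protein = TRUE)
}

#' Canned geometric crystal fixtures
#'
#' Minimal synthetic crystals whose end-to-end pipeline output matches the
#' corresponding abstract graph fixture:
#' \describe{
#'   \item{c2_dimer}{space group P2; one pseudo-chain straddling the
#'     crystallographic 2-fold, giving one isologous interface type.}
#'   \item{fiber}{P1 with a short a axis; the chain touches its own +a
#'     translate (one heterologous self-contact type).}
#'   \item{heterodimer_ab}{P1; two pseudo-chains of different sequence in
#'     contact (one inter-entity type).}
#' }
#'
#' @param name Template name.
#' @param path Optional path: when given, the crystal is written as mmCIF.
#' @param clash_tol Minimum allowed inter-chain atom distance (error
#'   below; default 2 Angstrom).
#' @return An `xtal_structure` (invisibly when `path` is given).
#' @export
crystal_fixture <- function(name = c("c2_dimer", "fiber", "heterodimer_ab"),
                            path = NULL, clash_tol = 2) {
  name <- match.arg(name)
  s <- switch(name,
    c2_dimer = structure(list(
      cell = crystal_cell(40, 30, 40),
      ops = space_group_operators("P 2"),
      chains = list(A = .blob_chain("A", 1L, x = 2.5, y0 = 10, z0 = 0)),
      space_group = "P 2", pdb_id = "c2fix"), class = "xtal_structure"),
    fiber = structure(list(
      cell = crystal_cell(10, 30, 30),
      ops = space_group_operators("P 1"),
      chains = list(A = .line_chain("A", 1L, xs = c(2, 5, 8), y = 15,
                                    z = 15)),
      space_group = "P 1", pdb_id = "fibfix"), class = "xtal_structure"),
    heterodimer_ab = structure(list(
      cell = crystal_cell(30, 30, 30),
      ops = space_group_operators("P 1"),
      chains = list(
        A = .blob_chain("A", 1L, x = 10, y0 = 14, z0 = 14, "ALA"),
        B = .blob_chain("B", 2L, x = 15, y0 = 14, z0 = 14, "GLY")),
      space_group = "P 1", pdb_id = "abfix"), class = "xtal_structure")
  )
  .check_clashes(s, clash_tol)
  if (!is.null(path)) {
    write_mmcif(s, path, data_name = name)
    return(invisible(s))
  }
  s
}

# error when symmetry-related chains overlap
.check_clashes <- function(s, clash_tol) {
  chains <- protein_chains(s)
  ids <- names(chains)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (ia in seq_along(ids)) for (ib in seq(ia, length(ids))) {
    for (g in seq_along(s$ops)) for (si in seq_len(nrow(shifts))) {
      t <- as.integer(shifts[si, ])
      if (ia == ib && g == 1L && all(t == 0L)) next
      b <- apply_operator(chains[[ib]], s$ops[[g]], t, s$cell)
      if (min(.cross_dist(chains[[ia]]$xyz, b$xyz)) < clash_tol)
        stop("fixture chains clash: ", ids[ia], " vs ", ids[ib],
             " (op ", g, ", shift ", paste(t, collapse = ","), ")")
    }
  }
  invisible(s)
}

## ---- synthetic alignments -------------------------------------------------

#' Synthetic multiple sequence alignment for an entity
#'
#' Builds an alignment whose per-column entropy is controlled: conserved
#' columns hold a single residue class across all rows; variable columns
#' draw residues uniformly from all six classes. The query (first row) is
#' ungapped, mapping 1:1 onto entity residues.
#'
#' @param length Query length.
#' @param n_seqs Number of rows (default 20).
#' @param conserved Integer positions painted conserved (entropy 0).
#' @param seed RNG seed.
#' @param entity_id Entity label.
#' @return An `entity_alignment`.
#' @export
synthetic_alignment <- function(length, n_seqs = 20, conserved = integer(0),
                                seed = 1, entity_id = NA_integer_) {
  reps <- c("A", "D", "F", "G", "K", "N")  # one residue per reduced class
  .with_seed(seed, {
    cols <- lapply(seq_len(length), function(j) {
      if (j %in% conserved) rep(reps[1 + (j %% 6)], n_seqs)
      else sample(reps, n_seqs, replace = TRUE)
    })
    mat <- do.call(cbind, cols)
    seqs <- apply(mat, 1, paste, collapse = "")
    entity_alignment(seqs, query = 1, entity_id = entity_id)
  })
}
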