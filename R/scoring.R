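# Probabilistic scoring of superassemblies.
#
# Engagement of an interface type is a binary event with probability p_i
# (the mean of its member interface probabilities). Treating types as
# independent, a superassembly s = (s_1..s_n) has raw probability
#
#   P(s) = prod_i [ p_i if s_i else (1 - p_i) ]
#
# deliberately per *type*, not per interface instance: an instance-level
# product would bias scores towards high-order cyclic assemblies. Invalid
# combinations carry probability 0, so the raw mass over valid
# superassemblies can be below one; normalization redistributes it.
# Superassemblies differing only by induced interfaces (same multiset of
# assembly stoichiometries) are merged, reporting the most-engaged member
# with the group's total probability.

#' Mean probability of an interface type
#'
#' @param type An `interface_type` (with `members`).
#' @param iface_p Named numeric vector of per-interface probabilities
#'   (names = interface ids).
#' @return The arithmetic mean of the member probabilities.
#' @export
type_probability <- function(type, iface_p) {
  pv <- iface_p[as.character(type$members)]
  if (any(is.na(pv)))
    stop("unscored member interfaces: ",
         paste(type$members[is.na(pv)], collapse = ", "))
  mean(pv)
}

#' Attach interface-type probabilities to a lattice graph
#'
#' Fills `g$types$p` from per-interface scores (averaged per type) or from
#' an explicit override keyed by type id or interface id.
#'
#' @param g A `quotient_graph`.
#' @param scores Data frame from [score_interfaces()] (columns
#'   `interfaceId`, `p`), or `NULL`.
#' @param override Optional named list/vector: `list(typeId = p)` entries
#'   keyed `"type:<id>"` or plainly by type id; interface-keyed entries
#'   `"iface:<id>"` override single members before averaging.
#' @return The graph with `types$p` filled.
#' @export
assign_type_probabilities <- function(g, scores = NULL, override = NULL) {
  iface_p <- NULL
  if (!is.null(scores))
    iface_p <- stats::setNames(scores$p, as.character(scores$interfaceId))
  ov <- as.list(override)
  if (!is.null(iface_p) && length(ov) > 0) {
    ik <- grep("^iface:", names(ov), value = TRUE)
    for (k in ik) iface_p[sub("^iface:", "", k)] <- as.numeric(ov[[k]])
  }
  for (i in seq_len(nrow(g$types))) {
    tp <- g$types$type[i]
    key <- as.character(tp)
    if (!is.null(ov[[paste0("type:", key)]])) {
      g$types$p[i] <- as.numeric(ov[[paste0("type:", key)]])
    } else if (!is.null(ov[[key]])) {
      g$types$p[i] <- as.numeric(ov[[key]])
    } else if (!is.null(iface_p)) {
      members <- unique(g$edges$iface[g$edges$type == tp])
      pv <- iface_p[as.character(members)]
      if (any(is.na(pv)))
        stop("unscored member interfaces for type ", tp, ": ",
             paste(members[is.na(pv)], collapse = ", "))
      g$types$p[i] <- mean(pv)
    }
  }
  g
}

#' Raw probability of a superassembly (independence product)
#'
#' @param engaged Integer vector of engaged type ids.
#' @param p Named numeric vector of type probabilities (names = type ids).
#' @return `prod_i p_i^[engaged] (1-p_i)^[not engaged]`.
#' @export
superassembly_probability <- function(engaged, p) {
  stopifnot(all(p >= 0 & p <= 1))
  ids <- as.integer(names(p))
  prod(ifelse(ids %in% engaged, p, 1 - p))
}

#' Normalize probabilities over the valid superassemblies
#'
#' Divides each raw probability by the total valid mass, redistributing
#' the probability of interface events that lead to invalid assemblies.
#'
#' @param raw Numeric vector of raw probabilities.
#' @return Probabilities summing to exactly 1.
#' @export
normalize_over_valid <- function(raw) {
  tot <- sum(raw)
  if (tot <= 0)
    stop("all valid superassemblies have zero probability mass; ",
         "interface probabilities are inconsistent (all 0/1)")
  raw / tot
}

#' Interface types that are induced in an engaged set
#'
#' A type is induced when disengaging it leaves every assembly of the
#' superassembly connected (it is topologically redundant).
#'
#' @param g A `quotient_graph`.
#' @param engaged Integer vector of engaged type ids.
#' @return Integer vector of induced type ids.
#' @export
induced_types <- function(g, engaged) {
  if (length(engaged) == 0) return(integer(0))
  full <- .engaged_analysis(g, engaged_edges(g, engaged))
  Filter(function(t) {
    red <- .engaged_analysis(g, engaged_edges(g, setdiff(engaged, t)))
    red$valid && identical(red$comp, full$comp)
  }, engaged)
}

.stoich_key <- function(sa) {
  paste(sort(vapply(sa$assemblies, function(a)
    paste(a$stoich, collapse = ","), character(1))), collapse = ";")
}

#' Score, normalize and merge the valid superassemblies of a graph
#'
#' @param g A `quotient_graph` with `types$p` filled.
#' @param superassemblies Output of [enumerate_superassemblies()].
#' @return List of predictions sorted by decreasing probability, each:
#'   `engaged`, `assemblies`, `prob` (normalized merged probability),
#'   `prob_raw` (raw probability of the representative), `merged_from`
#'   (engaged sets of the group), `rank`, `oligomer_size` (largest
#'   assembly), `stoich` (representative formula strings), `point_groups`.
#'   Probabilities over predictions sum to 1.
#' @export
score_superassemblies <- function(g, superassemblies) {
  if (any(is.na(g$types$p)))
    stop("interface-type probabilities missing; call ",
         "assign_type_probabilities() first")
  p <- stats::setNames(g$types$p, as.character(g$types$type))
  raw <- vapply(superassemblies, function(sa)
    superassembly_probability(sa$engaged, p), numeric(1))
  prob <- normalize_over_valid(raw)
  keys <- vapply(superassemblies, .stoich_key, character(1))
  groups <- split(seq_along(superassemblies), keys)
  preds <- lapply(groups, function(idx) {
    # representative: most engaged types, then larger raw probability,
    # then lexicographically smallest type set
    ord <- order(-vapply(idx, function(i)
      length(superassemblies[[i]]$engaged), integer(1)),
      -raw[idx],
      vapply(idx, function(i) paste(sprintf("%06d",
        superassemblies[[i]]$engaged), collapse = ","), character(1)))
    rep_i <- idx[ord[1]]
    sa <- superassemblies[[rep_i]]
    list(engaged = sa$engaged,
         assemblies = sa$assemblies,
         prob = sum(prob[idx]),
         prob_raw = raw[rep_i],
         merged_from = lapply(idx, function(i)
           superassemblies[[i]]$engaged),
         oligomer_size = max(vapply(sa$assemblies, function(a) a$size,
                                    integer(1))),
         stoich = unique(vapply(sa$assemblies, function(a)
           format_stoich(a$stoich), character(1))))
  })
  # rank by probability; ties prefer the smaller (more stable) oligomer
  ord <- order(-vapply(preds, function(x) x$prob, numeric(1)),
               vapply(preds, function(x) x$oligomer_size, integer(1)))
  preds <- preds[ord]
  for (i in seq_along(preds)) preds[[i]]$rank <- i
  unname(preds)
}

#' Predict the biological assembly of a lattice graph
#'
#' Runs enumeration, scoring, normalization and induced-interface merging,
#' and returns the ranked predictions with point-group labels attached.
#'
#' @param g A `quotient_graph` with `types$p` filled.
#' @param s Optional `xtal_structure` for geometric point-group detection;
#'   without it a topological heuristic labels the groups.
#' @param max_types Enumeration guard.
#' @param tol Point-group RMSD tolerance (Angstrom).
#' @return List: `predictions` (ranked, probabilities summing to 1),
#'   `prediction` (rank 1), `superassemblies` (all valid, unmerged).
#' @export
predict_assembly <- function(g, s = NULL, max_types = 32, tol = 2.0) {
  sas <- enumerate_superassemblies(g, max_types)
  preds <- score_superassemblies(g, sas)
  preds <- lapply(preds, function(pr) {
    pr$assemblies <- lapply(pr$assemblies, function(a) {
      a$point_group <- detect_point_group(a, s, tol)
      a
    })
    pr$point_groups <- unique(vapply(pr$assemblies, function(a)
      a$point_group, character(1)))
    pr
  })
  list(predictions = preds, prediction = preds[[1]],
       superassemblies = sas)
}
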