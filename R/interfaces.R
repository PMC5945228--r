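# Pairwise interface detection in the crystal lattice.
#
# Every contact between an asymmetric-unit chain (under the identity) and
# any chain image (any operator, cell shifts within a 3x3x3 neighbourhood)
# is detected once, in a canonical orientation, measured by buried surface
# area and clustered into interface types by the similarity of entity-level
# residue-residue contact sets.

#' An interface node reference
#'
#' Identifies one side of a crystal contact: a chain of the asymmetric unit
#' under a space-group operator and an integer cell shift.
#'
#' @param chain Chain identifier.
#' @param op_id 1-based operator index.
#' @param shift Integer 3-vector of Miller-index offsets.
#' @return A plain list used as a node reference.
#' @export
node_ref <- function(chain, op_id = 1L, shift = c(0L, 0L, 0L)) {
  list(chain = chain, op_id = as.integer(op_id), shift = as.integer(shift))
}

.node_key <- function(ref) {
  paste(ref$chain, ref$op_id, paste(ref$shift, collapse = ","), sep = "|")
}

#' Find all pairwise interfaces in a crystal
#'
#' Scans every asymmetric-unit chain against all symmetry images of all
#' chains within one cell of neighbourhood, keeps contacts with any
#' atom-atom distance below `cutoff`, and measures each by buried surface
#' area; contacts burying less than `min_area` are discarded as
#' micro-contacts. Each physical contact orbit is returned exactly once in
#' canonical orientation. Interfaces are numbered by non-increasing area.
#'
#' @param s An `xtal_structure`.
#' @param cutoff Atom-atom candidate distance in Angstrom (default 5.5).
#' @param min_area Minimum buried surface area to keep an interface
#'   (default 35 Angstrom^2).
#' @param contact_cutoff Heavy-atom distance defining residue-residue
#'   contact pairs used for clustering (default 5.5).
#' @param n_points Shrake-Rupley sphere points per atom.
#' @return List of `interface` objects: fields `id`, `chain_a`, `chain_b`
#'   (node references), `area`, `contacts` (2-column residue-pair matrix),
#'   `detail` (per-residue asa/bsa tables), `isologous`, `type_id` (filled
#'   by [cluster_interface_types()]).
#' @export
find_interfaces <- function(s, cutoff = 5.5, min_area = 35,
                            contact_cutoff = 5.5, n_points = 960) {
  chains <- protein_chains(s)
  if (length(chains) == 0) stop("structure has no protein chains")
  ids <- names(chains)
  shifts <- as.matrix(expand.grid(h = -1:1, k = -1:1, l = -1:1))
  found <- list()
  seen <- character(0)
  for (ia in seq_along(ids)) {
    a <- chains[[ia]]
    for (ib in seq(ia, length(ids))) {
      b0 <- chains[[ib]]
      for (g in seq_along(s$ops)) {
        for (si in seq_len(nrow(shifts))) {
          t <- as.integer(shifts[si, ])
          if (ia == ib && g == 1L && all(t == 0L)) next
          if (ia == ib) {
            # dedup the two orientations of a self-entity contact orbit
            flip <- .flip_image(s$ops, g, t)
            key_f <- paste(ids[ia], flip$op_id,
                           paste(flip$shift, collapse = ","), sep = "|")
            key_g <- paste(ids[ia], g, paste(t, collapse = ","), sep = "|")
            if (.img_lt(flip$op_id, flip$shift, g, t)) next
            if (key_g %in% seen) next
            seen <- c(seen, key_f, key_g)
          }
          b <- apply_operator(b0, s$ops[[g]], t, s$cell)
          if (!.chains_near(a, b, cutoff)) next
          dmat <- .cross_dist(a$xyz, b$xyz)
          if (min(dmat) >= cutoff) next
          bsa <- buried_surface_area(a, b, n_points = n_points)
          if (as.numeric(bsa) < min_area) next
          cp <- which(dmat < contact_cutoff, arr.ind = TRUE)
          contacts <- unique(cbind(a$resno[cp[, 1]], b$resno[cp[, 2]]))
          iface <- structure(list(
            id = NA_integer_,
            chain_a = node_ref(ids[ia], 1L, c(0L, 0L, 0L)),
            chain_b = node_ref(ids[ib], g, t),
            entity_a = a$entity_id,
            entity_b = b0$entity_id,
            area = as.numeric(bsa),
            contacts = contacts,
            detail = list(bsa_a = attr(bsa, "bsa_a"),
                          bsa_b = attr(bsa, "bsa_b")),
            isologous = NA,
            type_id = NA_integer_
          ), class = "interface")
          iface$isologous <- detect_isologous(iface)
          found[[length(found) + 1L]] <- iface
        }
      }
    }
  }
  # number by non-increasing area; ties broken lexicographically
  if (length(found) == 0) return(found)
  keyfun <- function(f) paste(f$chain_a$chain, f$chain_b$chain,
                              f$chain_b$op_id,
                              paste(f$chain_b$shift, collapse = ","))
  ord <- order(-vapply(found, function(f) f$area, numeric(1)),
               vapply(found, keyfun, character(1)))
  found <- found[ord]
  for (i in seq_along(found)) found[[i]]$id <- i
  found
}

# image (op,shift) ordering used for canonical orientation of self contacts
.img_lt <- function(op1, s1, op2, s2) {
  if (op1 != op2) return(op1 < op2)
  for (i in 1:3) if (s1[i] != s2[i]) return(s1[i] < s2[i])
  FALSE
}

# the reversed representation of a same-chain contact:
# {(c,1,0),(c,g,t)} == {(c,1,0),(c,m,t')} with (m,t') the inverse image
.flip_image <- function(ops, g, t) {
  gi <- symop_invert(symop(NA, ops[[g]]$rot, ops[[g]]$trans + t))
  symop_match(gi, ops)
}

.chains_near <- function(a, b, cutoff) {
  ca <- colMeans(a$xyz); cb <- colMeans(b$xyz)
  ra <- sqrt(max(rowSums((a$xyz - matrix(ca, nrow(a$xyz), 3, byrow = TRUE))^2)))
  rb <- sqrt(max(rowSums((b$xyz - matrix(cb, nrow(b$xyz), 3, byrow = TRUE))^2)))
  sqrt(sum((ca - cb)^2)) <= ra + rb + cutoff
}

.cross_dist <- function(x, y) {
  xx <- rowSums(x^2); yy <- rowSums(y^2)
  d2 <- outer(xx, yy, "+") - 2 * (x %*% t(y))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' @export
print.interface <- function(x, ...) {
  cat(sprintf("<interface %s> %s -- %s_op%d@(%s)  %.1f A^2%s%s\n",
              ifelse(is.na(x$id), "?", x$id),
              x$chain_a$chain, x$chain_b$chain, x$chain_b$op_id,
              paste(x$chain_b$shift, collapse = ","), x$area,
              if (isTRUE(x$isologous)) " isologous" else "",
              if (is.na(x$type_id)) "" else paste0(" type ", x$type_id)))
  invisible(x)
}

#' Materialize the two placed chains of an interface
#'
#' @param s The `xtal_structure`.
#' @param iface An `interface`.
#' @return List with elements `a` and `b`: chain records with transformed
#'   coordinates.
#' @export
interface_chains <- function(s, iface) {
  a <- s$chains[[iface$chain_a$chain]]
  a <- apply_operator(a, s$ops[[iface$chain_a$op_id]], iface$chain_a$shift,
                      s$cell)
  b <- s$chains[[iface$chain_b$chain]]
  b <- apply_operator(b, s$ops[[iface$chain_b$op_id]], iface$chain_b$shift,
                      s$cell)
  list(a = a, b = b)
}

#' Core / rim / surface classification of residues at an interface
#'
#' A residue is part of the interface when it buries any area; it is *core*
#' when its burial fraction `bsa/asa` reaches `core_cutoff` (default 0.95),
#' *rim* otherwise. Non-interface residues with relative accessibility
#' (against the residue extracted in isolation) above `surface_cutoff` are
#' *surface*; the remainder are *interior*.
#'
#' @param s The `xtal_structure`.
#' @param iface An `interface` from [find_interfaces()].
#' @param core_cutoff Burial fraction for core residues (default 0.95).
#' @param surface_cutoff Relative ASA separating surface from interior
#'   (default 0.05).
#' @param n_points Shrake-Rupley sphere points.
#' @return List with data frames `a` and `b`: columns `resno`, `asa`,
#'   `ref`, `bsa`, `label` in `{core, rim, surface, interior}`.
#' @export
classify_core_rim <- function(s, iface, core_cutoff = 0.95,
                              surface_cutoff = 0.05, n_points = 960) {
  ch <- interface_chains(s, iface)
  side <- function(chain, bsa_res) {
    ra <- .chain_residue_asa(chain, n_points = n_points, reference = TRUE)
    res <- names(ra$asa)
    bsa <- bsa_res[res]
    bsa[is.na(bsa)] <- 0
    label <- ifelse(bsa > 0,
                    ifelse(ra$asa > 0 & bsa / ra$asa >= core_cutoff,
                           "core", "rim"),
                    ifelse(ra$asa / ra$ref >= surface_cutoff,
                           "surface", "interior"))
    data.frame(resno = as.integer(res), asa = unname(ra$asa),
               ref = unname(ra$ref), bsa = unname(bsa),
               label = unname(label), stringsAsFactors = FALSE)
  }
  list(a = side(ch$a, iface$detail$bsa_a),
       b = side(ch$b, iface$detail$bsa_b))
}

.contact_keys <- function(contacts, flip = FALSE) {
  if (is.null(contacts) || nrow(contacts) == 0) return(character(0))
  if (flip) paste(contacts[, 2], contacts[, 1]) else
    paste(contacts[, 1], contacts[, 2])
}

.jaccard <- function(k1, k2) {
  u <- length(union(k1, k2))
  if (u == 0) return(1)
  length(intersect(k1, k2)) / u
}

#' Is an interface isologous?
#'
#' An isologous (face-to-face) contact joins two copies of one entity
#' through the same surface patch on both sides, as across a 2-fold axis.
#' Detected as near-symmetry of the residue-residue contact set under
#' transposition: `J(C, C^T) >= tol`.
#'
#' @param iface An `interface`.
#' @param tol Transpose-Jaccard threshold (default 0.8).
#' @return `TRUE`/`FALSE`; always `FALSE` across different entities.
#' @export
detect_isologous <- function(iface, tol = 0.8) {
  if (!identical(iface$entity_a, iface$entity_b)) return(FALSE)
  k <- .contact_keys(iface$contacts)
  kt <- .contact_keys(iface$contacts, flip = TRUE)
  .jaccard(k, kt) >= tol
}

#' Cluster interfaces into interface types
#'
#' Two interfaces belong to one type when they join the same unordered
#' entity pair and their entity-level residue-residue contact sets are
#' similar (Jaccard >= `sim_cutoff`); clustering is single linkage. For
#' same-entity pairs both orientations of the contact set are tried and the
#' better one counts. Types are numbered by descending mean area.
#'
#' @param interfaces List of `interface` objects.
#' @param sim_cutoff Jaccard similarity threshold (default 0.3).
#' @return List of `interface_type` objects: `type_id`, `members`
#'   (interface ids), `mean_area`, `isologous`, `entities`, `p`
#'   (probability, `NA` until scored). The input interfaces' `type_id`
#'   fields are filled in the returned attribute `interfaces`.
#' @export
cluster_interface_types <- function(interfaces, sim_cutoff = 0.3) {
  n <- length(interfaces)
  if (n == 0) return(structure(list(), interfaces = interfaces))
  epair <- vapply(interfaces, function(f)
    paste(sort(c(f$entity_a, f$entity_b)), collapse = "-"), character(1))
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sim <- function(f1, f2) {
    k1 <- .contact_keys(f1$contacts)
    j <- .jaccard(k1, .contact_keys(f2$contacts))
    if (identical(f1$entity_a, f1$entity_b))
      j <- max(j, .jaccard(k1, .contact_keys(f2$contacts, flip = TRUE)))
    j
  }
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (epair[i] != epair[j]) next
      if (sim(interfaces[[i]], interfaces[[j]]) >= sim_cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  mean_area <- vapply(groups, function(g)
    mean(vapply(interfaces[g], function(f) f$area, numeric(1))), numeric(1))
  ord <- order(-mean_area)
  types <- vector("list", length(groups))
  for (k in seq_along(ord)) {
    g <- groups[[ord[k]]]
    for (i in g) interfaces[[i]]$type_id <- k
    types[[k]] <- structure(list(
      type_id = k,
      members = vapply(interfaces[g], function(f) as.integer(f$id),
                       integer(1)),
      mean_area = unname(mean_area[ord[k]]),
      isologous = any(vapply(interfaces[g], function(f)
        isTRUE(f$isologous), logical(1))),
      entities = sort(c(interfaces[[g[1]]]$entity_a,
                        interfaces[[g[1]]]$entity_b)),
      p = NA_real_
    ), class = "interface_type")
  }
  structure(types, interfaces = interfaces)
}

#' Tabulate interfaces
#'
#' @param interfaces List of `interface` objects.
#' @return A data frame: id, typeId, chains, operator, shift, area,
#'   isologous.
#' @export
interfaces_table <- function(interfaces) {
  if (length(interfaces) == 0)
    return(data.frame(id = integer(0), typeId = integer(0),
                      chainA = character(0), chainB = character(0),
                      opB = integer(0), shift = character(0),
                      area = numeric(0), isologous = logical(0)))
  do.call(rbind, lapply(interfaces, function(f) data.frame(
    id = f$id, typeId = f$type_id,
    chainA = f$chain_a$chain, chainB = f$chain_b$chain,
    opB = f$chain_b$op_id,
    shift = paste(f$chain_b$shift, collapse = ","),
    area = f$area, isologous = f$isologous,
    stringsAsFactors = FALSE)))
}

#' Write the interface table as TSV
#'
#' @param interfaces List of `interface` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interfaces_tsv <- function(interfaces, path) {
  utils::write.table(interfaces_table(interfaces), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
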