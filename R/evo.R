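# Evolutionary interface scoring.
#
# Sequence entropy is computed over a 6-letter reduced amino-acid alphabet
# (Mirny classes): {ACILMV} {DE} {FHWY} {GP} {KR} {NQST}. The core-surface
# score cs is a Z-score of the mean entropy of the interface-core residues
# against a null distribution obtained by repeatedly sampling the same
# number of residues from the protein surface. Together with the geometry
# score gm (number of interface-core residues) a trained logistic model
# gives the probability that an interface is biologically relevant:
#
#   p(gm, cs) = 1 / (1 + exp(-(-3.9 + 0.31*gm - 2.1*cs)))

.REDUCED_CLASSES <- list(
  "1" = c("A", "C", "I", "L", "M", "V"),
  "2" = c("D", "E"),
  "3" = c("F", "H", "W", "Y"),
  "4" = c("G", "P"),
  "5" = c("K", "R"),
  "6" = c("N", "Q", "S", "T")
)

.REDUCED_MAP <- local({
  m <- character(0)
  for (cl in names(.REDUCED_CLASSES)) m[.REDUCED_CLASSES[[cl]]] <- cl
  m
})

# run code with a private, seeded RNG stream, leaving the caller's RNG alone
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Reduce an amino-acid sequence to the 6-class alphabet
#'
#' Maps each residue onto one of six physico-chemical classes; `X`, gaps
#' (`-`, `.`) and any unrecognised letter map to the null class `"0"`,
#' which is excluded from entropy counts.
#'
#' @param seq Amino-acid string (one-letter codes) or character vector of
#'   single letters.
#' @return Character vector of class symbols `"1"`..`"6"` (or `"0"`), one
#'   per input residue.
#' @export
reduce_alphabet <- function(seq) {
  chars <- if (length(seq) == 1 && nchar(seq[1]) > 1)
    strsplit(seq, "")[[1]] else as.character(seq)
  out <- .REDUCED_MAP[toupper(chars)]
  out[is.na(out)] <- "0"
  unname(out)
}

#' Shannon entropy of an alignment column over the reduced alphabet
#'
#' @param column Character vector of residues (one-letter codes or reduced
#'   class symbols); gaps and null-class symbols are excluded from counts.
#' @param base Logarithm base; the default `exp(1)` gives nats.
#' @return Entropy (0 for an empty or single-class column).
#' @export
column_entropy <- function(column, base = exp(1)) {
  cl <- if (all(column %in% c(as.character(0:6))))
    column else reduce_alphabet(column)
  cl <- cl[cl != "0"]
  if (length(cl) == 0) return(0)
  p <- table(cl) / length(cl)
  -sum(p * log(p)) / log(base)
}

#' Build an entity alignment object
#'
#' Wraps a multiple sequence alignment of homologs of one entity. The
#' query row's ungapped positions map 1:1 onto the entity's residues.
#'
#' @param seqs Character vector of aligned sequences (equal length, gaps
#'   `-`).
#' @param query Index of the query row (default 1).
#' @param entity_id Entity label.
#' @return An `entity_alignment`: fields `seqs`, `query`, `entity_id`,
#'   `entropies` (per query residue position, 1-based ungapped numbering).
#' @export
entity_alignment <- function(seqs, query = 1, entity_id = NA_integer_) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1)
    stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  qrow <- mat[query, ]
  qpos <- which(!(qrow %in% c("-", ".")))
  ent <- vapply(qpos, function(j) column_entropy(mat[, j]), numeric(1))
  names(ent) <- as.character(seq_along(qpos))
  structure(list(seqs = seqs, query = query, entity_id = entity_id,
                 entropies = ent, n_rows = length(seqs)),
            class = "entity_alignment")
}

#' Read a FASTA multiple sequence alignment for one entity
#'
#' @param path FASTA file of aligned homolog sequences; the first record is
#'   the query unless `query` names another row.
#' @param query Row index of the query sequence.
#' @param entity_id Entity label.
#' @return An `entity_alignment`.
#' @export
read_alignment <- function(path, query = 1, entity_id = NA_integer_) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    aa <- Biostrings::readAAStringSet(path)
    seqs <- as.character(aa)
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^>", lines)
    idx <- cumsum(hdr)
    seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste, character(1),
                   collapse = "")
  }
  entity_alignment(unname(seqs), query = query, entity_id = entity_id)
}

#' Core-surface evolutionary Z-score
#'
#' Compares the mean sequence entropy of the `m` interface-core residues
#' against a null distribution built by sampling `m` residues (without
#' replacement, per draw) from the protein surface `n_samples` times:
#' `cs = (mean(core) - mean(sample means)) / sd(sample means)`.
#'
#' @param core_entropies Entropies of the core residues (length `m >= 1`).
#' @param surface_entropies Entropies of the surface residue pool.
#' @param n_samples Number of Monte-Carlo draws (default 10000).
#' @param seed RNG seed for the sampling (default 42); the caller's RNG
#'   state is untouched.
#' @return List `cs` (the Z-score), `flag` (`"ok"`, `"degenerate"` when the
#'   null has zero spread, or `"unscorable"` when `m = 0` or the surface
#'   pool is smaller than `m`).
#' @export
core_surface_zscore <- function(core_entropies, surface_entropies,
                                n_samples = 10000, seed = 42) {
  m <- length(core_entropies)
  if (m == 0 || length(surface_entropies) < m)
    return(list(cs = NA_real_, flag = "unscorable"))
  means <- .with_seed(seed, {
    vapply(seq_len(n_samples), function(i)
      mean(sample(surface_entropies, m, replace = FALSE)), numeric(1))
  })
  sdv <- stats::sd(means)
  if (!is.finite(sdv) || sdv < 1e-12)
    return(list(cs = 0, flag = "degenerate"))
  list(cs = (mean(core_entropies) - mean(means)) / sdv, flag = "ok")
}

#' Geometry score of an interface
#'
#' The number of interface-core residues summed over both sides.
#'
#' @param core_labels Output of [classify_core_rim()].
#' @return Non-negative integer `gm`.
#' @export
geometry_score <- function(core_labels) {
  sum(core_labels$a$label == "core") + sum(core_labels$b$label == "core")
}

#' Logistic probability that an interface is biologically relevant
#'
#' Evaluates the trained logistic model
#' `p = 1 / (1 + exp(-(-3.9 + 0.31*gm - 2.1*cs)))`.
#'
#' @param gm Geometry score (core residue count).
#' @param cs Core-surface Z-score (use 0 when unavailable).
#' @return Probability in (0, 1). Vectorized over `gm`/`cs`.
#' @export
interface_probability <- function(gm, cs) {
  1 / (1 + exp(-(-3.9 + 0.31 * gm - 2.1 * cs)))
}

#' Score all interfaces of a structure
#'
#' Computes `gm`, `cs` and `p` for each interface. When no alignment is
#' available for an entity, `cs` falls back to 0 and the interface is
#' flagged `gm_only` (low confidence). For same-protein sides the Z-score
#' is computed per side against that side's own surface pool and averaged
#' over scorable sides.
#'
#' @param s The `xtal_structure`.
#' @param interfaces List of `interface` objects.
#' @param alignments Optional named list of `entity_alignment`, keyed by
#'   entity id (as character).
#' @param n_samples Monte-Carlo draws for `cs`.
#' @param seed RNG seed for the sampling.
#' @param core_cutoff,surface_cutoff Passed to [classify_core_rim()].
#' @param n_points Shrake-Rupley sphere points.
#' @return Data frame: `interfaceId`, `gm`, `cs`, `p`, `flag`.
#' @export
score_interfaces <- function(s, interfaces, alignments = NULL,
                             n_samples = 10000, seed = 42,
                             core_cutoff = 0.95, surface_cutoff = 0.05,
                             n_points = 960) {
  rows <- lapply(interfaces, function(f) {
    lab <- classify_core_rim(s, f, core_cutoff, surface_cutoff, n_points)
    gm <- geometry_score(lab)
    side_cs <- function(tab, entity) {
      aln <- alignments[[as.character(entity)]]
      if (is.null(aln)) return(NULL)
      # alignment positions are 1:L in chain residue order (tab is sorted)
      ent <- aln$entropies
      core_e <- ent[as.character(which(tab$label == "core"))]
      surf_e <- ent[as.character(which(tab$label == "surface"))]
      core_e <- core_e[!is.na(core_e)]
      surf_e <- surf_e[!is.na(surf_e)]
      core_surface_zscore(core_e, surf_e, n_samples, seed)
    }
    flag <- "ok"
    if (is.null(alignments)) {
      cs <- 0; flag <- "gm_only"
    } else {
      za <- side_cs(lab$a, f$entity_a)
      zb <- side_cs(lab$b, f$entity_b)
      vals <- c(if (!is.null(za) && za$flag == "ok") za$cs,
                if (!is.null(zb) && zb$flag == "ok") zb$cs)
      if (length(vals) > 0) {
        cs <- mean(vals)
      } else if ((!is.null(za) && za$flag == "degenerate") ||
                 (!is.null(zb) && zb$flag == "degenerate")) {
        cs <- 0; flag <- "degenerate"
      } else {
        cs <- 0; flag <- "gm_only"
      }
    }
    data.frame(interfaceId = f$id, gm = gm, cs = cs,
               p = interface_probability(gm, cs), flag = flag,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
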