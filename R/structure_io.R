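# Crystal structure input/output.
#
# A minimal, dependency-free reader for the records the lattice-graph method
# needs: unit cell, space-group operators, polymer chains with heavy-atom
# coordinates, and entity assignments. Standard mmCIF and PDB dialects are
# supported. Waters and ligands are dropped; nucleic-acid chains are kept
# but flagged (the classifier targets protein-protein interfaces);
# alternate locations resolve to the highest-occupancy conformer; hydrogens
# are ignored.

.AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O", UNK = "X"
)
.WATERS <- c("HOH", "WAT", "DOD", "H2O")
.NUCLEIC <- c("A", "C", "G", "U", "I", "DA", "DC", "DG", "DT", "DI", "DU")

.ATOM_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                 SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, X = 1.90)

.atom_radius <- function(elem) {
  r <- .ATOM_RADII[toupper(elem)]
  r[is.na(r)] <- 1.70
  unname(r)
}

#' Read a crystal structure
#'
#' Parses an mmCIF or PDB file and returns the unit cell, space-group
#' operator list and polymer chains. Entities are taken from file metadata
#' (mmCIF `label_entity_id`) when available, otherwise chains with identical
#' sequences are grouped into one entity.
#'
#' @param path Path to the structure file.
#' @param format One of `"auto"`, `"mmcif"`, `"pdb"`.
#' @return An object of class `xtal_structure`: fields `cell` (`xtal_cell`),
#'   `ops` (list of `symop`), `chains` (named list of chain records),
#'   `space_group` (symbol, possibly `NA`), `pdb_id`.
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (ext %in% c("cif", "mmcif") || grepl("^data_", first))
      "mmcif" else "pdb"
  }
  s <- if (format == "mmcif") .read_mmcif(path) else .read_pdb(path)
  .validate_structure(s, path)
}

.validate_structure <- function(s, path) {
  if (is.null(s$cell))
    stop("missing unit cell record (_cell / CRYST1) in ", path)
  if (is.null(s$ops) || length(s$ops) == 0)
    stop("missing space-group record (_symmetry / CRYST1) in ", path)
  if (length(s$chains) == 0)
    stop("no polymer chains found in ", path)
  s
}

.finish_structure <- function(cell, ops, atoms, entity_map = NULL,
                              pdb_id = NA_character_, space_group = NA_character_) {
  chains <- .atoms_to_chains(atoms, entity_map)
  structure(list(cell = cell, ops = ops, chains = chains,
                 space_group = space_group, pdb_id = pdb_id),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  np <- sum(vapply(x$chains, function(ch) ch$is_protein, logical(1)))
  cat(sprintf("<xtal_structure%s> %d chains (%d protein), %d operators, SG %s\n",
              if (is.na(x$pdb_id)) "" else paste0(" ", x$pdb_id),
              length(x$chains), np, length(x$ops),
              if (is.na(x$space_group)) "?" else x$space_group))
  invisible(x)
}

# atoms: data.frame(chain, resno, resname, atom, elem, alt, occ, x, y, z, entity)
.atoms_to_chains <- function(atoms, entity_map = NULL) {
  if (nrow(atoms) == 0) return(list())
  atoms <- atoms[!(toupper(atoms$elem) %in% c("H", "D")), , drop = FALSE]
  atoms <- atoms[!(atoms$resname %in% .WATERS), , drop = FALSE]
  # highest-occupancy alternate conformer per (chain, residue, atom name)
  key <- paste(atoms$chain, atoms$resno, atoms$atom, sep = "\r")
  atoms <- atoms[order(key, -atoms$occ), , drop = FALSE]
  atoms <- atoms[!duplicated(paste(atoms$chain, atoms$resno, atoms$atom,
                                   sep = "\r")), , drop = FALSE]
  chains <- list()
  for (cid in unique(atoms$chain)) {
    a <- atoms[atoms$chain == cid, , drop = FALSE]
    a <- a[order(a$resno), , drop = FALSE]
    resnames <- a$resname[!duplicated(a$resno)]
    n_aa <- sum(resnames %in% names(.AA3TO1))
    n_nuc <- sum(resnames %in% .NUCLEIC)
    if (n_aa == 0 && n_nuc == 0) next  # ligand-only "chain"
    seq1 <- paste(ifelse(is.na(.AA3TO1[resnames]), "X", .AA3TO1[resnames]),
                  collapse = "")
    ent <- if (!is.null(entity_map) && cid %in% names(entity_map))
      entity_map[[cid]] else NA_integer_
    chains[[cid]] <- list(
      chain_id = cid,
      entity_id = ent,
      xyz = cbind(x = a$x, y = a$y, z = a$z),
      resno = a$resno,
      resname = a$resname,
      atom = a$atom,
      elem = a$elem,
      radius = .atom_radius(a$elem),
      sequence = seq1,
      is_protein = n_aa >= n_nuc
    )
  }
  # entity fallback: exact sequence identity
  ents <- vapply(chains, function(ch) ch$entity_id, integer(1))
  if (any(is.na(ents))) {
    seqs <- vapply(chains, function(ch) ch$sequence, character(1))
    chains <- lapply(chains, function(ch) {
      ch$entity_id <- match(ch$sequence, unique(seqs))
      ch
    })
  }
  chains
}

## ---- mmCIF ----------------------------------------------------------------

# Minimal CIF tokenizer: returns list(items = named character,
# loops = list of data.frames with character columns).
.parse_cif <- function(lines) {
  toks_re <- "('[^']*')|(\"[^\"]*\")|([^[:space:]]+)"
  items <- list(); loops <- list()
  i <- 1L; n <- length(lines)
  read_multiline <- function(i) {
    # lines[i] starts with ';' — gather until closing ';'
    val <- sub("^;", "", lines[i]); i <- i + 1L
    buf <- character(0)
    while (i <= n && !grepl("^;", lines[i])) { buf <- c(buf, lines[i]); i <- i + 1L }
    list(value = paste(c(val, buf), collapse = "\n"), next_i = i + 1L)
  }
  tokenize <- function(line) {
    m <- regmatches(line, gregexpr(toks_re, line))[[1]]
    m <- m[!grepl("^#", m)]
    gsub("^['\"]|['\"]$", "", m)
  }
  while (i <= n) {
    line <- lines[i]
    if (grepl("^\\s*#", line) || !nzchar(trimws(line)) || grepl("^data_", line)) {
      i <- i + 1L; next
    }
    if (grepl("^\\s*loop_", line)) {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && grepl("^\\s*_", lines[i])) {
        tags <- c(tags, trimws(lines[i])); i <- i + 1L
      }
      vals <- character(0)
      while (i <= n && !grepl("^\\s*(_|loop_|data_|#)", lines[i])) {
        if (grepl("^;", lines[i])) {
          ml <- read_multiline(i); vals <- c(vals, ml$value); i <- ml$next_i
        } else {
          vals <- c(vals, tokenize(lines[i])); i <- i + 1L
        }
      }
      if (length(tags) > 0 && length(vals) %% length(tags) == 0 &&
          length(vals) > 0) {
        mat <- matrix(vals, ncol = length(tags), byrow = TRUE)
        df <- as.data.frame(mat, stringsAsFactors = FALSE)
        names(df) <- tags
        loops[[length(loops) + 1L]] <- df
      }
      next
    }
    if (grepl("^\\s*_", line)) {
      toks <- tokenize(line)
      tag <- toks[1]
      if (length(toks) >= 2) {
        items[[tag]] <- paste(toks[-1], collapse = " ")
        i <- i + 1L
      } else if (i + 1L <= n && grepl("^;", lines[i + 1L])) {
        ml <- read_multiline(i + 1L)
        items[[tag]] <- ml$value; i <- ml$next_i
      } else if (i + 1L <= n) {
        items[[tag]] <- gsub("^['\"]|['\"]$", "", trimws(lines[i + 1L]))
        i <- i + 2L
      } else i <- i + 1L
      next
    }
    i <- i + 1L
  }
  list(items = items, loops = loops)
}

.cif_loop <- function(cif, category) {
  for (df in cif$loops) {
    if (any(startsWith(names(df), paste0(category, ".")))) return(df)
  }
  # single-row categories appear as plain items
  keys <- names(cif$items)
  if (is.null(keys)) return(NULL)
  hit <- keys[startsWith(keys, paste0(category, "."))]
  if (length(hit) > 0) {
    df <- as.data.frame(cif$items[hit], stringsAsFactors = FALSE,
                        optional = TRUE)
    names(df) <- hit
    return(df)
  }
  NULL
}

.cif_col <- function(df, ...) {
  for (nm in c(...)) if (nm %in% names(df)) return(df[[nm]])
  NULL
}

.read_mmcif <- function(path) {
  cif <- .parse_cif(readLines(path, warn = FALSE))
  it <- cif$items
  cell <- NULL
  if (!is.null(it[["_cell.length_a"]])) {
    cell <- crystal_cell(as.numeric(it[["_cell.length_a"]]),
                         as.numeric(it[["_cell.length_b"]]),
                         as.numeric(it[["_cell.length_c"]]),
                         as.numeric(it[["_cell.angle_alpha"]]),
                         as.numeric(it[["_cell.angle_beta"]]),
                         as.numeric(it[["_cell.angle_gamma"]]))
  }
  sg <- it[["_symmetry.space_group_name_H-M"]]
  if (is.null(sg)) sg <- it[["_space_group.name_H-M_alt"]]
  ops <- NULL
  symloop <- .cif_loop(cif, "_symmetry_equiv")
  if (is.null(symloop)) symloop <- .cif_loop(cif, "_space_group_symop")
  if (!is.null(symloop)) {
    trips <- .cif_col(symloop, "_symmetry_equiv.pos_as_xyz",
                      "_symmetry_equiv_pos_as_xyz",
                      "_space_group_symop.operation_xyz")
    if (!is.null(trips)) ops <- operators_from_triplets(trips)
  }
  if (is.null(ops) && !is.null(sg)) ops <- space_group_operators(sg)
  atoms_df <- .cif_loop(cif, "_atom_site")
  if (is.null(atoms_df)) stop("no _atom_site loop in ", path)
  grp <- .cif_col(atoms_df, "_atom_site.group_PDB")
  keep <- if (is.null(grp)) rep(TRUE, nrow(atoms_df)) else grp != "HETATM" |
    .cif_col(atoms_df, "_atom_site.label_comp_id") %in% names(.AA3TO1)
  atoms_df <- atoms_df[keep, , drop = FALSE]
  chain <- .cif_col(atoms_df, "_atom_site.auth_asym_id",
                    "_atom_site.label_asym_id")
  resno <- .cif_col(atoms_df, "_atom_site.auth_seq_id",
                    "_atom_site.label_seq_id")
  occ <- .cif_col(atoms_df, "_atom_site.occupancy")
  alt <- .cif_col(atoms_df, "_atom_site.label_alt_id")
  atoms <- data.frame(
    chain = chain,
    resno = as.integer(resno),
    resname = .cif_col(atoms_df, "_atom_site.label_comp_id"),
    atom = .cif_col(atoms_df, "_atom_site.label_atom_id"),
    elem = .cif_col(atoms_df, "_atom_site.type_symbol"),
    alt = if (is.null(alt)) "." else alt,
    occ = if (is.null(occ)) 1 else as.numeric(occ),
    x = as.numeric(.cif_col(atoms_df, "_atom_site.Cartn_x")),
    y = as.numeric(.cif_col(atoms_df, "_atom_site.Cartn_y")),
    z = as.numeric(.cif_col(atoms_df, "_atom_site.Cartn_z")),
    stringsAsFactors = FALSE
  )
  entity <- .cif_col(atoms_df, "_atom_site.label_entity_id")
  entity_map <- NULL
  if (!is.null(entity) && !all(entity %in% c(".", "?"))) {
    em <- tapply(entity, atoms$chain, function(v) v[1])
    entity_map <- as.list(as.integer(factor(em, levels = unique(em))))
    names(entity_map) <- names(em)
  }
  pdb_id <- NA_character_
  dl <- grep("^data_", readLines(path, n = 1L, warn = FALSE), value = TRUE)
  if (length(dl) == 1) pdb_id <- sub("^data_", "", dl)
  .finish_structure(cell, ops, atoms, entity_map, pdb_id,
                    if (is.null(sg)) NA_character_ else sg)
}

## ---- PDB ------------------------------------------------------------------

.read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cryst <- grep("^CRYST1", lines, value = TRUE)
  cell <- NULL; ops <- NULL; sg <- NA_character_
  if (length(cryst) >= 1) {
    l <- cryst[1]
    cell <- crystal_cell(as.numeric(substr(l, 7, 15)),
                         as.numeric(substr(l, 16, 24)),
                         as.numeric(substr(l, 25, 33)),
                         as.numeric(substr(l, 34, 40)),
                         as.numeric(substr(l, 41, 47)),
                         as.numeric(substr(l, 48, 54)))
    sg <- trimws(substr(l, 56, 66))
    if (nzchar(sg)) ops <- space_group_operators(sg) else sg <- NA_character_
  }
  al <- lines[grepl("^(ATOM  |HETATM)", lines)]
  if (length(al) == 0) al <- character(0)
  # stop at first ENDMDL: use model 1 only
  endmdl <- grep("^ENDMDL", lines)
  if (length(endmdl) > 0) {
    first_end <- endmdl[1]
    al <- lines[seq_len(first_end - 1)]
    al <- al[grepl("^(ATOM  |HETATM)", al)]
  }
  atoms <- data.frame(
    chain = substr(al, 22, 22),
    resno = as.integer(substr(al, 23, 26)),
    resname = trimws(substr(al, 18, 20)),
    atom = trimws(substr(al, 13, 16)),
    elem = trimws(substr(al, 77, 78)),
    alt = substr(al, 17, 17),
    occ = suppressWarnings(as.numeric(substr(al, 55, 60))),
    x = as.numeric(substr(al, 31, 38)),
    y = as.numeric(substr(al, 39, 46)),
    z = as.numeric(substr(al, 47, 54)),
    stringsAsFactors = FALSE
  )
  atoms$occ[is.na(atoms$occ)] <- 1
  noelem <- !nzchar(atoms$elem)
  atoms$elem[noelem] <- substr(gsub("[^A-Za-z].*$", "", atoms$atom[noelem]), 1, 1)
  pdb_id <- NA_character_
  hdr <- grep("^HEADER", lines, value = TRUE)
  if (length(hdr) >= 1 && nchar(hdr[1]) >= 66)
    pdb_id <- trimws(substr(hdr[1], 63, 66))
  if (!nzchar(pdb_id) || length(pdb_id) == 0) pdb_id <- NA_character_
  .finish_structure(cell, ops, atoms, NULL, pdb_id, sg)
}

## ---- transforms -----------------------------------------------------------

#' Apply a symmetry operator plus lattice shift to a chain
#'
#' Transforms a chain's Cartesian coordinates by
#' `orth(R * frac(x) + t + shift)`: the operator acts in the fractional
#' basis and `shift` is an integer Miller-index offset selecting the image
#' cell.
#'
#' @param chain A chain record from an `xtal_structure`.
#' @param op A `symop`.
#' @param cell_shift Integer 3-vector of unit-cell offsets.
#' @param cell The `xtal_cell`.
#' @return The transformed chain record (copy).
#' @export
apply_operator <- function(chain, op, cell_shift, cell) {
  fr <- fractionalize(cell, chain$xyz)
  fr <- t(op$rot %*% t(fr)) +
    matrix(op$trans + cell_shift, nrow(fr), 3, byrow = TRUE)
  chain$xyz <- orthogonalize(cell, fr)
  chain
}

#' List protein chains of a structure
#'
#' @param s An `xtal_structure`.
#' @return Named list of protein chain records.
#' @export
protein_chains <- function(s) {
  Filter(function(ch) ch$is_protein, s$chains)
}

## ---- mmCIF writing --------------------------------------------------------

#' Write a structure as minimal mmCIF
#'
#' Emits `_cell`, a `_symmetry_equiv` operator loop (so the file is
#' self-describing for any space group) and an `_atom_site` loop. Used by
#' the fixture generator and for exporting assembly coordinates.
#'
#' @param s An `xtal_structure`.
#' @param path Output file path.
#' @param data_name Value for the leading `data_` block.
#' @return `path`, invisibly.
#' @export
write_mmcif <- function(s, path, data_name = "qslattice") {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("data_%s", data_name)
  w("#")
  w("_cell.length_a    %.4f", s$cell$a)
  w("_cell.length_b    %.4f", s$cell$b)
  w("_cell.length_c    %.4f", s$cell$c)
  w("_cell.angle_alpha %.4f", s$cell$alpha)
  w("_cell.angle_beta  %.4f", s$cell$beta)
  w("_cell.angle_gamma %.4f", s$cell$gamma)
  if (!is.na(s$space_group))
    w("_symmetry.space_group_name_H-M '%s'", s$space_group)
  w("#")
  w("loop_")
  w("_symmetry_equiv.id")
  w("_symmetry_equiv.pos_as_xyz")
  for (op in s$ops) w("%d '%s'", op$op_id, symop_to_xyz(op))
  w("#")
  w("loop_")
  w("_atom_site.group_PDB")
  w("_atom_site.id")
  w("_atom_site.type_symbol")
  w("_atom_site.label_atom_id")
  w("_atom_site.label_alt_id")
  w("_atom_site.label_comp_id")
  w("_atom_site.label_asym_id")
  w("_atom_site.label_entity_id")
  w("_atom_site.auth_seq_id")
  w("_atom_site.Cartn_x")
  w("_atom_site.Cartn_y")
  w("_atom_site.Cartn_z")
  w("_atom_site.occupancy")
  w("_atom_site.auth_asym_id")
  serial <- 0L
  for (ch in s$chains) {
    for (i in seq_len(nrow(ch$xyz))) {
      serial <- serial + 1L
      w("ATOM %d %s %s . %s %s %d %d %.3f %.3f %.3f 1.00 %s",
        serial, ch$elem[i], ch$atom[i], ch$resname[i], ch$chain_id,
        ch$entity_id, ch$resno[i],
        ch$xyz[i, 1], ch$xyz[i, 2], ch$xyz[i, 3], ch$chain_id)
    }
  }
  w("#")
  invisible(path)
}
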