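# End-to-end pipeline: structure -> interfaces -> scores -> lattice graph
# -> enumeration -> prediction -> report files.

#' Assemble a run configuration
#'
#' Collects all tunable thresholds with their defaults. The configuration
#' is echoed into every report for provenance.
#'
#' @param input Path to an mmCIF/PDB structure or a lattice-graph JSON
#'   file (the abstract entry point bypassing geometry).
#' @param format `"auto"`, `"mmcif"`, `"pdb"` or `"graph"`.
#' @param out_dir Output directory for report files (created if needed).
#' @param msa_dir Optional directory of per-entity FASTA alignments named
#'   `entity_<id>.fasta`.
#' @param probabilities Optional path to a JSON probability override
#'   (`{"type:<id>": p}` / `{"<typeId>": p}` / `{"iface:<id>": p}`), or a
#'   named list of the same shape.
#' @param cutoff Atom-atom candidate distance (Angstrom).
#' @param min_area Minimum interface area (Angstrom^2).
#' @param contact_cutoff Residue contact distance for clustering.
#' @param sim_cutoff Jaccard threshold for interface-type clustering.
#' @param core_cutoff Burial fraction defining core residues.
#' @param surface_cutoff Relative ASA defining surface residues.
#' @param n_points Shrake-Rupley sphere points per atom.
#' @param n_samples Monte-Carlo draws for the core-surface Z-score.
#' @param seed RNG seed for the Z-score sampling.
#' @param max_types Enumeration guard.
#' @param pg_tol Point-group RMSD tolerance (Angstrom).
#' @param graphml Also write the lattice graph as GraphML.
#' @param assembly_out Optional path for the predicted assembly as mmCIF.
#' @return A `run_config` list.
#' @export
run_config <- function(input, format = "auto", out_dir = NULL,
                       msa_dir = NULL, probabilities = NULL,
                       cutoff = 5.5, min_area = 35, contact_cutoff = 5.5,
                       sim_cutoff = 0.3, core_cutoff = 0.95,
                       surface_cutoff = 0.05, n_points = 960,
                       n_samples = 10000, seed = 42, max_types = 32,
                       pg_tol = 2.0, graphml = FALSE, assembly_out = NULL) {
  stopifnot(cutoff > 0, min_area >= 0, sim_cutoff >= 0, sim_cutoff <= 1,
            core_cutoff > 0, core_cutoff <= 1,
            surface_cutoff >= 0, surface_cutoff < 1,
            n_points >= 100, n_samples >= 1, max_types >= 1)
  structure(list(input = input, format = format, out_dir = out_dir,
                 msa_dir = msa_dir, probabilities = probabilities,
                 cutoff = cutoff, min_area = min_area,
                 contact_cutoff = contact_cutoff, sim_cutoff = sim_cutoff,
                 core_cutoff = core_cutoff, surface_cutoff = surface_cutoff,
                 n_points = n_points, n_samples = n_samples, seed = seed,
                 max_types = max_types, pg_tol = pg_tol, graphml = graphml,
                 assembly_out = assembly_out),
            class = "run_config")
}

.load_probability_override <- function(probabilities) {
  if (is.null(probabilities)) return(NULL)
  if (is.character(probabilities) && length(probabilities) == 1) {
    if (!file.exists(probabilities))
      stop("probability file not found: ", probabilities)
    return(jsonlite::read_json(probabilities, simplifyVector = TRUE))
  }
  probabilities
}

.load_alignments <- function(msa_dir, entities) {
  if (is.null(msa_dir)) return(NULL)
  out <- list()
  for (e in entities) {
    f <- file.path(msa_dir, paste0("entity_", e, ".fasta"))
    if (file.exists(f))
      out[[as.character(e)]] <- read_alignment(f, entity_id = e)
  }
  if (length(out) == 0) NULL else out
}

#' Run the full assembly-prediction pipeline
#'
#' Executes read -> interface detection -> scoring -> lattice graph ->
#' enumeration -> superassembly scoring -> prediction, and writes the JSON
#' report plus the interface TSV into `out_dir` (when given). Lattice-graph
#' JSON inputs skip the geometric stages and score from the probabilities
#' carried in the file.
#'
#' @param config A `run_config` (or the `input` path, using defaults).
#' @return Invisibly, a list: `report` (the report structure), `structure`
#'   (or `NULL` for graph input), `graph`, `result`
#'   (from [predict_assembly()]), `files` (paths written).
#' @export
run_full <- function(config) {
  if (is.character(config)) config <- run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!file.exists(config$input))
    stop("input file not found: ", config$input)
  fmt <- config$format
  if (fmt == "auto" && tolower(tools::file_ext(config$input)) == "json")
    fmt <- "graph"
  ov <- .load_probability_override(config$probabilities)
  s <- NULL
  interfaces <- list()
  if (fmt == "graph") {
    g <- read_graph_json(config$input)
    g <- assign_type_probabilities(g, scores = NULL, override = ov)
    pdb_id <- sub("\\.[^.]*$", "", basename(config$input))
  } else {
    s <- read_structure(config$input,
                        if (fmt == "auto") "auto" else fmt)
    interfaces <- find_interfaces(s, cutoff = config$cutoff,
                                  min_area = config$min_area,
                                  contact_cutoff = config$contact_cutoff,
                                  n_points = config$n_points)
    if (length(interfaces) == 0)
      stop("no interfaces above the area floor; crystal is all monomers")
    types <- cluster_interface_types(interfaces,
                                     sim_cutoff = config$sim_cutoff)
    interfaces <- attr(types, "interfaces")
    ents <- unique(vapply(protein_chains(s), function(ch) ch$entity_id,
                          integer(1)))
    alns <- .load_alignments(config$msa_dir, ents)
    scores <- score_interfaces(s, interfaces, alignments = alns,
                               n_samples = config$n_samples,
                               seed = config$seed,
                               core_cutoff = config$core_cutoff,
                               surface_cutoff = config$surface_cutoff,
                               n_points = config$n_points)
    g <- build_lattice_graph(s, interfaces, types)
    g <- assign_type_probabilities(g, scores = scores, override = ov)
    pdb_id <- if (!is.na(s$pdb_id)) s$pdb_id else
      sub("\\.[^.]*$", "", basename(config$input))
  }
  if (any(is.na(g$types$p)))
    stop("interface-type probabilities unavailable; supply an MSA ",
         "directory or a probability override")
  res <- predict_assembly(g, s = s, max_types = config$max_types,
                          tol = config$pg_tol)
  report <- .build_report(pdb_id, config, g, res)
  files <- character(0)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    jf <- file.path(config$out_dir, paste0(pdb_id, ".report.json"))
    jsonlite::write_json(report, jf, auto_unbox = TRUE, digits = 12,
                         null = "null", pretty = TRUE)
    files <- c(files, jf)
    if (length(interfaces) > 0) {
      tf <- file.path(config$out_dir, paste0(pdb_id, ".interfaces.tsv"))
      write_interfaces_tsv(interfaces, tf)
      files <- c(files, tf)
    }
    if (isTRUE(config$graphml)) {
      gf <- file.path(config$out_dir, paste0(pdb_id, ".graphml"))
      export_graph(g, gf, "graphml")
      files <- c(files, gf)
    }
  }
  if (!is.null(config$assembly_out) && !is.null(s)) {
    write_assembly_mmcif(s, res$prediction$assemblies[[
      which.max(vapply(res$prediction$assemblies, function(a) a$size,
                       integer(1)))]], config$assembly_out)
    files <- c(files, config$assembly_out)
  }
  invisible(list(report = report, structure = s, graph = g, result = res,
                 files = files))
}

.build_report <- function(pdb_id, config, g, res) {
  sa_entry <- function(sa, raw = NA, norm = NA) {
    list(engaged = I(sa$engaged),
         assemblies = lapply(sa$assemblies, function(a) list(
           stoichiometry = format_stoich(a$stoich),
           size = a$size,
           pointGroup = if (is.na(a$point_group)) NULL else a$point_group)))
  }
  p <- stats::setNames(g$types$p, as.character(g$types$type))
  raw <- vapply(res$superassemblies, function(sa)
    superassembly_probability(sa$engaged, p), numeric(1))
  norm <- normalize_over_valid(raw)
  valid_list <- lapply(seq_along(res$superassemblies), function(i) {
    e <- sa_entry(res$superassemblies[[i]])
    e$probRaw <- raw[i]
    e$probNormalized <- norm[i]
    e
  })
  pred_entry <- function(pr) list(
    engaged = I(pr$engaged),
    probability = pr$prob,
    rank = pr$rank,
    oligomerSize = pr$oligomer_size,
    stoichiometry = I(pr$stoich),
    pointGroups = I(pr$point_groups),
    mergedFrom = lapply(pr$merged_from, I),
    confidence = pr$prob)
  cfg <- unclass(config)
  cfg$probabilities <- if (is.character(cfg$probabilities))
    cfg$probabilities else if (!is.null(cfg$probabilities)) "(inline)" else NULL
  list(pdbId = pdb_id,
       config = cfg[!vapply(cfg, is.null, logical(1))],
       interfaceTypes = lapply(seq_len(nrow(g$types)), function(i) list(
         typeId = g$types$type[i],
         p = g$types$p[i],
         meanArea = g$types$mean_area[i],
         isologous = if (is.na(g$types$isologous[i])) NULL else
           g$types$isologous[i])),
       validSuperassemblies = valid_list,
       predictions = lapply(res$predictions, pred_entry),
       prediction = pred_entry(res$prediction))
}

#' Write an assembly's coordinates as mmCIF
#'
#' Materializes every member chain of an assembly at its crystal position
#' (operator plus cell offset) and writes the result as a P1 mmCIF file.
#'
#' @param s The source `xtal_structure`.
#' @param a An `assembly`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_mmcif <- function(s, a, path) {
  chains <- list()
  for (i in seq_len(nrow(a$members))) {
    m <- a$members[i, ]
    ch <- apply_operator(s$chains[[m$chain]], s$ops[[m$op]],
                         c(m$ox, m$oy, m$oz), s$cell)
    ch$chain_id <- paste0(m$chain, "_", m$op)
    chains[[ch$chain_id]] <- ch
  }
  out <- structure(list(cell = s$cell, ops = space_group_operators("P 1"),
                        chains = chains, space_group = "P 1",
                        pdb_id = s$pdb_id), class = "xtal_structure")
  write_mmcif(out, path, data_name = "assembly")
  invisible(path)
}
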