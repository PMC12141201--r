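## End-to-end orchestration of the two phases.
##
## Phase 1: pockets -> generated ligands -> docking energies (the
## ligand-generation table). Phase 2: surrogate assignment -> multi-objective
## ranking -> top-k docking -> screen report. Intermediates are first-class
## files (pool SDF, assignment CSV, ranked CSV, report JSON) so each stage
## is independently re-runnable; with the mock engine and a fixed seed the
## whole pipeline is bit-reproducible (timestamps live only in the log).

#' Assemble and validate a pipeline configuration
#'
#' @param protein Path to the target protein PDB.
#' @param library Path to the drug library (SMILES or SDF by extension).
#' @param output_dir Directory for intermediates and the report.
#' @param pocket_dir Fpocket-style output directory to parse; `NULL` only if
#'   `provider` supplies pocket-tagged ligands some other way.
#' @param approved Optional path to a JSON/text file of approved drug ids
#'   (enables evaluation), or a character vector of ids.
#' @param encoder Similarity mode: `"tanimoto"`, `"morgan_cosine"`,
#'   `"graph_cosine"`.
#' @param ranking_mode `"ss_plus_be"`, `"ss"` or `"be"`.
#' @param normalization `"mean_square"` or `"rms"`.
#' @param top_m Pockets to use (default all).
#' @param n_ligands Ligands generated per pocket (default 20).
#' @param engine `"mock"` or `"external:<binary>"`.
#' @param top_k Docking policy: `"until_first_hit"` or a fixed integer.
#' @param seed Pipeline seed, recorded in every output.
#' @param margin,min_edge Docking-box construction (angstroms).
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(protein, library, output_dir,
                            pocket_dir = NULL, approved = NULL,
                            encoder = "tanimoto", ranking_mode = "ss_plus_be",
                            normalization = "mean_square",
                            top_m = Inf, n_ligands = 20, engine = "mock",
                            top_k = "until_first_hit", seed = 1,
                            margin = 4, min_edge = 10) {
  if (!encoder %in% c("tanimoto", "morgan_cosine", "graph_cosine"))
    vs_stop("input", "invalid value for field 'encoder': %s", encoder)
  if (!ranking_mode %in% c("ss_plus_be", "ss", "be"))
    vs_stop("input", "invalid value for field 'ranking_mode': %s", ranking_mode)
  if (!normalization %in% c("mean_square", "rms"))
    vs_stop("input", "invalid value for field 'normalization': %s", normalization)
  if (!(identical(top_k, "until_first_hit") || is_count(top_k, 1)))
    vs_stop("input", "invalid value for field 'top_k': %s", format(top_k))
  if (!(engine == "mock" || grepl("^external:", engine)))
    vs_stop("input", "invalid value for field 'engine': %s", engine)
  cfg <- list(protein = protein, library = library, output_dir = output_dir,
              pocket_dir = pocket_dir, approved = approved, encoder = encoder,
              ranking_mode = ranking_mode, normalization = normalization,
              top_m = top_m, n_ligands = n_ligands, engine = engine,
              top_k = top_k, seed = seed, margin = margin, min_edge = min_edge)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

config_hash <- function(cfg) {
  keys <- setdiff(sort(names(cfg)), c("hash", "output_dir"))
  sprintf("%08x", vs_hash_string(paste(
    vapply(keys, function(k) paste0(k, "=", paste(format(cfg[[k]]), collapse = ",")),
           character(1)), collapse = ";")))
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror [pipeline_config()] arguments; `overrides` (e.g. CLI flags)
#' take precedence.
#'
#' @param path YAML file path.
#' @param overrides Named list overriding file values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!requireNamespace("yaml", quietly = TRUE))
    vs_stop("environment", "the 'yaml' package is required to read config files")
  if (!file.exists(path)) vs_stop("input", "no such config file: %s", path)
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

build_engine <- function(cfg, oracle = NULL) {
  if (cfg$engine == "mock") mock_engine(cfg$seed, similarity_oracle = oracle)
  else vina_engine(sub("^external:", "", cfg$engine))
}

#' Phase 1: generate pocket-conditioned ligands and dock them
#'
#' For each selected pocket, generates ligands and docks each into its
#' pocket's box, producing the ligand-generation table. The pool is
#' persisted as SDF (with pocket and energy data fields) and CSV.
#'
#' @param cfg A `pipeline_config`.
#' @param provider Optional `ligand_provider`; defaults to the seeded
#'   synthetic provider.
#' @return List of `generated_ligand` objects with binding energies set.
#' @export
run_phase1 <- function(cfg, provider = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  protein <- read_protein(cfg$protein)
  if (is.null(cfg$pocket_dir))
    vs_stop("pocket", "no pocket directory configured and auto-detection is not available")
  pockets <- select_pockets(parse_fpocket_output(cfg$pocket_dir), cfg$top_m)
  provider <- provider %||% synthetic_provider(derive_seed(cfg$seed, "provider"))
  engine <- build_engine(cfg)
  pool <- list()
  for (p in pockets) {
    ligs <- generate_ligands(p, cfg$n_ligands, cfg$seed, provider)
    box <- pocket_to_dockbox(p, cfg$margin, cfg$min_edge)
    for (g in ligs) {
      g$binding_energy <- dock(protein, g$molecule, box, engine)$binding_energy
      pool[[length(pool) + 1]] <- g
    }
    vs_log("phase1", "pocket %d: %d ligands generated and docked",
           p$pocket_id, length(ligs))
  }
  write_pool_sdf(pool, file.path(cfg$output_dir, "pool.sdf"))
  utils::write.csv(pool_table(pool),
                   file.path(cfg$output_dir, "ligand_generation.csv"),
                   row.names = FALSE)
  pool
}

pool_table <- function(pool) {
  data.frame(
    ligand_id = vapply(pool, function(g) g$molecule$id, character(1)),
    smiles = vapply(pool, function(g) g$molecule$smiles, character(1)),
    pocket_id = vapply(pool, `[[`, integer(1), "pocket_id"),
    binding_energy = vapply(pool, `[[`, numeric(1), "binding_energy"),
    generator_tag = vapply(pool, `[[`, character(1), "generator_tag"),
    stringsAsFactors = FALSE)
}

write_pool_sdf <- function(pool, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (g in pool) {
    m <- g$molecule
    writeLines(molfile_from_graph(m$atoms, m$bonds, m$coords3d, title = m$id), con)
    writeLines(c("> <vscreenr_id>", m$id, "",
                 "> <vscreenr_pocket>", as.character(g$pocket_id), "",
                 "> <vscreenr_energy>",
                 sprintf("%.6f", g$binding_energy %||% NA_real_), "",
                 "$$$$"), con)
  }
  invisible(length(pool))
}

#' Read a generated-ligand pool from an SDF written by [run_phase1()]
#'
#' @param path SDF path with `<vscreenr_pocket>` / `<vscreenr_energy>` data
#'   fields (missing fields give pocket 1 / NA energy).
#' @return List of `generated_ligand` objects.
#' @export
read_pool_sdf <- function(path) {
  mols <- read_molecules(path, "sdf", source = "generated")
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  starts <- c(1L, utils::head(ends, -1) + 1L)
  field <- function(rec, tag) {
    k <- grep(paste0("^>\\s*<", tag, ">"), rec)
    if (length(k) > 0 && k[1] < length(rec)) trimws(rec[k[1] + 1]) else NA_character_
  }
  meta <- lapply(seq_along(ends), function(k) {
    rec <- lines[starts[k]:ends[k]]
    list(id = field(rec, "vscreenr_id") %||% NA_character_,
         pocket = suppressWarnings(as.integer(field(rec, "vscreenr_pocket"))),
         energy = suppressWarnings(as.numeric(field(rec, "vscreenr_energy"))))
  })
  ids <- vapply(meta, function(m) m$id %||% NA_character_, character(1))
  lapply(mols, function(m) {
    k <- match(m$id, ids)
    new_generated_ligand(m,
                         pocket_id = if (!is.na(k) && !is.na(meta[[k]]$pocket))
                           meta[[k]]$pocket else 1L,
                         binding_energy = if (!is.na(k)) meta[[k]]$energy else NA_real_,
                         generator_tag = "sdf")
  })
}

read_approved_ids <- function(approved) {
  if (is.null(approved)) return(character(0))
  if (is.character(approved) && length(approved) == 1 && file.exists(approved)) {
    if (grepl("\\.json$", approved)) {
      obj <- jsonlite::read_json(approved, simplifyVector = TRUE)
      if (is.list(obj) && !is.null(obj$approved_ids)) return(as.character(obj$approved_ids))
      return(as.character(unlist(obj)))
    }
    return(trimws(readLines(approved, warn = FALSE)))
  }
  as.character(approved)
}

#' Phase 2: similarity search, multi-objective ranking, top-k docking
#'
#' @param cfg A `pipeline_config`.
#' @param pool Ligand-generation table from [run_phase1()] (or
#'   [read_pool_sdf()]).
#' @return A `screen_report`; the assignment table, ranked table and report
#'   JSON are persisted under the output directory.
#' @export
run_phase2 <- function(cfg, pool) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- if (grepl("\\.sdf$", cfg$library, ignore.case = TRUE)) "sdf" else "smiles"
  drugs <- read_molecules(cfg$library, fmt, source = "library")
  asg <- assign_surrogates(drugs, pool, mode = cfg$encoder)
  write_assignments(asg, file.path(cfg$output_dir, "assignments.csv"))
  ranked <- rank_candidates(
    fitness_scores(asg, mode = cfg$ranking_mode, normalization = cfg$normalization),
    asg)
  approved <- read_approved_ids(cfg$approved)
  protein <- read_protein(cfg$protein)
  engine <- build_engine(cfg)
  pockets <- if (!is.null(cfg$pocket_dir)) parse_fpocket_output(cfg$pocket_dir)
  else list()
  k_docked <- NA_integer_
  dock_time <- NA_real_
  if (identical(cfg$top_k, "until_first_hit") && length(approved) > 0 &&
      length(pockets) > 0) {
    sim <- simulate_topk_docking(ranked, approved, protein, engine, drugs,
                                 pockets, cfg$margin, cfg$min_edge)
    k_docked <- sim$k
    dock_time <- sim$total_time
  } else if (is_count(cfg$top_k, 1) && length(pockets) > 0) {
    kk <- as.integer(min(cfg$top_k, nrow(ranked)))
    t0 <- proc.time()[["elapsed"]]
    for (r in seq_len(kk)) {
      did <- ranked$drug_id[ranked$rank == r]
      mol <- drugs[[match(did, vapply(drugs, `[[`, character(1), "id"))]]
      pk <- pockets[[match(ranked$pocket_id[ranked$rank == r],
                           vapply(pockets, `[[`, integer(1), "pocket_id"))]]
      tryCatch(dock(protein, mol, pocket_to_dockbox(pk, cfg$margin, cfg$min_edge),
                    engine),
               vs_error = function(e)
                 vs_log("phase2", "docking failed for %s: %s", did,
                        conditionMessage(e)))
    }
    k_docked <- kk
    dock_time <- proc.time()[["elapsed"]] - t0
  }
  report <- new_screen_report(
    target_id = tools::file_path_sans_ext(basename(cfg$protein)),
    ranked = ranked,
    approved_ids = if (length(approved) > 0) approved else "<none>",
    n_library = nrow(ranked) + length(attr(asg, "skipped")),
    k_docked = k_docked, skipped = attr(asg, "skipped"),
    docking_time = dock_time, seed = cfg$seed, config_hash = cfg$hash)
  if (length(approved) == 0) {
    report$first_hit_rank <- NA_integer_
    report$hit_rate_reduction <- NA_real_
  }
  write_screen_report(report,
                      json_path = file.path(cfg$output_dir, "report.json"),
                      csv_path = file.path(cfg$output_dir, "ranked.csv"))
  report
}

#' Run the full two-phase pipeline
#'
#' @param cfg A `pipeline_config`.
#' @param provider Optional phase-1 `ligand_provider`.
#' @param resume Reuse an existing `pool.sdf` under the output directory
#'   instead of re-running phase 1.
#' @return The phase-2 `screen_report`.
#' @export
run_pipeline <- function(cfg, provider = NULL, resume = FALSE) {
  pool_path <- file.path(cfg$output_dir, "pool.sdf")
  pool <- if (resume && file.exists(pool_path)) {
    vs_log("pipeline", "resuming: reusing %s", pool_path)
    read_pool_sdf(pool_path)
  } else run_phase1(cfg, provider)
  run_phase2(cfg, pool)
}
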