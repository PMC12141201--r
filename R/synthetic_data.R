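## Self-contained synthetic screening instances.
##
## A synthetic screen stands in for a real drug-target evaluation set: a
## small protein fixture with pockets, a generated-ligand pool built from
## one scaffold family, a drug library whose planted "approved" actives are
## derived FROM the pool by one or two extra local edits (so they are
## structurally close to the pool — the retrieval direction under test),
## and decoys drawn from an unrelated scaffold family. Mock binding
## energies come from the similarity-aware mock engine, so actives bind
## better on average. Everything is deterministic under the seed. No
## resemblance to any real library's chemical distribution or to binding
## physics is claimed.

## Decoy scaffolds: deliberately unrelated to the pool scaffold family
## (aliphatic and saturated-heterocycle cores, no fused aromatics).
decoy_scaffolds <- function() {
  c("C1CCCCC1N", "CCCCCCC(=O)O", "C1CCOC1CO", "CC(C)CC(C)N",
    "O=C1CCCCC1", "CCOC(=O)CC", "C1CCNCC1", "CCSCC(=O)N")
}

## Deterministic helix-like protein fixture (~200 atoms): a parametric
## alpha-helix backbone with pseudo side-chain atoms, sufficient for parser
## and box-geometry work; no docking realism claimed.
synthetic_protein <- function(n_res = 26) {
  res3 <- c("ALA", "LEU", "SER", "VAL", "THR", "GLY", "ILE", "ASP")
  rows <- list()
  serial <- 0
  for (i in seq_len(n_res)) {
    phi <- i * 100 * pi / 180
    base <- c(2.3 * cos(phi), 2.3 * sin(phi), 1.5 * i)
    offs <- list(N = c(-0.5, 0.8, -0.6), CA = c(0, 0, 0), C = c(1.2, 0.4, 0.4),
                 O = c(1.9, 1.2, 0.1), CB = c(-0.4, -1.2, 0.7),
                 CG = c(-0.9, -2.3, 1.4), CD = c(-1.5, -3.2, 0.8))
    for (nm in names(offs)) {
      serial <- serial + 1
      rows[[serial]] <- data.frame(
        serial = serial, name = nm, resid = res3[(i - 1) %% length(res3) + 1],
        chain = "A", resno = i, insert = "",
        x = base[1] + offs[[nm]][1], y = base[2] + offs[[nm]][2],
        z = base[3] + offs[[nm]][3],
        element = substr(nm, 1, 1), stringsAsFactors = FALSE)
    }
  }
  new_protein("synthetic_helix", do.call(rbind, rows), chains = "A")
}

write_protein_pdb <- function(protein, path) {
  at <- protein$atoms
  lines <- sprintf(
    "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    at$serial, substr(at$name, 1, 3), at$resid, at$chain, at$resno,
    at$x, at$y, at$z, at$element)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

## Two hand-placed pockets near the helix ends, with member atoms taken
## from the protein so the Fpocket-dialect export is parseable and
## consistent with the in-memory pockets.
synthetic_pockets <- function(protein) {
  at <- protein$atoms
  mk <- function(pid, resmin, resmax, score) {
    sel <- at$resno >= resmin & at$resno <= resmax
    xyz <- as.matrix(at[sel, c("x", "y", "z")])
    new_pocket(pid, centroid = colMeans(xyz),
               extent = apply(xyz, 2, max) - apply(xyz, 2, min),
               score = score, n_alpha_spheres = sum(sel),
               member_atom_serials = at$serial[sel])
  }
  list(mk(1L, 1L, 8L, 0.8), mk(2L, 19L, 26L, 0.5))
}

write_fpocket_dir <- function(protein, pockets, dir) {
  out <- file.path(dir, paste0(protein$id, "_out"))
  dir.create(file.path(out, "pockets"), recursive = TRUE, showWarnings = FALSE)
  at <- protein$atoms
  info <- character(0)
  for (p in pockets) {
    sel <- at$serial %in% p$member_atom_serials
    sub <- protein; sub$atoms <- at[sel, , drop = FALSE]
    write_protein_pdb(sub, file.path(out, "pockets",
                                     sprintf("pocket%d_atm.pdb", p$pocket_id)))
    info <- c(info, sprintf("Pocket %d :", p$pocket_id),
              sprintf("\tScore : %.3f", p$score),
              sprintf("\tNumber of Alpha Spheres : %d", p$n_alpha_spheres), "")
  }
  writeLines(info, file.path(out, paste0(protein$id, "_info.txt")))
  invisible(out)
}

#' Build a synthetic screening instance
#'
#' @param seed Instance seed; regeneration with the same seed and parameters
#'   is identical.
#' @param n_decoys Decoy library size (default 1000).
#' @param n_actives Planted approved actives (default 20).
#' @param pool_size Generated-ligand pool size, split across the fixture's
#'   two pockets (default 50).
#' @param active_edits Maximum extra local edits separating an active from
#'   its source pool ligand (default 2).
#' @return A `synthetic_screen`: protein, pockets, pool (with mock binding
#'   energies), library, `approved_ids`, seed and params.
#' @export
make_screen <- function(seed, n_decoys = 1000, n_actives = 20, pool_size = 50,
                        active_edits = 2) {
  if (!is_count(n_decoys, 1) || !is_count(n_actives, 1) ||
      !is_count(pool_size, 1) || !is_count(active_edits, 1))
    vs_stop("parameter", "all screen counts must be integers >= 1")
  protein <- synthetic_protein()
  pockets <- synthetic_pockets(protein)
  provider <- synthetic_provider(derive_seed(seed, "pool"))
  n1 <- ceiling(pool_size / 2)
  pool <- c(generate_ligands(pockets[[1]], n1, seed, provider),
            if (pool_size > n1)
              generate_ligands(pockets[[2]], pool_size - n1, seed, provider))
  ## similarity-aware mock energies: ligands resembling the pool scaffold
  ## family dock better
  scaffold_fps <- lapply(provider$scaffolds, morgan_fingerprint)
  oracle <- function(mol) {
    fp <- morgan_fingerprint(mol)
    max(vapply(scaffold_fps, function(s) tanimoto(fp, s), numeric(1)))
  }
  engine <- mock_engine(seed, similarity_oracle = oracle)
  for (k in seq_along(pool)) {
    pk <- pockets[[match(pool[[k]]$pocket_id,
                         vapply(pockets, `[[`, integer(1), "pocket_id"))]]
    pool[[k]]$binding_energy <-
      dock(protein, pool[[k]]$molecule, pocket_to_dockbox(pk), engine)$binding_energy
  }
  ## actives: extra local edits on randomly chosen pool ligands
  actives <- with_seed(derive_seed(seed, "actives"), {
    smi <- character(0)
    guard <- 0
    while (length(smi) < n_actives && guard < 20) {
      guard <- guard + 1
      need <- n_actives - length(smi)
      src <- sample(length(pool), need, replace = TRUE)
      nedit <- sample(active_edits, need, replace = TRUE)
      cand <- edited_smiles_batch(lapply(pool[src], `[[`, "molecule"), nedit)
      smi <- c(smi, cand[!is.na(cand)])
    }
    molecules_from_smiles(smi[seq_len(min(n_actives, length(smi)))],
                          ids = sprintf("active_%03d", seq_len(min(n_actives, length(smi)))),
                          source = "library")
  })
  decoy_provider <- synthetic_provider(derive_seed(seed, "decoys"),
                                       scaffold_set = decoy_scaffolds())
  decoys <- decoy_provider$generate(n_decoys, seed, 0L)
  for (k in seq_along(decoys)) {
    decoys[[k]]$id <- sprintf("decoy_%04d", k)
    decoys[[k]]$source <- "library"
  }
  library_mols <- c(unclass(actives), unclass(decoys))
  ord <- with_seed(derive_seed(seed, "shuffle"), sample(length(library_mols)))
  structure(list(
    protein = protein, pockets = pockets, pool = pool,
    library = library_mols[ord],
    approved_ids = vapply(actives, `[[`, character(1), "id"),
    seed = seed,
    params = list(n_decoys = n_decoys, n_actives = n_actives,
                  edit_distance_of_actives = active_edits,
                  pool_size = pool_size)),
    class = "synthetic_screen")
}

#' @export
print.synthetic_screen <- function(x, ...) {
  cat(sprintf("<synthetic screen seed %s> library %d (%d approved), pool %d, %d pockets\n",
              format(x$seed), length(x$library), length(x$approved_ids),
              length(x$pool), length(x$pockets)))
  invisible(x)
}

#' Export a synthetic screen to disk
#'
#' Writes `library.smi`, `pool.sdf` (with pocket and energy data fields),
#' `protein.pdb`, an Fpocket-dialect pocket directory, and `truth.json`
#' (approved ids, seed, params).
#'
#' @param screen A `synthetic_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_screen <- function(screen, dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_molecules(screen$library, file.path(dir, "library.smi"), "smiles")
  write_pool_sdf(screen$pool, file.path(dir, "pool.sdf"))
  write_protein_pdb(screen$protein, file.path(dir, "protein.pdb"))
  write_fpocket_dir(screen$protein, screen$pockets, dir)
  jsonlite::write_json(
    list(approved_ids = screen$approved_ids, seed = screen$seed,
         params = screen$params),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the surrogate-retrieval recovery experiment over several seeds
#'
#' For each seed: build a synthetic screen, assign surrogates under `mode`,
#' score with the chosen ranking mode, rank, and evaluate first-hit rank and
#' hit rate reduction. The median over seeds summarises the run.
#'
#' @param seeds Integer vector of at least 3 seeds.
#' @param n_decoys,n_actives,pool_size Screen parameters (see
#'   [make_screen()]).
#' @param mode Similarity mode (see [similarity_matrix()]).
#' @param ranking Ranking mode (see [fitness_scores()]).
#' @return data.frame (seed, first_hit_rank, hit_rate_reduction) with
#'   attribute `medians`.
#' @export
recovery_experiment <- function(seeds, n_decoys = 1000, n_actives = 20,
                                pool_size = 50, mode = "tanimoto",
                                ranking = "ss_plus_be") {
  if (length(seeds) < 3) vs_stop("parameter", "need at least 3 seeds")
  rows <- lapply(seeds, function(s) {
    res <- tryCatch({
      scr <- make_screen(s, n_decoys, n_actives, pool_size)
      asg <- assign_surrogates(scr$library, scr$pool, mode = mode)
      ranked <- rank_candidates(fitness_scores(asg, mode = ranking), asg)
      r <- first_hit_rank(ranked, scr$approved_ids)
      data.frame(seed = s, first_hit_rank = r,
                 hit_rate_reduction = if (is.na(r)) NA_real_
                 else hit_rate_reduction(r, length(scr$library)))
    }, vs_error = function(e)
      vs_stop("evaluation", "seed %s failed: %s", format(s), conditionMessage(e)))
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "medians") <- c(
    first_hit_rank = stats::median(out$first_hit_rank, na.rm = TRUE),
    hit_rate_reduction = stats::median(out$hit_rate_reduction, na.rm = TRUE))
  out
}

#' Expected first-hit rank under a random ranking
#'
#' Under a uniformly random permutation of an `n`-compound library
#' containing `a` actives, the expected minimum active rank is
#' `(n + 1) / (a + 1)` — the baseline any informative ranking must beat.
#'
#' @param n Library size.
#' @param a Number of actives.
#' @return Expected first-hit rank.
#' @export
expected_null_first_hit <- function(n, a) (n + 1) / (a + 1)
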