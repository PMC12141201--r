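## Screen evaluation: first-approved-drug rank, hit rate reduction, the
## top-k docking cost simulation, and drug-likeness property profiling.

#' Rank of the first approved drug in a ranked candidate list
#'
#' @param ranked Ranked candidate table (as from [rank_candidates()]).
#' @param approved Non-empty character set of approved drug ids.
#' @return The smallest rank whose drug id is approved, or `NA_integer_`
#'   when no approved drug is ranked.
#' @export
first_hit_rank <- function(ranked, approved) {
  if (is.null(ranked) || nrow(ranked) == 0)
    vs_stop("evaluation", "empty ranked list")
  if (length(approved) == 0)
    vs_stop("evaluation", "empty approved-drug set")
  hits <- ranked$rank[ranked$drug_id %in% approved]
  if (length(hits) == 0) NA_integer_ else as.integer(min(hits))
}

#' Hit rate reduction
#'
#' `100 * (1 - r / n_library)`: the percentage of the library that need not
#' be evaluated further once the first approved drug is found at rank `r`.
#'
#' @param r First-hit rank (1-based).
#' @param n_library Library size.
#' @return Percentage in `[0, 100)`.
#' @export
#' @examples
#' hit_rate_reduction(1, 100)    # 99
#' hit_rate_reduction(250, 1000) # 75
hit_rate_reduction <- function(r, n_library) {
  if (!is_count(r, 1) || !is_count(n_library, 1) || r > n_library)
    vs_stop("parameter", "need 1 <= r <= n_library (got r=%s, N=%s)",
            format(r), format(n_library))
  100 * (1 - r / n_library)
}

#' Simulate the screening cost of docking down to the first approved drug
#'
#' Mirrors the iterative screening protocol: `k` is set to the first-hit
#' rank and every candidate ranked 1..k is docked against the box of its
#' inherited pocket. Wall time is reported but is hardware-dependent and is
#' never asserted in tests.
#'
#' @param ranked Ranked candidate table (needs `drug_id` and `pocket_id`).
#' @param approved Approved drug id set.
#' @param protein A `protein_structure`.
#' @param engine A `docking_engine`.
#' @param drugs List of `molecule` objects covering the ranked drugs.
#' @param pockets List of `pocket` objects covering the inherited pockets.
#' @param margin,min_edge Box construction parameters.
#' @return List with `k` (first-hit rank, `NA` when absent), `results`
#'   (one `docking_result` per docked candidate), and `total_time` (seconds).
#' @export
simulate_topk_docking <- function(ranked, approved, protein, engine, drugs,
                                  pockets, margin = 4, min_edge = 10) {
  k <- first_hit_rank(ranked, approved)
  if (is.na(k)) {
    vs_log("evaluation", "no approved drug in the ranked list; skipping docking")
    return(list(k = NA_integer_, results = list(), total_time = 0))
  }
  drug_ids <- vapply(drugs, `[[`, character(1), "id")
  pocket_ids <- vapply(pockets, `[[`, integer(1), "pocket_id")
  t0 <- proc.time()[["elapsed"]]
  results <- list()
  for (r in seq_len(k)) {
    did <- ranked$drug_id[ranked$rank == r]
    mol <- drugs[[match(did, drug_ids)]]
    pk <- pockets[[match(ranked$pocket_id[ranked$rank == r], pocket_ids)]]
    res <- tryCatch(
      dock(protein, mol, pocket_to_dockbox(pk, margin, min_edge), engine),
      vs_error = function(e) {
        vs_log("evaluation", "docking failed for %s: %s", did,
               conditionMessage(e))
        NULL
      })
    if (!is.null(res)) results[[length(results) + 1]] <- res
  }
  list(k = k, results = results,
       total_time = proc.time()[["elapsed"]] - t0)
}

## Drug-likeness ------------------------------------------------------------

## ADS (asymmetric double sigmoidal) desirability function and its published
## per-property parameters (a, b, c, d, e, f, dmax) for the quantitative
## estimate of drug-likeness.
qed_ads <- function(x, p) {
  v <- p[1] + p[2] / (1 + exp(-(x - p[3] + p[4] / 2) / p[5])) *
    (1 - 1 / (1 + exp(-(x - p[3] - p[4] / 2) / p[6])))
  pmax(v / p[7], 1e-6)
}

QED_ADS_PARAMS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 0.000000001, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.010000000, 272.4121427, 2.558379970, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.217788970, 957.7374108, 2.274627939, 0.000000001, 1.317690384, 0.375760881, 312.3372610),
  ALERTS = c(0.010000000, 1199.094025, -0.09002883, 0.000000001, 0.185904477, 0.875193782, 417.7253140))

QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

## Weighted geometric mean of the desirabilities. The structural-alert count
## is fixed at zero (no SMARTS matcher is wired in); lipophilicity comes
## from the conversion backend's logP model. Documented in the vignette.
qed_score <- function(mw, alogp, hba, hbd, psa, rotb, arom, alerts = 0) {
  x <- c(MW = unname(mw), ALOGP = unname(alogp), HBA = unname(hba),
         HBD = unname(hbd), PSA = unname(psa), ROTB = unname(rotb),
         AROM = unname(arom), ALERTS = unname(alerts))
  d <- vapply(names(x), function(nm) qed_ads(x[[nm]], QED_ADS_PARAMS[[nm]]),
              numeric(1))
  exp(sum(QED_WEIGHTS * log(d)) / sum(QED_WEIGHTS))
}

## Number of independent aromatic rings: the circuit rank of the subgraph of
## bonds joining two aromatic atoms (naphthalene 2, biphenyl 2, benzene 1).
aromatic_ring_count <- function(mol) {
  w <- bond_weights(mol$atoms, mol$bonds)
  ar <- which(w == 1.5)
  if (length(ar) == 0) return(0L)
  verts <- unique(c(mol$bonds$i[ar], mol$bonds$j[ar]))
  comp <- count_components(verts, mol$bonds[ar, , drop = FALSE])
  as.integer(length(ar) - length(verts) + comp)
}

count_components <- function(verts, bonds) {
  idx <- stats::setNames(seq_along(verts), verts)
  parent <- seq_along(verts)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  for (r in seq_len(nrow(bonds))) {
    ra <- find(idx[[as.character(bonds$i[r])]])
    rb <- find(idx[[as.character(bonds$j[r])]])
    if (ra != rb) parent[rb] <- ra
  }
  length(unique(vapply(seq_along(verts), find, integer(1))))
}

## Backend descriptor batch: logP, TPSA, HBA, HBD, rotatable bonds.
ob_descriptors <- function(mols) {
  input <- paste0(vapply(mols, `[[`, character(1), "smiles"),
                  " r", seq_along(mols), collapse = "\n")
  res <- ob_convert("SMI", "SMI", paste0(input, "\n"),
                    options = data.frame(names = "append",
                                         args = "logP TPSA HBA1 HBD rotors"))
  out <- matrix(NA_real_, length(mols), 5,
                dimnames = list(NULL, c("logp", "tpsa", "hba", "hbd", "rotb")))
  for (ln in strsplit(res, "\n", fixed = TRUE)[[1]]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) next
    vals <- strsplit(trimws(f[2]), "[ \t]+")[[1]]
    k <- suppressWarnings(as.integer(sub("^r", "", vals[1])))
    if (is.na(k) || length(vals) < 6) next
    out[k, ] <- suppressWarnings(as.numeric(vals[2:6]))
  }
  out
}

## Self-contained synthetic-accessibility estimate: fragment commonness
## within the analysed set (circular fragments, radius 2) combined with
## size and ring-complexity penalties, mapped to the conventional 1 (easy)
## to 10 (hard) range. This is the package's own variant, not the published
## fragment-database score; it is monotone in rarity and complexity.
sa_score_set <- function(mols) {
  frags <- lapply(mols, function(m) unique(mol_circular_ids(m, 2)))
  all_f <- unlist(frags)
  freq <- table(all_f)
  n <- length(mols)
  vapply(seq_along(mols), function(k) {
    p <- as.numeric(freq[as.character(frags[[k]])]) / n
    commonness <- mean(log10(p))
    heavy <- nrow(mols[[k]]$atoms)
    nring <- max(0, nrow(mols[[k]]$bonds) - heavy + 1)
    raw <- -commonness + log10(max(heavy, 1)) / 2 + 0.3 * nring
    min(10, max(1, 1 + 2 * raw))
  }, numeric(1))
}

#' Drug-likeness property profile of a molecule set
#'
#' One row per molecule: molecular weight (Da), quantitative estimate of
#' drug-likeness (QED, weighted desirability form; the structural-alert term
#' is treated as alert-free and lipophilicity uses the conversion backend's
#' logP), a self-contained synthetic-accessibility estimate (1 easy to 10
#' hard; fragment commonness is measured within the input set), heavy-atom
#' count, aromatic-ring count, rotatable-bond count, hydrogen-bond acceptors
#' and donors, and topological polar surface area (A^2). A `summary`
#' attribute holds per-column means and medians.
#'
#' @param mols List of `molecule` objects.
#' @return data.frame, one row per molecule, with attribute `summary`.
#' @export
druglikeness_profile <- function(mols) {
  stopifnot(length(mols) > 0, all(vapply(mols, is_molecule, logical(1))))
  desc <- ob_descriptors(mols)
  tab <- data.frame(
    mol_id = vapply(mols, `[[`, character(1), "id"),
    mw = vapply(mols, molecular_weight, numeric(1)),
    heavy_atoms = vapply(mols, function(m) nrow(m$atoms), integer(1)),
    aromatic_rings = vapply(mols, aromatic_ring_count, integer(1)),
    rotatable_bonds = desc[, "rotb"],
    hba = desc[, "hba"], hbd = desc[, "hbd"],
    tpsa = desc[, "tpsa"], logp = desc[, "logp"],
    stringsAsFactors = FALSE)
  tab$qed <- vapply(seq_along(mols), function(k) {
    if (anyNA(desc[k, ])) return(NA_real_)
    qed_score(tab$mw[k], desc[k, "logp"], desc[k, "hba"], desc[k, "hbd"],
              desc[k, "tpsa"], desc[k, "rotb"], tab$aromatic_rings[k])
  }, numeric(1))
  tab$sa_score <- sa_score_set(mols)
  if (anyNA(desc))
    vs_log("evaluation", "descriptor failures for %d molecule(s)",
           sum(apply(desc, 1, anyNA)))
  num <- tab[, setdiff(names(tab), "mol_id")]
  attr(tab, "summary") <- data.frame(
    property = names(num),
    mean = vapply(num, function(x) mean(x, na.rm = TRUE), numeric(1)),
    median = vapply(num, function(x) stats::median(x, na.rm = TRUE), numeric(1)),
    row.names = NULL)
  tab
}

## Screen report -------------------------------------------------------------

new_screen_report <- function(target_id, ranked, approved_ids, n_library,
                              k_docked = NA_integer_, skipped = character(0),
                              docking_time = NA_real_, seed = NA_integer_,
                              config_hash = NA_character_) {
  r <- first_hit_rank(ranked, approved_ids)
  hrr <- if (is.na(r)) NA_real_ else hit_rate_reduction(r, n_library)
  structure(list(target_id = target_id, ranked = ranked,
                 approved_ids = approved_ids, n_library = n_library,
                 first_hit_rank = r, hit_rate_reduction = hrr,
                 k_docked = k_docked, skipped = skipped,
                 docking_time = docking_time, seed = seed,
                 config_hash = config_hash),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("Screen report for target %s (%d candidates ranked, seed %s)\n",
              x$target_id, nrow(x$ranked), format(x$seed)))
  cat(sprintf("  first approved drug at rank: %s\n",
              if (is.na(x$first_hit_rank)) "none" else x$first_hit_rank))
  cat(sprintf("  hit rate reduction:          %s\n",
              if (is.na(x$hit_rate_reduction)) "n/a"
              else sprintf("%.2f%%", x$hit_rate_reduction)))
  cat(sprintf("  candidates docked (k):       %s\n",
              if (is.na(x$k_docked)) "none" else x$k_docked))
  if (length(x$skipped) > 0)
    cat(sprintf("  skipped drugs:               %d\n", length(x$skipped)))
  invisible(x)
}

#' @export
summary.screen_report <- function(object, n = 10, ...) {
  print(object)
  cat("\nTop candidates:\n")
  print(utils::head(object$ranked[, intersect(
    c("rank", "drug_id", "fitness", "similarity", "binding_energy", "pocket_id"),
    names(object$ranked))], n), row.names = FALSE)
  invisible(object)
}

#' Serialize a screen report to JSON (and optionally the ranked CSV)
#'
#' @param report A `screen_report`.
#' @param json_path Output JSON path.
#' @param csv_path Optional ranked-table CSV path.
#' @return `json_path`, invisibly.
#' @export
write_screen_report <- function(report, json_path, csv_path = NULL) {
  stopifnot(inherits(report, "screen_report"))
  obj <- report[c("target_id", "n_library", "first_hit_rank",
                  "hit_rate_reduction", "k_docked", "skipped", "seed",
                  "config_hash")]
  obj$ranked <- report$ranked
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) utils::write.csv(report$ranked, csv_path,
                                           row.names = FALSE)
  invisible(json_path)
}
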