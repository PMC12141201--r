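## Surrogate search: assign each library drug its most similar generated
## ligand, inheriting that ligand's binding energy and pocket. This is the
## retrieval step that replaces per-drug docking with similarity search.

new_drug_assignment <- function(drug, matched_ligand_id, similarity,
                                binding_energy, pocket_id) {
  structure(list(drug = drug, matched_ligand_id = matched_ligand_id,
                 similarity = similarity, binding_energy = binding_energy,
                 pocket_id = as.integer(pocket_id)),
            class = "drug_assignment")
}

#' @export
print.drug_assignment <- function(x, ...) {
  cat(sprintf("<assignment %s -> %s> similarity=%.3f BE=%.2f kcal/mol pocket=%d\n",
              x$drug$id, x$matched_ligand_id, x$similarity, x$binding_energy,
              x$pocket_id))
  invisible(x)
}

#' Assign each drug its most similar generated ligand
#'
#' For every library drug the argmax-similarity ligand of the generated pool
#' is selected under the chosen encoding mode; the drug inherits that
#' ligand's binding energy and pocket. Ties are broken by lower (better)
#' binding energy, then by lexicographically smaller ligand id, so the
#' assignment is deterministic.
#'
#' @param drugs Non-empty list of `molecule` objects.
#' @param pool Non-empty list of `generated_ligand` objects, all carrying
#'   binding energies.
#' @param mode Similarity mode, see [similarity_matrix()].
#' @param ... Further encoder parameters passed to [similarity_matrix()].
#' @return List of `drug_assignment` objects in drug order. Drugs whose
#'   encoding fails are skipped and listed in the `skipped` attribute.
#' @export
assign_surrogates <- function(drugs, pool,
                              mode = c("tanimoto", "morgan_cosine", "graph_cosine"),
                              ...) {
  mode <- match.arg(mode)
  if (length(pool) == 0) vs_stop("search", "empty generated-ligand pool")
  if (length(drugs) == 0) vs_stop("search", "empty drug list")
  stopifnot(all(vapply(pool, inherits, logical(1), "generated_ligand")))
  be <- vapply(pool, `[[`, numeric(1), "binding_energy")
  if (anyNA(be))
    vs_stop("search", "pool ligands without binding energies: %s",
            paste(vapply(pool[is.na(be)], function(g) g$molecule$id,
                         character(1)), collapse = ", "))
  skipped <- character(0)
  enc_ok <- vapply(drugs, function(d) {
    !inherits(tryCatch(morgan_fingerprint(d, 1, 64), vs_error = identity),
              "condition")
  }, logical(1))
  if (!all(enc_ok)) {
    skipped <- vapply(drugs[!enc_ok], `[[`, character(1), "id")
    vs_log("search", "%d drug(s) failed encoding and were skipped: %s",
           length(skipped), paste(skipped, collapse = ", "))
    drugs <- drugs[enc_ok]
    if (length(drugs) == 0) vs_stop("search", "no encodable drugs left")
  }
  qmols <- lapply(pool, `[[`, "molecule")
  S <- similarity_matrix(qmols, drugs, mode = mode, ...)
  lig_ids <- vapply(qmols, `[[`, character(1), "id")
  pocket <- vapply(pool, `[[`, integer(1), "pocket_id")
  out <- vector("list", length(drugs))
  for (k in seq_along(drugs)) {
    j <- pick_best_ligand(S[k, ], be, lig_ids)
    out[[k]] <- new_drug_assignment(drugs[[k]], lig_ids[j], S[k, j], be[j],
                                    pocket[j])
  }
  structure(out, skipped = skipped)
}

## Argmax with the documented tie-breaks: max similarity, then lower binding
## energy, then smaller ligand id.
pick_best_ligand <- function(sims, energies, ids) {
  best <- which(sims == max(sims))
  if (length(best) > 1) best <- best[energies[best] == min(energies[best])]
  if (length(best) > 1) best <- best[order(ids[best])[1]]
  best[1]
}

#' Write an assignment table to CSV
#'
#' Columns: drug_id, matched_ligand_id, similarity, binding_energy,
#' pocket_id.
#'
#' @param assignments List of `drug_assignment` objects.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  tab <- assignments_table(assignments)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
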