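## Multi-objective rank-sum ranking.
##
## Each library drug carries two criteria inherited from its surrogate
## assignment: f1, the similarity to its most similar generated ligand, and
## f2, that ligand's docking binding energy (kcal/mol, lower is better). The
## combined fitness is
##
##   f(x) = w1 * f1(x) / E(f1^2)  -  w2 * f2(x) / E(f2^2)
##
## with rank-sum criterion weights w_i = 2(n + 1 - i) / (n (n + 1)) (n = 2
## criteria, so w = (2/3, 1/3)) and expectations taken as arithmetic means
## over the drug set being ranked. The minus sign rewards strongly negative
## (favourable) binding energies. The denominator is the mean of squares as
## written; `normalization = "rms"` switches to its square root, which makes
## each term dimensionless.

#' Rank-sum criterion weights
#'
#' `w_i = 2(n + 1 - i) / (n (n + 1))` for `i = 1..n`: positive, strictly
#' decreasing, summing to one.
#'
#' @param n Number of criteria (>= 1).
#' @return Numeric vector of weights.
#' @export
#' @examples
#' rank_sum_weights(2)  # 2/3, 1/3
#' rank_sum_weights(4)  # 0.4 0.3 0.2 0.1
rank_sum_weights <- function(n) {
  if (!is_count(n, 1)) vs_stop("parameter", "n must be an integer >= 1")
  i <- seq_len(n)
  2 * (n + 1 - i) / (n * (n + 1))
}

#' Multi-objective fitness scores for surrogate assignments
#'
#' @param assignments List of `drug_assignment` objects (or a data.frame
#'   with columns `drug_id`, `similarity`, `binding_energy`).
#' @param mode `"ss_plus_be"` combines similarity and binding energy with
#'   rank-sum weights; `"ss"` uses similarity alone; `"be"` uses the negated
#'   binding energy alone.
#' @param normalization `"mean_square"` divides each criterion by the mean of
#'   its squares (as the fitness is defined); `"rms"` divides by the root
#'   mean square instead.
#' @return data.frame with columns `drug_id` and `fitness`, in input order.
#' @export
fitness_scores <- function(assignments, mode = c("ss_plus_be", "ss", "be"),
                           normalization = c("mean_square", "rms")) {
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  tab <- assignments_table(assignments)
  if (nrow(tab) == 0) vs_stop("rank", "no assignments to score")
  f1 <- tab$similarity
  f2 <- tab$binding_energy
  fitness <- switch(mode,
    ss = f1,
    be = -f2,
    ss_plus_be = {
      if (anyNA(f1) || anyNA(f2))
        vs_stop("rank", "ss_plus_be mode needs both similarity and binding energy for every drug")
      e1 <- mean(f1^2); e2 <- mean(f2^2)
      if (e1 == 0) vs_stop("rank", "degenerate input: all similarity scores are zero")
      if (e2 == 0) vs_stop("rank", "degenerate input: all binding energies are zero")
      if (normalization == "rms") { e1 <- sqrt(e1); e2 <- sqrt(e2) }
      w <- rank_sum_weights(2)
      w[1] * f1 / e1 - w[2] * f2 / e2
    })
  data.frame(drug_id = tab$drug_id, fitness = fitness, stringsAsFactors = FALSE)
}

#' Rank scored candidates
#'
#' Orders by descending fitness; ties are broken by higher similarity
#' (`f1`), then by drug id, so the ordering is total and deterministic.
#'
#' @param scored data.frame with `drug_id` and `fitness` (as from
#'   [fitness_scores()]).
#' @param assignments Optional assignment list/table supplying `similarity`,
#'   `binding_energy`, `pocket_id` and `matched_ligand_id` for the output
#'   and the tie-break.
#' @return data.frame of ranked candidates: `rank` (1 = best), `drug_id`,
#'   `fitness`, plus assignment columns when supplied.
#' @export
rank_candidates <- function(scored, assignments = NULL) {
  if (is.null(scored) || nrow(scored) == 0) vs_stop("rank", "nothing to rank")
  tab <- scored
  if (!is.null(assignments)) {
    at <- assignments_table(assignments)
    tab <- merge(tab, at, by = "drug_id", sort = FALSE)
    tab <- tab[match(scored$drug_id, tab$drug_id), , drop = FALSE]
  }
  f1 <- if ("similarity" %in% names(tab)) tab$similarity else rep(0, nrow(tab))
  ord <- order(-tab$fitness, -f1, tab$drug_id)
  out <- tab[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

## Coerce a list of drug_assignment objects (or an already-tabular input)
## into the canonical assignment table.
assignments_table <- function(assignments) {
  if (is.data.frame(assignments)) return(assignments)
  if (length(assignments) == 0)
    return(data.frame(drug_id = character(0), similarity = numeric(0),
                      binding_energy = numeric(0)))
  stopifnot(all(vapply(assignments, inherits, logical(1), "drug_assignment")))
  data.frame(
    drug_id = vapply(assignments, function(a) a$drug$id, character(1)),
    matched_ligand_id = vapply(assignments, `[[`, character(1), "matched_ligand_id"),
    similarity = vapply(assignments, `[[`, numeric(1), "similarity"),
    binding_energy = vapply(assignments, `[[`, numeric(1), "binding_energy"),
    pocket_id = vapply(assignments, `[[`, integer(1), "pocket_id"),
    stringsAsFactors = FALSE)
}
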