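options(vscreenr.quiet = TRUE)

## A small diverse set of valid drug-like SMILES used across tests.
fixture_smiles <- c(
  "CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CCN(CC)CC", "c1ccncc1",
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "c1ccc2[nH]ccc2c1", "CC(=O)Nc1ccccc1",
  "C1CCNCC1", "OCC(O)CO", "CC#N", "ClCc1ccccc1", "CC(N)C(=O)O",
  "c1ccc(cc1)S(=O)(=O)N", "O=C1CCCCC1", "CCOC(=O)C", "NC(=O)c1ccccc1",
  "CSc1ccccc1", "FC(F)(F)c1ccccc1", "C1CCOC1")

fixture_molecules <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- molecules_from_smiles(fixture_smiles,
                                      paste0("fx", seq_along(fixture_smiles)),
                                      source = "fixture")
    cache
  }
})

## Generated-ligand pool wrapper with prescribed energies/pockets.
fixture_pool <- function(mols, energies, pockets = NULL) {
  pockets <- pockets %||% rep(1L, length(mols))
  lapply(seq_along(mols), function(k) {
    g <- vscreenr:::new_generated_ligand(mols[[k]], pockets[k], energies[k],
                                         "fixture")
    g
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Random binary "fingerprint" pair with controlled overlap, for brute-force
## similarity checks.
random_fp_pair <- function(n_bits = 256) {
  a <- sort(sample(n_bits, sample(0:40, 1)))
  b <- sort(sample(n_bits, sample(0:40, 1)))
  mk <- function(on) structure(list(on = on, n_bits = n_bits, radius = 2L,
                                    mol_id = "x"), class = "fingerprint")
  list(a = mk(a), b = mk(b))
}

## Independent direct evaluation of the rank-sum fitness used as the oracle
## in ranking tests (kept deliberately naive: per-drug loop, no reuse of
## package internals).
oracle_fitness <- function(f1, f2, mode, normalization = "mean_square") {
  n <- length(f1)
  if (mode == "ss") return(f1)
  if (mode == "be") return(-f2)
  e1 <- sum(f1^2) / n
  e2 <- sum(f2^2) / n
  if (normalization == "rms") { e1 <- sqrt(e1); e2 <- sqrt(e2) }
  w1 <- 2 * (2 + 1 - 1) / (2 * 3)
  w2 <- 2 * (2 + 1 - 2) / (2 * 3)
  out <- numeric(n)
  for (k in seq_len(n)) out[k] <- w1 * f1[k] / e1 - w2 * f2[k] / e2
  out
}

## Independent argmax-with-tie-breaks oracle for surrogate assignment.
oracle_assign <- function(S, energies, ids) {
  apply(S, 1, function(row) {
    best <- NULL
    for (j in seq_along(row)) {
      if (is.null(best)) { best <- j; next }
      if (row[j] > row[best]) best <- j
      else if (row[j] == row[best]) {
        if (energies[j] < energies[best]) best <- j
        else if (energies[j] == energies[best] && ids[j] < ids[best]) best <- j
      }
    }
    best
  })
}

## Minimal Fpocket-dialect directory fixture built in code.
write_fpocket_fixture <- function(dir, scores = c(`1` = 0.8, `2` = 0.3, `3` = 0.5),
                                  coords = NULL) {
  pdir <- file.path(dir, "prot_out", "pockets")
  dir.create(pdir, recursive = TRUE, showWarnings = FALSE)
  info <- character(0)
  for (nm in names(scores)) {
    pid <- as.integer(nm)
    xyz <- if (!is.null(coords) && !is.null(coords[[nm]])) coords[[nm]]
    else matrix(c(0, 0, 0, 2, 4, 6), 2, 3, byrow = TRUE) + pid
    lines <- sprintf(
      "ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      seq_len(nrow(xyz)), seq_len(nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3])
    writeLines(c(lines, "END"),
               file.path(pdir, sprintf("pocket%d_atm.pdb", pid)))
    info <- c(info, sprintf("Pocket %d :", pid),
              sprintf("\tScore : %.3f", scores[[nm]]), "")
  }
  writeLines(info, file.path(dir, "prot_out", "prot_info.txt"))
  file.path(dir, "prot_out")
}

## Vina-style log fixture.
write_vina_log_fixture <- function(path, affinities = c(-7.2, -6.0, -5.1)) {
  writeLines(c(
    "Detected 8 CPUs", "Reading input ... done.",
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    sprintf("%5d %11.1f %10.3f %10.3f", seq_along(affinities), affinities,
            c(0, 1.2, 2.1)[seq_along(affinities)],
            c(0, 2.2, 3.3)[seq_along(affinities)]),
    "Writing output ... done."), path)
  path
}
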