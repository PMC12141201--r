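## Molecule records
##
## A molecule is a light S3 record: an identifier, the canonical SMILES
## (which *is* the molecular identity throughout the package), an atom table,
## a bond table and optional 3D coordinates. Canonicalization, aromaticity
## perception and format conversion are delegated to OpenBabel through
## ChemmineOB; the graph tables exist so that fingerprints, editing and
## descriptors can work without further backend round-trips.

ATOMIC_MASS <- c(
  H = 1.008, B = 10.811, C = 12.011, N = 14.007, O = 15.999, F = 18.998,
  Na = 22.990, Mg = 24.305, Si = 28.086, P = 30.974, S = 32.06, Cl = 35.453,
  K = 39.098, Ca = 40.078, Fe = 55.845, Zn = 65.38, Se = 78.971,
  Br = 79.904, I = 126.904
)

## Standard valence lists used to infer implicit hydrogen counts for
## charge-neutral organic-subset atoms (bracket atoms carry explicit counts).
DEFAULT_VALENCES <- list(
  B = 3, C = 4, N = c(3, 5), O = 2, P = c(3, 5), S = c(2, 4, 6),
  F = 1, Cl = 1, Br = 1, I = 1
)

ob_convert <- function(from, to, text, options = NULL) {
  tryCatch(
    if (is.null(options)) ChemmineOB::convertFormat(from, to, text)
    else ChemmineOB::convertFormat(from, to, text, options = options),
    error = function(e) vs_stop("encoding", "format conversion %s->%s failed: %s",
                                from, to, conditionMessage(e))
  )
}

#' Canonicalize SMILES strings
#'
#' Strings are first checked for well-formedness (the backend silently
#' repairs some malformed inputs), then canonicalized by OpenBabel with
#' explicit hydrogens stripped. Failures yield `NA`.
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @export
#' @examples
#' canonical_smiles(c("OCC", "C(C"))
canonical_smiles <- function(smiles) {
  out <- rep(NA_character_, length(smiles))
  ok <- smiles_is_valid(smiles)
  if (!any(ok)) return(out)
  idx <- which(ok)
  input <- paste0(smiles[idx], " r", seq_along(idx), collapse = "\n")
  res <- ob_convert("SMI", "CAN", paste0(input, "\n"),
                    options = data.frame(names = "d", args = ""))
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2) next
    k <- suppressWarnings(as.integer(sub("^r", "", parts[2])))
    if (!is.na(k) && nzchar(parts[1])) out[idx[k]] <- parts[1]
  }
  ## a canonical form must itself tokenize; guard against backend surprises
  bad <- !is.na(out) & !smiles_is_valid(out)
  out[bad] <- NA_character_
  out
}

## Minimal fixed-column V2000 reader for the connection tables the backend
## emits. Returns one record per $$$$ block: title, element vector, bond
## table, coordinate matrix.
parse_molfile_records <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0 && length(lines) > 4) ends <- length(lines)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  recs <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    rec <- lines[starts[k]:ends[k]]
    if (length(rec) < 4) next
    na <- suppressWarnings(as.integer(substr(rec[4], 1, 3)))
    nb <- suppressWarnings(as.integer(substr(rec[4], 4, 6)))
    if (is.na(na) || is.na(nb) || length(rec) < 4 + na + nb) next
    al <- rec[4 + seq_len(na)]
    bl <- if (nb > 0) rec[4 + na + seq_len(nb)] else character(0)
    bonds <- data.frame(
      i = as.integer(substr(bl, 1, 3)), j = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9)))
    recs[[k]] <- list(
      title = trimws(rec[1]),
      elements = trimws(substr(al, 32, 34)),
      coords = cbind(as.numeric(substr(al, 1, 10)),
                     as.numeric(substr(al, 11, 20)),
                     as.numeric(substr(al, 21, 30))),
      bonds = bonds)
  }
  recs[!vapply(recs, is.null, logical(1))]
}

## Build molecule objects from canonical SMILES (assumed already canonical
## and valid). Returns a list of molecules; elements are NULL on failure.
mols_from_canonical <- function(can, ids, source = "library") {
  stopifnot(length(can) == length(ids))
  out <- vector("list", length(can))
  if (length(can) == 0) return(out)
  input <- paste0(can, " r", seq_along(can), collapse = "\n")
  sdftxt <- ob_convert("SMI", "SDF", paste0(input, "\n"))
  for (rec in parse_molfile_records(sdftxt)) {
    j <- suppressWarnings(as.integer(sub("^r", "", rec$title)))
    if (is.na(j)) next
    toks <- smiles_tokenize(can[j])
    if (is.null(toks) || nrow(toks) != length(rec$elements) ||
        !all(toks$element == rec$elements)) next  # order mismatch: refuse
    atoms <- data.frame(element = toks$element, charge = toks$charge,
                        aromatic = toks$aromatic, stringsAsFactors = FALSE)
    atoms$hcount <- infer_hcounts(atoms, rec$bonds, toks$hcount)
    out[[j]] <- new_molecule(id = ids[j], smiles = can[j], atoms = atoms,
                             bonds = rec$bonds, coords3d = NULL, source = source)
  }
  out
}

new_molecule <- function(id, smiles, atoms, bonds, coords3d = NULL,
                         source = c("library", "generated", "fixture")) {
  source <- match.arg(source)
  structure(list(id = as.character(id), smiles = smiles, atoms = atoms,
                 bonds = bonds, coords3d = coords3d, source = source),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule %s> %s  (%d heavy atoms, %d bonds, source=%s)\n",
              x$id, x$smiles, nrow(x$atoms), nrow(x$bonds), x$source))
  invisible(x)
}

is_molecule <- function(x) inherits(x, "molecule")

#' Construct molecules from SMILES strings
#'
#' The main molecule constructor: validates, canonicalizes (stripping
#' explicit hydrogens) and builds the atom/bond tables. Unparseable inputs
#' are dropped; the returned list carries a `skipped` attribute with their
#' positions.
#'
#' @param smiles Character vector of SMILES strings.
#' @param ids Identifiers; defaults to `mol_<position>`.
#' @param source Provenance tag: `"library"`, `"generated"` or `"fixture"`.
#' @return List of `molecule` objects (parseable inputs only, in input
#'   order), with attribute `skipped` (integer positions of dropped inputs).
#' @export
#' @examples
#' mols <- molecules_from_smiles(c("CCO", "c1ccccc1"), c("ethanol", "benzene"))
#' mols[[1]]
molecules_from_smiles <- function(smiles, ids = NULL,
                                  source = c("library", "generated", "fixture")) {
  source <- match.arg(source)
  if (length(smiles) == 0) return(structure(list(), skipped = integer(0)))
  ids <- ids %||% paste0("mol_", seq_along(smiles))
  can <- canonical_smiles(smiles)
  mols <- vector("list", length(smiles))
  okpos <- which(!is.na(can))
  if (length(okpos) > 0)
    mols[okpos] <- mols_from_canonical(can[okpos], ids[okpos], source = source)
  skipped <- which(vapply(mols, is.null, logical(1)))
  structure(mols[setdiff(seq_along(mols), skipped)], skipped = skipped)
}

## Implicit hydrogen counts. `explicit` holds bracket-atom H counts (NA for
## organic-subset atoms, whose count follows from standard valences). Bonds
## between two aromatic atoms weigh 1.5 so the result does not depend on the
## kekulization the backend happened to emit.
infer_hcounts <- function(atoms, bonds, explicit = NULL) {
  n <- nrow(atoms)
  bw <- bond_weights(atoms, bonds)
  bsum <- numeric(n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      bsum[bonds$i[r]] <- bsum[bonds$i[r]] + bw[r]
      bsum[bonds$j[r]] <- bsum[bonds$j[r]] + bw[r]
    }
  }
  h <- integer(n)
  for (a in seq_len(n)) {
    if (!is.null(explicit) && !is.na(explicit[a])) { h[a] <- explicit[a]; next }
    vals <- DEFAULT_VALENCES[[atoms$element[a]]]
    if (is.null(vals)) { h[a] <- 0L; next }
    need <- ceiling(bsum[a] - 1e-9)
    fit <- vals[vals >= need]
    h[a] <- if (length(fit) == 0) 0L else as.integer(min(fit) - need)
  }
  h
}

## Per-bond weights: 1.5 for bonds joining two aromatic atoms (a
## kekulization-independent stand-in for the aromatic bond class), the
## integer order otherwise.
bond_weights <- function(atoms, bonds) {
  if (nrow(bonds) == 0) return(numeric(0))
  arom <- atoms$aromatic[bonds$i] & atoms$aromatic[bonds$j]
  ifelse(arom & bonds$order %in% c(1L, 2L), 1.5, as.numeric(bonds$order))
}

#' Molecular weight of a molecule
#'
#' Monoisotopic-free average molecular weight: sum of standard atomic masses
#' of the heavy atoms plus implicit hydrogens.
#'
#' @param mol A `molecule`.
#' @return Weight in daltons.
#' @export
molecular_weight <- function(mol) {
  stopifnot(is_molecule(mol))
  m <- ATOMIC_MASS[mol$atoms$element]
  if (anyNA(m))
    vs_stop("encoding", "no atomic mass for element(s): %s",
            paste(unique(mol$atoms$element[is.na(m)]), collapse = ", "))
  sum(m) + ATOMIC_MASS[["H"]] * sum(mol$atoms$hcount)
}

## Emit a V2000 molfile from graph tables (used for editing round-trips and
## SDF output). Coordinates default to zero; OpenBabel re-perceives
## aromaticity from the kekulized orders on read-back.
molfile_from_graph <- function(atoms, bonds, coords = NULL, title = "") {
  n <- nrow(atoms); m <- nrow(bonds)
  if (n > 999) vs_stop("io", "molfile writer supports at most 999 atoms")
  if (is.null(coords)) coords <- matrix(0, n, 3)
  head <- sprintf("%s\n  vscreenr\n\n%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                  title, n, m)
  al <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                coords[, 1], coords[, 2], coords[, 3], atoms$element)
  bl <- if (m > 0) sprintf("%3d%3d%3d  0  0  0  0", bonds$i, bonds$j, bonds$order)
  chg <- which(atoms$charge != 0)
  cl <- if (length(chg) > 0)
    vapply(chg, function(a) sprintf("M  CHG  1 %3d %3d", a, atoms$charge[a]),
           character(1))
  paste(c(head, al, bl, cl, "M  END"), collapse = "\n")
}

## Canonical SMILES for a batch of graph-edited candidates. Returns NA where
## the backend rejects the structure (the validity gate for edits).
canonical_from_graphs <- function(graphs) {
  if (length(graphs) == 0) return(character(0))
  blocks <- vapply(seq_along(graphs), function(k)
    paste0(molfile_from_graph(graphs[[k]]$atoms, graphs[[k]]$bonds,
                              title = paste0("r", k)), "\n$$$$"),
    character(1))
  res <- tryCatch(
    ob_convert("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"),
               options = data.frame(names = "d", args = "")),
    error = function(e) "")
  out <- rep(NA_character_, length(graphs))
  for (ln in strsplit(res, "\n", fixed = TRUE)[[1]]) {
    parts <- strsplit(ln, "[ \t]+")[[1]]
    if (length(parts) < 2) next
    k <- suppressWarnings(as.integer(sub("^r", "", parts[2])))
    if (!is.na(k) && nzchar(parts[1])) out[k] <- parts[1]
  }
  out[!is.na(out) & !smiles_is_valid(out)] <- NA_character_
  out
}
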