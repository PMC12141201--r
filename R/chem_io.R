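## Reading and writing the pipeline's interchange formats.
##
## SMILES libraries are whitespace-separated "SMILES ID" lines ("#" comments
## ignored); SDF is V2000 with the molecule id in the title line and
## duplicated in a <vscreenr_id> data field; proteins are fixed-column PDB.
## Large drug libraries routinely contain a few unparseable records, so the
## readers skip-and-log rather than fail.

#' Read a molecule library
#'
#' @param path File path.
#' @param format `"smiles"` or `"sdf"`.
#' @param source Provenance tag recorded on each molecule.
#' @return List of `molecule` objects in file order, with attribute
#'   `n_skipped` (count of unparseable records, also reported to the log).
#' @export
read_molecules <- function(path, format = c("smiles", "sdf"),
                           source = c("library", "generated", "fixture")) {
  format <- match.arg(format)
  source <- match.arg(source)
  if (!file.exists(path)) vs_stop("input", "no such file: %s", path)
  res <- if (format == "smiles") read_smiles_file(path, source)
  else read_sdf_file(path, source)
  if (attr(res, "n_skipped") > 0)
    vs_log("chem_io", "%d unparseable record(s) skipped in %s",
           attr(res, "n_skipped"), path)
  if (length(res) == 0)
    vs_stop("input", "no parseable molecule records in %s", path)
  res
}

read_smiles_file <- function(path, source) {
  lines <- trimws(readLines(path, warn = FALSE))
  ## "#" comments are whole-line only: "#" inside a record is a triple bond
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(structure(list(), n_skipped = 0L))
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1)
  ids <- vapply(seq_along(parts), function(k) {
    p <- parts[[k]]
    if (length(p) >= 2) paste(p[-1], collapse = "_") else paste0("mol_", k)
  }, character(1))
  mols <- molecules_from_smiles(smi, ids, source = source)
  structure(unclass(mols), n_skipped = length(attr(mols, "skipped")))
}

read_sdf_file <- function(path, source) {
  lines <- readLines(path, warn = FALSE)
  ends <- which(trimws(lines) == "$$$$")
  if (length(ends) == 0)
    return(structure(list(), n_skipped = 0L))
  starts <- c(1L, head(ends, -1) + 1L)
  n <- length(ends)
  titles <- character(n)
  blocks <- character(n)
  ids <- character(n)
  for (k in seq_len(n)) {
    rec <- lines[starts[k]:ends[k]]
    titles[k] <- trimws(rec[1])
    tag <- grep("^>\\s*<vscreenr_id>", rec)
    ids[k] <- if (length(tag) > 0 && tag[1] < length(rec)) trimws(rec[tag[1] + 1])
    else if (nzchar(titles[k])) titles[k] else paste0("mol_", k)
    rec[1] <- paste0("r", k)  # unique title so conversion output realigns
    blocks[k] <- paste(rec, collapse = "\n")
  }
  res <- tryCatch(
    ob_convert("SDF", "CAN", paste0(paste(blocks, collapse = "\n"), "\n"),
               options = data.frame(names = "d", args = "")),
    error = function(e) "")
  can <- rep(NA_character_, n)
  for (ln in strsplit(res, "\n", fixed = TRUE)[[1]]) {
    p <- strsplit(ln, "[ \t]+")[[1]]
    if (length(p) < 2) next
    k <- suppressWarnings(as.integer(sub("^r", "", p[2])))
    if (!is.na(k) && nzchar(p[1])) can[k] <- p[1]
  }
  can[!is.na(can) & !smiles_is_valid(can)] <- NA_character_
  ok <- which(!is.na(can))
  mols <- if (length(ok) > 0) mols_from_canonical(can[ok], ids[ok], source) else list()
  keep <- !vapply(mols, is.null, logical(1))
  structure(mols[keep], n_skipped = n - sum(keep))
}

#' Write molecules to a file
#'
#' @param mols List of `molecule` objects.
#' @param path Output path.
#' @param format `"smiles"`, `"sdf"`, or `"pdbqt_stub"` (a minimal PDBQT for
#'   the docking adapter's external preparation step; requires or embeds 3D
#'   coordinates).
#' @return Number of records written, invisibly.
#' @export
write_molecules <- function(mols, path, format = c("smiles", "sdf", "pdbqt_stub")) {
  format <- match.arg(format)
  stopifnot(all(vapply(mols, is_molecule, logical(1))))
  con <- tryCatch(file(path, "w"),
                  error = function(e) vs_stop("io", "cannot write %s: %s", path,
                                              conditionMessage(e)))
  on.exit(close(con))
  if (format == "smiles") {
    for (m in mols) writeLines(sprintf("%s %s", m$smiles, m$id), con)
  } else if (format == "sdf") {
    for (m in mols) {
      writeLines(molfile_from_graph(m$atoms, m$bonds, m$coords3d, title = m$id), con)
      writeLines(c("> <vscreenr_id>", m$id, "", "$$$$"), con)
    }
  } else {
    for (m in mols) {
      if (is.null(m$coords3d)) m <- embed_3d(m)
      writeLines(pdbqt_stub_lines(m), con)
    }
  }
  invisible(length(mols))
}

#' Embed 3D coordinates for a molecule
#'
#' Generates a single deterministic conformer through the conversion
#' backend's 3D builder; atom order is preserved, so coordinates align with
#' the molecule's atom table.
#'
#' @param mol A `molecule`.
#' @return The molecule with `coords3d` populated.
#' @export
embed_3d <- function(mol) {
  stopifnot(is_molecule(mol))
  sdftxt <- ob_convert("SMI", "SDF", paste0(mol$smiles, " x\n"),
                       options = data.frame(names = "gen3D", args = ""))
  recs <- parse_molfile_records(sdftxt)
  if (length(recs) == 0)
    vs_stop("encoding", "3D embedding failed for %s", mol$id)
  heavy <- which(recs[[1]]$elements != "H")
  if (length(heavy) != nrow(mol$atoms) ||
      !all(recs[[1]]$elements[heavy] == mol$atoms$element))
    vs_stop("encoding", "3D embedding reordered atoms for %s", mol$id)
  mol$coords3d <- recs[[1]]$coords[heavy, , drop = FALSE]
  mol
}

pdbqt_stub_lines <- function(mol) {
  xyz <- mol$coords3d
  c(sprintf("REMARK  vscreenr pdbqt stub for %s (no charges, no torsion tree)", mol$id),
    "ROOT",
    vapply(seq_len(nrow(mol$atoms)), function(a) {
      sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f  0.00  0.00    %6.3f %-2s",
              a, substr(paste0(mol$atoms$element[a], a), 1, 4),
              xyz[a, 1], xyz[a, 2], xyz[a, 3], 0, mol$atoms$element[a])
    }, character(1)),
    "ENDROOT", "TORSDOF 0")
}

## Protein structures --------------------------------------------------------

new_protein <- function(id, atoms, chains) {
  structure(list(id = id, atoms = atoms, chains = chains),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein %s> %d atoms, %d chain(s): %s\n", x$id, nrow(x$atoms),
              length(x$chains), paste(x$chains, collapse = ",")))
  invisible(x)
}

#' Read a protein structure from a PDB file
#'
#' Loads the ATOM records of the first MODEL; HETATM records are excluded
#' unless `include_het = TRUE`. The element is taken from the element column
#' when present, falling back to the atom-name field.
#'
#' @param path PDB file path.
#' @param include_het Keep HETATM records?
#' @return A `protein_structure` with an atom table (serial, name, residue,
#'   chain, residue number, insertion code, x/y/z, element) and chain set.
#' @export
read_protein <- function(path, include_het = FALSE) {
  if (!file.exists(path)) vs_stop("input", "no such file: %s", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, multi = FALSE)),
                  error = function(e)
                    vs_stop("structure", "cannot parse PDB %s: %s", path,
                            conditionMessage(e)))
  at <- pdb$atom
  if (!include_het) at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0)
    vs_stop("structure", "no %s records in %s",
            if (include_het) "ATOM/HETATM" else "ATOM", path)
  element <- at$elesy
  miss <- is.na(element) | !nzchar(trimws(element))
  element[miss] <- substr(trimws(at$elety[miss]), 1, 1)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resid = at$resid,
    chain = at$chain, resno = at$resno, insert = at$insert %||% "",
    x = at$x, y = at$y, z = at$z, element = trimws(element),
    stringsAsFactors = FALSE)
  if (anyDuplicated(atoms$serial))
    vs_stop("structure", "duplicate atom serial numbers in %s", path)
  if (!all(is.finite(c(atoms$x, atoms$y, atoms$z))))
    vs_stop("structure", "non-finite coordinates in %s", path)
  new_protein(id = tools::file_path_sans_ext(basename(path)), atoms = atoms,
              chains = sort(unique(atoms$chain)))
}
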