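## Docking stage: an adapter contract for an external engine (AutoDock
## Vina-style, invoked as a subprocess) plus a deterministic mock engine so
## the whole pipeline runs and tests offline. Downstream code never
## interprets energies beyond "lower is better".

new_docking_result <- function(ligand_id, pocket_id, poses, engine_tag) {
  poses <- poses[order(vapply(poses, `[[`, numeric(1), "energy"))]
  structure(list(ligand_id = ligand_id, pocket_id = as.integer(pocket_id),
                 binding_energy = poses[[1]]$energy, poses = poses,
                 engine_tag = engine_tag),
            class = "docking_result")
}

#' @export
print.docking_result <- function(x, ...) {
  cat(sprintf("<docking %s @ pocket %d> best %.2f kcal/mol over %d pose(s) [%s]\n",
              x$ligand_id, x$pocket_id, x$binding_energy, length(x$poses),
              x$engine_tag))
  invisible(x)
}

#' Dock a molecule into a search box
#'
#' @param protein A `protein_structure`.
#' @param mol A `molecule`.
#' @param box A `dock_box` (as from [pocket_to_dockbox()]).
#' @param engine A docking engine, e.g. [mock_engine()] or [vina_engine()].
#' @param pocket_id Pocket identifier; defaults to the box's.
#' @return A `docking_result`: best binding energy (kcal/mol) and poses
#'   sorted ascending by energy.
#' @export
dock <- function(protein, mol, box, engine, pocket_id = box$pocket_id) {
  if (!inherits(engine, "docking_engine"))
    vs_stop("parameter", "engine must be a docking_engine")
  if (!inherits(box, "dock_box") || any(box$size <= 0))
    vs_stop("parameter", "invalid docking box")
  poses <- engine$fn(protein, mol, box, pocket_id %||% NA_integer_)
  if (length(poses) == 0)
    vs_stop("docking", "engine %s returned no poses for %s", engine$tag, mol$id)
  new_docking_result(mol$id, pocket_id %||% NA_integer_, poses, engine$tag)
}

#' Deterministic mock docking engine
#'
#' Energies are a pure function of (seed, ligand canonical SMILES,
#' pocket id): a seeded hash mapped into `[-12, -2]` kcal/mol, the typical
#' span of screening outputs. When a `similarity_oracle` is supplied (as in
#' synthetic screens) the energy is `-2 - 10 * oracle(mol)` instead, so that
#' planted actives dock better and recovery is testable. Three poses are
#' produced, offset above the best energy.
#'
#' @param seed Integer folded into the hash.
#' @param similarity_oracle Optional `function(mol) -> [0, 1]`.
#' @return A `docking_engine`.
#' @export
mock_engine <- function(seed = 0, similarity_oracle = NULL) {
  force(seed); force(similarity_oracle)
  fn <- function(protein, mol, box, pocket_id) {
    base <- if (is.null(similarity_oracle)) {
      u <- vs_hash_unit(paste(seed, mol$smiles, pocket_id, sep = "|"))
      -12 + 10 * u
    } else {
      -2 - 10 * similarity_oracle(mol)
    }
    lapply(c(0, 0.7, 1.5), function(off)
      list(coords3d = NULL, energy = base + off))
  }
  structure(list(kind = "mock", fn = fn,
                 tag = sprintf("mock_seed%d%s", as.integer(seed),
                               if (is.null(similarity_oracle)) "" else "_oracle")),
            class = "docking_engine")
}

#' External docking engine adapter
#'
#' Runs an AutoDock Vina compatible binary as a subprocess: the receptor and
#' ligand are written as PDBQT stubs (final preparation is delegated to the
#' engine's ecosystem), a key = value config carries the box, and the result
#' table is parsed from the engine log. The binary is an optional runtime
#' dependency; constructing the adapter fails with an environment error when
#' it is not on the PATH.
#'
#' @param binary Engine executable name or path (default `"vina"`).
#' @param exhaustiveness,num_modes Engine search settings (defaults 8, 9).
#' @param workdir Scratch directory for the per-call files.
#' @return A `docking_engine`.
#' @export
vina_engine <- function(binary = "vina", exhaustiveness = 8, num_modes = 9,
                        workdir = tempdir()) {
  if (Sys.which(binary) == "")
    vs_stop("environment", "docking binary '%s' not found on PATH", binary)
  fn <- function(protein, mol, box, pocket_id) {
    stem <- file.path(workdir, sprintf("dock_%s_p%s", mol$id, pocket_id))
    rec <- paste0(stem, "_receptor.pdbqt")
    lig <- paste0(stem, "_ligand.pdbqt")
    cfg <- paste0(stem, ".cfg")
    logf <- paste0(stem, ".log")
    write_receptor_pdbqt(protein, rec)
    write_molecules(list(mol), lig, format = "pdbqt_stub")
    writeLines(dockbox_config_lines(box, receptor = rec, ligand = lig,
                                    exhaustiveness = exhaustiveness,
                                    num_modes = num_modes), cfg)
    status <- system2(binary, c("--config", cfg), stdout = logf, stderr = logf)
    if (status != 0)
      vs_stop("docking", "engine %s exited with status %d for %s:\n%s",
              binary, status, mol$id,
              paste(readLines(logf, warn = FALSE), collapse = "\n"))
    tab <- parse_vina_log(logf)
    lapply(seq_len(nrow(tab)), function(r)
      list(coords3d = NULL, energy = tab$affinity[r]))
  }
  structure(list(kind = "external", fn = fn, tag = basename(binary)),
            class = "docking_engine")
}

write_receptor_pdbqt <- function(protein, path) {
  at <- protein$atoms
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  0.00  0.00    %6.3f %-2s",
    at$serial, substr(at$name, 1, 4), at$resid, at$chain, at$resno,
    at$x, at$y, at$z, 0, at$element)
  writeLines(c(lines, "TER"), path)
  invisible(path)
}

#' Parse a Vina-style result table from an engine log
#'
#' Looks for the standard `mode | affinity` block and returns its rows in
#' file order.
#'
#' @param path Log file path.
#' @return data.frame with columns `mode` and `affinity` (kcal/mol).
#' @export
parse_vina_log <- function(path) {
  if (!file.exists(path)) vs_stop("input", "no such file: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*mode\\s*\\|\\s*affinity", lines)
  if (length(hdr) == 0)
    vs_stop("docking", "no result table ('mode | affinity' block) in %s", path)
  rows <- list()
  for (ln in lines[(hdr[1] + 1):length(lines)]) {
    m <- regmatches(ln, regexec("^\\s*([0-9]+)\\s+(-?[0-9.]+)", ln))[[1]]
    if (length(m) == 3)
      rows[[length(rows) + 1]] <- data.frame(mode = as.integer(m[2]),
                                             affinity = as.numeric(m[3]))
    else if (length(rows) > 0 && !grepl("^[-+\\s|]*$", ln)) break
  }
  if (length(rows) == 0)
    vs_stop("docking", "result table in %s has no rows", path)
  do.call(rbind, rows)
}
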