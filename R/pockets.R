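## Binding pockets and docking boxes.
##
## Cavity detection itself is external (the pipeline consumes Fpocket's
## on-disk output); this module parses that output into pocket records,
## orders them, and turns pockets into docking search boxes.

new_pocket <- function(pocket_id, centroid, extent, score,
                       n_alpha_spheres = NA_integer_,
                       member_atom_serials = integer(0)) {
  structure(list(pocket_id = as.integer(pocket_id),
                 centroid = as.numeric(centroid),
                 extent = as.numeric(extent),
                 score = as.numeric(score),
                 n_alpha_spheres = as.integer(n_alpha_spheres),
                 member_atom_serials = member_atom_serials),
            class = "pocket")
}

#' @export
print.pocket <- function(x, ...) {
  cat(sprintf("<pocket %d> score=%.3f centroid=(%.1f, %.1f, %.1f) extent=(%.1f, %.1f, %.1f)\n",
              x$pocket_id, x$score, x$centroid[1], x$centroid[2], x$centroid[3],
              x$extent[1], x$extent[2], x$extent[3]))
  invisible(x)
}

#' Parse an Fpocket output directory into pocket records
#'
#' Expects the Fpocket on-disk dialect: per-pocket atom files
#' `pocket<N>_atm.pdb` (searched recursively, so both a flat directory and
#' the usual `<name>_out/pockets/` layout work) and an `*_info.txt` file with
#' `Pocket <N> :` blocks containing a `Score :` line. The pocket centroid is
#' the unweighted mean of the atom coordinates in the pocket file and the
#' extent is the per-axis max minus min.
#'
#' @param dir Directory path.
#' @return List of `pocket` objects sorted by descending score, ties broken
#'   by ascending pocket number. Pocket files without atoms are skipped and
#'   logged.
#' @export
parse_fpocket_output <- function(dir) {
  if (!dir.exists(dir)) vs_stop("input", "no such directory: %s", dir)
  atm <- list.files(dir, pattern = "^pocket[0-9]+_atm\\.pdb$",
                    recursive = TRUE, full.names = TRUE)
  info <- list.files(dir, pattern = "_info\\.txt$",
                     recursive = TRUE, full.names = TRUE)
  if (length(atm) == 0)
    vs_stop("input", "no pocket atom files (pocket<N>_atm.pdb) under %s", dir)
  scores <- parse_fpocket_info(if (length(info) > 0) info[1] else NULL)
  pockets <- list()
  for (f in atm) {
    pid <- as.integer(sub("^pocket([0-9]+)_atm\\.pdb$", "\\1", basename(f)))
    coords <- tryCatch({
      pdb <- suppressWarnings(bio3d::read.pdb(f, multi = FALSE))
      at <- pdb$atom
      cbind(at$x, at$y, at$z)
    }, error = function(e) NULL)
    if (is.null(coords) || nrow(coords) == 0) {
      vs_log("pockets", "pocket file %s has no atoms; skipped", basename(f))
      next
    }
    serials <- tryCatch(suppressWarnings(bio3d::read.pdb(f, multi = FALSE))$atom$eleno,
                        error = function(e) integer(0))
    pockets[[length(pockets) + 1]] <- new_pocket(
      pocket_id = pid,
      centroid = colMeans(coords),
      extent = apply(coords, 2, max) - apply(coords, 2, min),
      score = scores[as.character(pid)] %||% NA_real_,
      member_atom_serials = serials)
  }
  if (length(pockets) == 0)
    vs_stop("input", "all pocket files under %s were empty", dir)
  score <- vapply(pockets, function(p) ifelse(is.na(p$score), -Inf, p$score),
                  numeric(1))
  pid <- vapply(pockets, `[[`, integer(1), "pocket_id")
  pockets[order(-score, pid)]
}

## "Pocket <N> :" blocks with "Score :" lines -> named numeric vector.
parse_fpocket_info <- function(path) {
  if (is.null(path) || !file.exists(path)) return(numeric(0))
  lines <- readLines(path, warn = FALSE)
  scores <- numeric(0)
  current <- NA_character_
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*Pocket\\s+([0-9]+)\\s*:", ln))[[1]]
    if (length(m) == 2) { current <- m[2]; next }
    m <- regmatches(ln, regexec("^\\s*Score\\s*:\\s*(-?[0-9.]+)", ln))[[1]]
    if (length(m) == 2 && !is.na(current)) scores[current] <- as.numeric(m[2])
  }
  scores
}

#' Select the top-scoring pockets
#'
#' @param pockets Score-sorted pocket list (as from [parse_fpocket_output()]).
#' @param top_m Number of pockets to keep; `Inf` keeps all (the default
#'   behaviour of looping over every predicted pocket).
#' @return The first `min(top_m, length(pockets))` pockets.
#' @export
select_pockets <- function(pockets, top_m = Inf) {
  if (length(pockets) == 0)
    vs_stop("pocket", "empty pocket list: the pipeline cannot proceed")
  if (!is.numeric(top_m) || length(top_m) != 1 || is.na(top_m) || top_m < 1)
    vs_stop("parameter", "top_m must be >= 1")
  pockets[seq_len(min(top_m, length(pockets)))]
}

#' Build a docking search box from a pocket
#'
#' The box is centred on the pocket centroid; each edge is the pocket extent
#' plus `2 * margin`, floored at `min_edge`.
#'
#' @param p A `pocket`.
#' @param margin Padding in angstroms added on each side (default 4).
#' @param min_edge Minimum box edge in angstroms (default 10).
#' @return A `dock_box` with `center`, `size` and the originating
#'   `pocket_id`.
#' @export
pocket_to_dockbox <- function(p, margin = 4, min_edge = 10) {
  stopifnot(inherits(p, "pocket"))
  if (!is.numeric(margin) || margin < 0) vs_stop("parameter", "margin must be >= 0")
  size <- pmax(p$extent + 2 * margin, min_edge)
  structure(list(center = p$centroid, size = size, pocket_id = p$pocket_id),
            class = "dock_box")
}

#' @export
print.dock_box <- function(x, ...) {
  cat(sprintf("<dock_box pocket %s> center=(%.1f, %.1f, %.1f) size=(%.1f, %.1f, %.1f)\n",
              x$pocket_id %||% "?", x$center[1], x$center[2], x$center[3],
              x$size[1], x$size[2], x$size[3]))
  invisible(x)
}

## Serialize a box to the docking adapter's key = value config dialect.
dockbox_config_lines <- function(box, receptor = NULL, ligand = NULL,
                                 exhaustiveness = 8, num_modes = 9) {
  c(if (!is.null(receptor)) sprintf("receptor = %s", receptor),
    if (!is.null(ligand)) sprintf("ligand = %s", ligand),
    sprintf("center_x = %.3f", box$center[1]),
    sprintf("center_y = %.3f", box$center[2]),
    sprintf("center_z = %.3f", box$center[3]),
    sprintf("size_x = %.3f", box$size[1]),
    sprintf("size_y = %.3f", box$size[2]),
    sprintf("size_z = %.3f", box$size[3]),
    sprintf("exhaustiveness = %d", exhaustiveness),
    sprintf("num_modes = %d", num_modes))
}
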