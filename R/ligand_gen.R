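## Ligand generation: the LG(pocket) contract of Phase 1.
##
## The production generator (a pocket-conditioned generative model) is
## external to this package; the contract accepts any provider. Two are
## shipped: a file-based adapter that reads an SDF produced by an external
## tool, and a seeded synthetic provider that draws molecules by random
## local edits of scaffolds. The synthetic provider ignores pocket geometry
## except for tagging — pocket conditioning is exactly the externalised
## piece — and exists so the whole pipeline is exercisable offline.

new_generated_ligand <- function(molecule, pocket_id, binding_energy = NA_real_,
                                 generator_tag = "unknown") {
  structure(list(molecule = molecule, pocket_id = as.integer(pocket_id),
                 binding_energy = binding_energy, generator_tag = generator_tag),
            class = "generated_ligand")
}

#' @export
print.generated_ligand <- function(x, ...) {
  cat(sprintf("<generated ligand %s @ pocket %d> %s  BE=%s [%s]\n",
              x$molecule$id, x$pocket_id, x$molecule$smiles,
              if (is.na(x$binding_energy)) "unset"
              else sprintf("%.2f kcal/mol", x$binding_energy),
              x$generator_tag))
  invisible(x)
}

#' Generate candidate ligands for a pocket
#'
#' @param pocket A `pocket` the ligands are conditioned on (tagging only for
#'   the synthetic provider).
#' @param n Number of ligands requested (>= 1).
#' @param seed Seed; generation is deterministic for fixed
#'   (seed, provider, pocket).
#' @param provider A `ligand_provider` ([synthetic_provider()] or
#'   [sdf_provider()]).
#' @return List of `generated_ligand` objects (at most `n`; invalid
#'   generations are dropped and logged). Binding energies are unset until
#'   the docking stage.
#' @export
generate_ligands <- function(pocket, n, seed, provider) {
  if (!is_count(n, 1)) vs_stop("parameter", "n must be an integer >= 1")
  if (!inherits(provider, "ligand_provider"))
    vs_stop("parameter", "provider must be a ligand_provider")
  pid <- if (inherits(pocket, "pocket")) pocket$pocket_id else as.integer(pocket)
  mols <- tryCatch(provider$generate(n, seed, pid),
                   vs_error = function(e) stop(e),
                   error = function(e)
                     vs_stop("generation", "provider %s failed: %s",
                             provider$tag, conditionMessage(e)))
  if (length(mols) < n)
    vs_log("ligand_gen", "pocket %d: %d of %d requested ligands produced",
           pid, length(mols), n)
  lapply(seq_along(mols), function(k) {
    m <- mols[[k]]
    m$source <- "generated"
    new_generated_ligand(m, pid, generator_tag = provider$tag)
  })
}

#' File-based generator adapter
#'
#' Wraps an SDF produced by an external generative tool as a ligand
#' provider; pocket conditioning is communicated to the external tool
#' out-of-band (pocket PDB + box config, see [dockbox_config_lines()]).
#'
#' @param path SDF file path.
#' @return A `ligand_provider` yielding the file's molecules (first `n`).
#' @export
sdf_provider <- function(path) {
  if (!file.exists(path)) vs_stop("input", "no such file: %s", path)
  structure(list(
    tag = sprintf("sdf:%s", basename(path)),
    generate = function(n, seed, pocket_id) {
      mols <- read_molecules(path, "sdf", source = "generated")
      mols[seq_len(min(n, length(mols)))]
    }), class = "ligand_provider")
}

## Fragment table for the edit moves: small substituents a medicinal chemist
## would decorate a scaffold with. `attach` is the atom bonded to the host.
default_fragments <- function() {
  frag <- function(el, bonds = NULL) {
    list(atoms = data.frame(element = el, charge = 0L, aromatic = FALSE,
                            hcount = NA_integer_, stringsAsFactors = FALSE),
         bonds = bonds %||% data.frame(i = integer(0), j = integer(0),
                                       order = integer(0)),
         attach = 1L)
  }
  list(
    methyl = frag("C"),
    hydroxyl = frag("O"),
    amino = frag("N"),
    fluoro = frag("F"),
    chloro = frag("Cl"),
    ethyl = frag(c("C", "C"), data.frame(i = 1L, j = 2L, order = 1L)),
    methoxy = frag(c("O", "C"), data.frame(i = 1L, j = 2L, order = 1L)),
    carboxyl = frag(c("C", "O", "O"),
                    data.frame(i = c(1L, 1L), j = c(2L, 3L), order = c(2L, 1L))),
    nitrile = frag(c("C", "N"), data.frame(i = 1L, j = 2L, order = 3L)),
    acetyl = frag(c("C", "O", "C"),
                  data.frame(i = c(1L, 1L), j = c(2L, 3L), order = c(2L, 1L)))
  )
}

## Default scaffold set for the synthetic provider: small drug-like cores.
default_scaffolds <- function() {
  c("c1ccccc1CC(=O)O",        # arylacetic acid
    "c1ccc2[nH]ccc2c1",       # indole
    "c1ccncc1CN",             # aminomethylpyridine
    "O=C(N)c1ccccc1O",        # salicylamide
    "c1ccc(cc1)S(=O)(=O)N",   # benzenesulfonamide
    "C1CCNCC1CCO",            # piperidine ethanol
    "c1cnc2ccccc2n1",         # quinoxaline
    "CC(=O)Nc1ccccc1")        # acetanilide
}

## One random local edit of a kekulized molecular graph. Aromatic flags are
## ignored during editing (the graph is treated purely through its bond
## orders); chemical validity is decided by the canonicalization backend
## afterwards. Returns the edited graph, or NULL if no move was feasible.
apply_random_edit <- function(g) {
  atoms <- g$atoms; bonds <- g$bonds
  plain <- atoms
  plain$aromatic <- FALSE
  h <- infer_hcounts(plain, bonds, explicit = NULL)
  ops <- sample(c("substitute", "add_bond", "remove_bond", "fragment"))
  for (op in ops) {
    if (op == "substitute") {
      bsum <- numeric(nrow(atoms))
      if (nrow(bonds) > 0) for (r in seq_len(nrow(bonds))) {
        bsum[bonds$i[r]] <- bsum[bonds$i[r]] + bonds$order[r]
        bsum[bonds$j[r]] <- bsum[bonds$j[r]] + bonds$order[r]
      }
      cand <- which(atoms$charge == 0)
      if (length(cand) == 0) next
      a <- if (length(cand) == 1) cand else sample(cand, 1)
      pool <- c("C", "N", "O", "S", "F", "Cl")
      pool <- pool[pool != atoms$element[a]]
      if (atoms$aromatic[a]) pool <- intersect(pool, c("C", "N"))
      ok <- vapply(pool, function(e)
        max(DEFAULT_VALENCES[[e]]) >= bsum[a], logical(1))
      pool <- pool[ok]
      if (length(pool) == 0) next
      atoms$element[a] <- if (length(pool) == 1) pool else sample(pool, 1)
      return(list(atoms = atoms, bonds = bonds))
    } else if (op == "add_bond") {
      free <- which(h >= 1)
      if (length(free) < 2) next
      pairs <- expand.grid(a = free, b = free)
      pairs <- pairs[pairs$a < pairs$b, , drop = FALSE]
      if (nrow(bonds) > 0) {
        key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
        pairs <- pairs[!paste(pairs$a, pairs$b) %in% key, , drop = FALSE]
      }
      if (nrow(pairs) == 0) next
      p <- pairs[sample(nrow(pairs), 1), ]
      bonds <- rbind(bonds, data.frame(i = p$a, j = p$b, order = 1L))
      return(list(atoms = atoms, bonds = bonds))
    } else if (op == "remove_bond") {
      cand <- which(bonds$order == 1L)
      cand <- cand[vapply(cand, function(r)
        graph_connected_without(nrow(atoms), bonds, r), logical(1))]
      if (length(cand) == 0) next
      r <- if (length(cand) == 1) cand else sample(cand, 1)
      bonds <- bonds[-r, , drop = FALSE]
      return(list(atoms = atoms, bonds = bonds))
    } else {
      hosts <- which(h >= 1)
      if (length(hosts) == 0) next
      a <- if (length(hosts) == 1) hosts else sample(hosts, 1)
      fr <- default_fragments()[[sample(length(default_fragments()), 1)]]
      off <- nrow(atoms)
      atoms <- rbind(atoms, fr$atoms)
      if (nrow(fr$bonds) > 0)
        bonds <- rbind(bonds, data.frame(i = fr$bonds$i + off,
                                         j = fr$bonds$j + off,
                                         order = fr$bonds$order))
      bonds <- rbind(bonds, data.frame(i = a, j = fr$attach + off, order = 1L))
      return(list(atoms = atoms, bonds = bonds))
    }
  }
  NULL
}

## Is the bond graph still connected after dropping bond row `drop`?
graph_connected_without <- function(n, bonds, drop) {
  b <- bonds[-drop, , drop = FALSE]
  if (n <= 1) return(TRUE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(b))) {
    adj[[b$i[r]]] <- c(adj[[b$i[r]]], b$j[r])
    adj[[b$j[r]]] <- c(adj[[b$j[r]]], b$i[r])
  }
  ## only the two endpoints of the dropped bond can get separated
  from <- bonds$i[drop]; to <- bonds$j[drop]
  seen <- logical(n); seen[from] <- TRUE
  queue <- from
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) {
      if (w == to) return(TRUE)
      seen[w] <- TRUE; queue <- c(queue, w)
    }
  }
  FALSE
}

## Apply `n_edits` random edits to a molecule's graph and return the batch
## of candidate graphs' canonical SMILES (NA where the backend rejects).
edited_smiles_batch <- function(mols, n_edits) {
  graphs <- vector("list", length(mols))
  for (k in seq_along(mols)) {
    g <- list(atoms = mols[[k]]$atoms, bonds = mols[[k]]$bonds)
    for (e in seq_len(n_edits[k])) {
      g2 <- apply_random_edit(g)
      if (is.null(g2)) break
      g <- g2
    }
    graphs[[k]] <- g
  }
  canonical_from_graphs(graphs)
}

#' Seeded synthetic ligand provider
#'
#' Draws molecules by applying 1 to `max_edits` random local edits to
#' scaffolds: atom substitutions among C/N/O/S/F/Cl, single-bond additions
#' and ring-bond removals that preserve connectivity, and attachment of
#' small fragments from a fixed table. Every emitted molecule has passed the
#' canonicalization backend's valence sanity check; infeasible or rejected
#' edits are resampled with bounded retries. Draws are deterministic for a
#' fixed (provider seed, call seed, pocket).
#'
#' @param seed Provider base seed.
#' @param scaffold_set Character vector of scaffold SMILES (default: a small
#'   set of drug-like cores).
#' @param max_edits Maximum edits per draw (default 3).
#' @return A `ligand_provider`.
#' @export
synthetic_provider <- function(seed, scaffold_set = default_scaffolds(),
                               max_edits = 3) {
  if (length(scaffold_set) == 0)
    vs_stop("parameter", "scaffold_set must be non-empty")
  scaffolds <- molecules_from_smiles(scaffold_set, source = "fixture")
  if (length(scaffolds) < length(scaffold_set))
    vs_stop("parameter", "invalid scaffold SMILES at position(s): %s",
            paste(attr(scaffolds, "skipped"), collapse = ", "))
  force(max_edits)
  base_seed <- seed
  generate <- function(n, seed, pocket_id) {
    eff <- derive_seed(derive_seed(base_seed, paste0("call", seed)),
                       paste0("pocket", pocket_id))
    with_seed(eff, {
      out <- character(0)
      tries <- 0
      while (length(out) < n && tries < 8) {
        tries <- tries + 1
        batch <- max(n - length(out), 8)
        picks <- sample(length(scaffolds), batch, replace = TRUE)
        nedit <- sample(max_edits, batch, replace = TRUE)
        smi <- edited_smiles_batch(scaffolds[picks], nedit)
        out <- c(out, smi[!is.na(smi)])
      }
      out <- out[seq_len(min(n, length(out)))]
      molecules_from_smiles(out, ids = sprintf("gen_p%s_%03d", pocket_id,
                                               seq_along(out)),
                            source = "generated")
    })
  }
  structure(list(tag = sprintf("synthetic_s%s", format(seed)),
                 generate = generate, scaffolds = scaffolds),
            class = "ligand_provider")
}
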