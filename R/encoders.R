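## Molecular encoders and similarity measures.
##
## Three comparable representations are provided, mirroring the screening
## modes: binary circular (Morgan-style) fingerprints compared with the
## Tanimoto coefficient, count-valued circular fingerprints compared with
## cosine similarity, and a deterministic seeded message-passing graph
## encoder that fills the neural-encoder slot of the pipeline (the slot a
## trained GNN/GAT/EGNN/Equiformer would occupy) compared with cosine.
##
## The circular fingerprint follows the standard ECFP construction: an
## initial per-atom invariant (element, degree, bonded valence, charge,
## hydrogen count, aromaticity) is iteratively re-hashed together with the
## sorted (bond class, neighbour invariant) pairs for `radius` rounds, and
## every intermediate identifier is folded into `n_bits` buckets. Bond
## classes treat any bond between two aromatic atoms as aromatic, so the
## result does not depend on the kekulization the IO backend emitted. Bit
## positions are deterministic for a given canonical SMILES but are not
## interchangeable with other toolkits' bit assignments.

FP_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B",
                 "Si", "Se", "Na", "K", "Mg", "Ca")

## Identifiers of all circular substructures up to `radius` (one per atom
## per round, round 0 included), as numbers in [0, 2^31 - 1).
mol_circular_ids <- function(mol, radius = 2) {
  atoms <- mol$atoms; bonds <- mol$bonds
  n <- nrow(atoms)
  bw2 <- as.integer(round(bond_weights(atoms, bonds) * 2))  # 2,3,4,6
  nb <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      nb[[bonds$i[r]]] <- rbind(nb[[bonds$i[r]]], c(bw2[r], bonds$j[r]))
      nb[[bonds$j[r]]] <- rbind(nb[[bonds$j[r]]], c(bw2[r], bonds$i[r]))
    }
  }
  elem <- match(atoms$element, FP_ELEMENTS, nomatch = 99L)
  degree <- vapply(nb, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  bval <- numeric(n)
  if (nrow(bonds) > 0) for (a in seq_len(n))
    if (!is.null(nb[[a]])) bval[a] <- sum(nb[[a]][, 1])
  inv <- vs_hash_mix(vs_hash_mix(vs_hash_mix(vs_hash_mix(vs_hash_mix(vs_hash_mix(
    rep(17, n), elem), degree), bval), atoms$charge + 16L), atoms$hcount),
    as.integer(atoms$aromatic))
  ids <- inv
  if (radius > 0) {
    for (r in seq_len(radius)) {
      newinv <- numeric(n)
      for (a in seq_len(n)) {
        h <- vs_hash_mix(vs_hash_mix(23, r), inv[a])
        e <- nb[[a]]
        if (!is.null(e)) {
          key <- e[, 1] * VS_HASH_MOD + inv[e[, 2]]
          ord <- order(key)
          for (k in ord) {
            h <- vs_hash_mix(h, e[k, 1])
            h <- vs_hash_mix(h, inv[e[k, 2]])
          }
        }
        newinv[a] <- h
      }
      inv <- newinv
      ids <- c(ids, inv)
    }
  }
  ids
}

#' Circular (Morgan-style) fingerprint of a molecule
#'
#' @param mol A `molecule`.
#' @param radius Neighbourhood radius in bonds (default 2, the de-facto
#'   standard, comparable to ECFP4).
#' @param n_bits Folded length (default 2048).
#' @param counts Keep substructure multiplicities? When `FALSE` (default)
#'   the fingerprint is binary.
#' @return A `fingerprint` object with set-bit positions (`on`, 1-based),
#'   optional per-bit counts, `n_bits`, `radius` and `mol_id`.
#' @export
morgan_fingerprint <- function(mol, radius = 2, n_bits = 2048, counts = FALSE) {
  if (!is_molecule(mol)) vs_stop("encoding", "not a molecule")
  if (!is_count(radius, 0) || !is_count(n_bits, 1))
    vs_stop("parameter", "radius must be >= 0 and n_bits >= 1")
  ids <- mol_circular_ids(mol, radius)
  bit <- as.integer(ids %% n_bits) + 1L
  fp <- list(on = sort(unique(bit)), n_bits = as.integer(n_bits),
             radius = as.integer(radius), mol_id = mol$id)
  if (counts) fp$counts <- table(bit)
  structure(fp, class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint %s> %d/%d bits set (radius %d)%s\n", x$mol_id,
              length(x$on), x$n_bits, x$radius,
              if (!is.null(x$counts)) ", with counts" else ""))
  invisible(x)
}

#' Tanimoto coefficient between two binary fingerprints
#'
#' `|A intersect B| / |A union B|`; defined as 0 when both fingerprints are
#' empty.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!inherits(a, "fingerprint") || !inherits(b, "fingerprint"))
    vs_stop("encoding", "tanimoto expects fingerprint objects")
  if (a$n_bits != b$n_bits)
    vs_stop("encoding", "fingerprint length mismatch (%d vs %d)", a$n_bits, b$n_bits)
  ni <- length(intersect(a$on, b$on))
  nu <- length(a$on) + length(b$on) - ni
  if (nu == 0) 0 else ni / nu
}

#' Cosine similarity between two embeddings or numeric vectors
#'
#' @param a,b `embedding` objects (or plain numeric vectors) of equal
#'   dimension; zero vectors are an error.
#' @return Similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  va <- if (inherits(a, "embedding")) a$vector else a
  vb <- if (inherits(b, "embedding")) b$vector else b
  if (!is.numeric(va) || !is.numeric(vb) || length(va) != length(vb))
    vs_stop("encoding", "embedding dimension mismatch")
  na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) vs_stop("encoding", "zero vector in cosine similarity")
  sum(va * vb) / (na * nb)
}

## Count vector (sparse, named by bit) from a counts fingerprint.
fp_count_vector <- function(fp) {
  v <- numeric(fp$n_bits)
  if (!is.null(fp$counts)) v[as.integer(names(fp$counts))] <- as.numeric(fp$counts)
  else v[fp$on] <- 1
  v
}

#' Deterministic reference graph encoder
#'
#' A seeded, untrained message-passing encoder that fills the pipeline's
#' neural-encoder contract. Atom features are a one-hot element (16 common
#' elements plus "other"), a one-hot degree clamped to 0–5, and the aromatic
#' flag. Each round sums neighbour features into each atom, applies a fixed
#' seeded random linear map and a tanh nonlinearity; the molecule embedding
#' is the atom-sum pooling passed through a seeded projection to dimension
#' `d`. The encoder is permutation invariant and a pure function of
#' (canonical SMILES, d, rounds, seed); it ignores 3D coordinates.
#'
#' @param mol A `molecule`.
#' @param d Embedding dimension (default 64).
#' @param rounds Message-passing rounds (default 2).
#' @param seed Seed for the random linear maps (default 42).
#' @return An `embedding` with fields `vector`, `encoder_tag`, `mol_id`.
#' @export
reference_graph_encoder <- function(mol, d = 64, rounds = 2, seed = 42) {
  if (!is_molecule(mol)) vs_stop("encoding", "not a molecule")
  n <- nrow(mol$atoms)
  nf <- 17 + 6 + 1
  H <- matrix(0, n, nf)
  ei <- match(mol$atoms$element, FP_ELEMENTS, nomatch = 17L)
  H[cbind(seq_len(n), ei)] <- 1
  deg <- integer(n)
  if (nrow(mol$bonds) > 0) {
    tb <- table(c(mol$bonds$i, mol$bonds$j))
    deg[as.integer(names(tb))] <- as.integer(tb)
  }
  H[cbind(seq_len(n), 17 + pmin(deg, 5L) + 1L)] <- 1
  H[, nf] <- as.numeric(mol$atoms$aromatic)
  W <- with_seed(seed, c(
    lapply(seq_len(rounds), function(r) matrix(stats::rnorm(nf * nf, sd = 1 / sqrt(nf)), nf, nf)),
    list(matrix(stats::rnorm(nf * d, sd = 1 / sqrt(nf)), nf, d))))
  A <- matrix(0, n, n)
  if (nrow(mol$bonds) > 0) {
    w <- bond_weights(mol$atoms, mol$bonds)
    A[cbind(mol$bonds$i, mol$bonds$j)] <- w
    A[cbind(mol$bonds$j, mol$bonds$i)] <- w
  }
  for (r in seq_len(rounds)) H <- tanh((H + A %*% H) %*% W[[r]])
  v <- as.numeric(colSums(H) %*% W[[rounds + 1]])
  if (!all(is.finite(v)) || sum(abs(v)) == 0)
    vs_stop("encoding", "degenerate embedding for %s", mol$id)
  structure(list(vector = v,
                 encoder_tag = sprintf("refgraph_d%d_r%d_s%d", d, rounds, seed),
                 mol_id = mol$id),
            class = "embedding")
}

## Binary fingerprint 0/1 matrix (n_mols x n_bits) for a molecule list.
fp_bit_matrix <- function(mols, radius = 2, n_bits = 2048) {
  M <- matrix(0, length(mols), n_bits)
  for (k in seq_along(mols))
    M[k, morgan_fingerprint(mols[[k]], radius, n_bits)$on] <- 1
  rownames(M) <- vapply(mols, `[[`, character(1), "id")
  M
}

fp_count_matrix <- function(mols, radius = 2, n_bits = 2048) {
  M <- matrix(0, length(mols), n_bits)
  for (k in seq_along(mols))
    M[k, ] <- fp_count_vector(morgan_fingerprint(mols[[k]], radius, n_bits,
                                                 counts = TRUE))
  rownames(M) <- vapply(mols, `[[`, character(1), "id")
  M
}

embedding_matrix <- function(mols, d = 64, rounds = 2, seed = 42) {
  M <- t(vapply(mols, function(m) reference_graph_encoder(m, d, rounds, seed)$vector,
                numeric(d)))
  rownames(M) <- vapply(mols, `[[`, character(1), "id")
  M
}

#' Similarity matrix between a query set and a library
#'
#' @param queries,library Non-empty lists of `molecule` objects.
#' @param mode `"tanimoto"` (binary circular fingerprints), `"morgan_cosine"`
#'   (count fingerprints, cosine), or `"graph_cosine"` (reference graph
#'   encoder, cosine).
#' @param radius,n_bits Fingerprint parameters (fingerprint modes).
#' @param d,rounds,seed Encoder parameters (`graph_cosine` mode).
#' @return Matrix of similarities, `length(library)` rows by
#'   `length(queries)` columns, with molecule ids as dimnames.
#' @export
similarity_matrix <- function(queries, library,
                              mode = c("tanimoto", "morgan_cosine", "graph_cosine"),
                              radius = 2, n_bits = 2048,
                              d = 64, rounds = 2, seed = 42) {
  mode <- match.arg(mode)
  if (length(queries) == 0 || length(library) == 0)
    vs_stop("encoding", "similarity_matrix needs non-empty query and library sets")
  if (mode == "tanimoto") {
    Q <- fp_bit_matrix(queries, radius, n_bits)
    L <- fp_bit_matrix(library, radius, n_bits)
    inter <- L %*% t(Q)
    uni <- outer(rowSums(L), rowSums(Q), "+") - inter
    S <- ifelse(uni == 0, 0, inter / uni)
  } else if (mode == "morgan_cosine") {
    Q <- fp_count_matrix(queries, radius, n_bits)
    L <- fp_count_matrix(library, radius, n_bits)
    S <- cosine_cross(L, Q)
  } else {
    Q <- embedding_matrix(queries, d, rounds, seed)
    L <- embedding_matrix(library, d, rounds, seed)
    S <- cosine_cross(L, Q)
  }
  dimnames(S) <- list(vapply(library, `[[`, character(1), "id"),
                      vapply(queries, `[[`, character(1), "id"))
  S
}

cosine_cross <- function(L, Q) {
  nl <- sqrt(rowSums(L^2)); nq <- sqrt(rowSums(Q^2))
  if (any(nl == 0))
    vs_stop("encoding", "zero vector for library molecule(s): %s",
            paste(rownames(L)[nl == 0], collapse = ", "))
  if (any(nq == 0))
    vs_stop("encoding", "zero vector for query molecule(s): %s",
            paste(rownames(Q)[nq == 0], collapse = ", "))
  (L %*% t(Q)) / outer(nl, nq)
}
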