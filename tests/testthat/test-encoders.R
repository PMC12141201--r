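test_that("fingerprints are deterministic and depend only on the canonical form", {
  m1 <- molecules_from_smiles("CCO", "a")[[1]]
  m2 <- molecules_from_smiles("OCC", "b")[[1]]
  expect_identical(morgan_fingerprint(m1)$on, morgan_fingerprint(m1)$on)
  expect_identical(morgan_fingerprint(m1)$on, morgan_fingerprint(m2)$on)
  ## methane still sets at least one bit
  ch4 <- molecules_from_smiles("C")[[1]]
  expect_gte(length(morgan_fingerprint(ch4, radius = 2)$on), 1)
})

test_that("fingerprints are invariant to the input representation (SMILES vs SDF)", {
  mols <- fixture_molecules()
  tf <- tempfile(fileext = ".sdf")
  write_molecules(mols, tf, "sdf")
  back <- read_molecules(tf, "sdf")
  for (k in seq_along(mols))
    expect_identical(morgan_fingerprint(back[[k]])$on,
                     morgan_fingerprint(mols[[k]])$on)
})

test_that("tanimoto matches brute-force set arithmetic on random pairs", {
  ## spec'd arithmetic cases
  fp <- function(on, n = 16) structure(list(on = on, n_bits = n, radius = 2L,
                                            mol_id = "x"), class = "fingerprint")
  expect_identical(tanimoto(fp(1:3), fp(1:3)), 1)
  expect_identical(tanimoto(fp(1:3), fp(4:6)), 0)
  expect_identical(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4, 5))), 0.4)
  expect_identical(tanimoto(fp(integer(0)), fp(integer(0))), 0)
  expect_error(tanimoto(fp(1:3, 16), fp(1:3, 32)), class = "vs_encoding_error")
  ## 1000 random pairs against an independent set-arithmetic oracle
  set.seed(401)
  for (rep in 1:1000) {
    pr <- random_fp_pair()
    ni <- sum(pr$a$on %in% pr$b$on)
    nu <- length(union(pr$a$on, pr$b$on))
    expected <- if (nu == 0) 0 else ni / nu
    expect_identical(tanimoto(pr$a, pr$b), expected)
    expect_identical(tanimoto(pr$b, pr$a), expected)  # symmetry
  }
})

test_that("cosine similarity matches vector arithmetic and rejects zero vectors", {
  emb <- function(v) structure(list(vector = v, encoder_tag = "t", mol_id = "m"),
                               class = "embedding")
  expect_equal(cosine_similarity(emb(c(1, 2, 3)), emb(c(1, 2, 3))), 1)
  expect_equal(cosine_similarity(emb(c(1, 0)), emb(c(0, 1))), 0)
  expect_equal(cosine_similarity(emb(c(1, 1)), emb(c(1, 0))), 1 / sqrt(2))
  expect_error(cosine_similarity(emb(c(0, 0)), emb(c(1, 0))),
               class = "vs_encoding_error")
  set.seed(402)
  for (rep in 1:1000) {
    a <- stats::rnorm(8); b <- stats::rnorm(8)
    expect_equal(cosine_similarity(emb(a), emb(b)),
                 sum(a * b) / sqrt(sum(a^2) * sum(b^2)), tolerance = 1e-12)
  }
})

test_that("the reference graph encoder is deterministic and permutation invariant", {
  mols <- fixture_molecules()
  for (m in mols) {
    e1 <- reference_graph_encoder(m)
    expect_identical(e1$vector, reference_graph_encoder(m)$vector)
    expect_equal(cosine_similarity(e1, e1), 1)
    ## permute atom order: same embedding within numerical tolerance
    n <- nrow(m$atoms)
    perm <- sample(n)
    inv <- order(perm)
    m2 <- m
    m2$atoms <- m$atoms[perm, , drop = FALSE]
    rownames(m2$atoms) <- NULL
    m2$bonds$i <- inv[m$bonds$i]
    m2$bonds$j <- inv[m$bonds$j]
    e2 <- reference_graph_encoder(m2)
    expect_equal(e1$vector, e2$vector, tolerance = 1e-9)
  }
  ## different seeds give different encoders
  expect_false(isTRUE(all.equal(reference_graph_encoder(mols[[1]], seed = 1)$vector,
                                reference_graph_encoder(mols[[1]], seed = 2)$vector)))
})

test_that("similarity matrices equal element-wise brute force in every mode", {
  set.seed(403)
  provider <- synthetic_provider(9)
  lib <- provider$generate(30, 2, 1L)
  qry <- provider$generate(10, 3, 2L)
  for (mode in c("tanimoto", "morgan_cosine", "graph_cosine")) {
    S <- similarity_matrix(qry, lib, mode = mode)
    expect_identical(dim(S), c(30L, 10L))
    for (i in sample(30, 6)) for (j in sample(10, 4)) {
      expected <- switch(mode,
        tanimoto = tanimoto(morgan_fingerprint(lib[[i]]),
                            morgan_fingerprint(qry[[j]])),
        morgan_cosine = {
          va <- vscreenr:::fp_count_vector(morgan_fingerprint(lib[[i]], counts = TRUE))
          vb <- vscreenr:::fp_count_vector(morgan_fingerprint(qry[[j]], counts = TRUE))
          sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
        },
        graph_cosine = cosine_similarity(reference_graph_encoder(lib[[i]]),
                                         reference_graph_encoder(qry[[j]])))
      expect_equal(S[i, j], expected, tolerance = 1e-12)
    }
  }
  ## library == queries: unit diagonal in tanimoto mode
  S <- similarity_matrix(lib, lib, mode = "tanimoto")
  expect_equal(unname(diag(S)), rep(1, 30))
  ## single pair reduces to the pairwise call
  S1 <- similarity_matrix(qry[1], lib[1], mode = "tanimoto")
  expect_equal(S1[1, 1], tanimoto(morgan_fingerprint(lib[[1]]),
                                  morgan_fingerprint(qry[[1]])))
})

test_that("tanimoto equals one exactly iff fingerprints coincide and are non-empty", {
  set.seed(404)
  for (rep in 1:100) {
    pr <- random_fp_pair()
    t <- tanimoto(pr$a, pr$b)
    expect_gte(t, 0); expect_lte(t, 1)
    if (t == 1) expect_identical(pr$a$on, pr$b$on)
  }
})
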