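small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_screen(11, n_decoys = 120, n_actives = 8, pool_size = 24)
    cache
  }
})

test_that("screens regenerate identically under the same seed and parameters", {
  s1 <- make_screen(11, n_decoys = 30, n_actives = 4, pool_size = 10)
  s2 <- make_screen(11, n_decoys = 30, n_actives = 4, pool_size = 10)
  smi <- function(x) vapply(x$library, `[[`, character(1), "smiles")
  expect_identical(smi(s1), smi(s2))
  expect_identical(vapply(s1$pool, `[[`, numeric(1), "binding_energy"),
                   vapply(s2$pool, `[[`, numeric(1), "binding_energy"))
  expect_identical(s1$approved_ids, s2$approved_ids)
  s3 <- make_screen(12, n_decoys = 30, n_actives = 4, pool_size = 10)
  expect_false(identical(smi(s1), smi(s3)))
})

test_that("screen composition matches the requested parameters", {
  scr <- small_screen()
  expect_length(scr$library, 128)
  expect_length(scr$approved_ids, 8)
  expect_length(scr$pool, 24)
  expect_true(all(scr$approved_ids %in%
                    vapply(scr$library, `[[`, character(1), "id")))
  expect_true(all(startsWith(setdiff(vapply(scr$library, `[[`, character(1), "id"),
                                     scr$approved_ids), "decoy")))
  ## pool energies are set and within the mock engine's range
  be <- vapply(scr$pool, `[[`, numeric(1), "binding_energy")
  expect_true(all(is.finite(be) & be <= -2 & be >= -12))
  ## pockets exist and pool ligands reference them
  pids <- vapply(scr$pockets, `[[`, integer(1), "pocket_id")
  expect_true(all(vapply(scr$pool, `[[`, integer(1), "pocket_id") %in% pids))
})

test_that("planted actives sit closer to the pool than decoys do", {
  scr <- small_screen()
  pool_mols <- lapply(scr$pool, `[[`, "molecule")
  S <- similarity_matrix(pool_mols, scr$library, mode = "tanimoto")
  nearest <- apply(S, 1, max)
  ids <- vapply(scr$library, `[[`, character(1), "id")
  act <- ids %in% scr$approved_ids
  expect_gt(mean(nearest[act]), mean(nearest[!act]))
})

test_that("exported screens round-trip through the package readers", {
  scr <- small_screen()
  dir <- tempfile()
  export_screen(scr, dir)
  lib <- read_molecules(file.path(dir, "library.smi"), "smiles")
  expect_length(lib, length(scr$library))
  expect_identical(vapply(lib, `[[`, character(1), "smiles"),
                   vapply(scr$library, `[[`, character(1), "smiles"))
  pool <- read_pool_sdf(file.path(dir, "pool.sdf"))
  expect_length(pool, length(scr$pool))
  expect_equal(vapply(pool, `[[`, numeric(1), "binding_energy"),
               vapply(scr$pool, `[[`, numeric(1), "binding_energy"),
               tolerance = 1e-6)
  prot <- read_protein(file.path(dir, "protein.pdb"))
  expect_identical(nrow(prot$atoms), nrow(scr$protein$atoms))
  pockets <- parse_fpocket_output(file.path(dir, "synthetic_helix_out"))
  expect_length(pockets, length(scr$pockets))
  expect_equal(pockets[[1]]$centroid, scr$pockets[[1]]$centroid, tolerance = 1e-3)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_identical(sort(truth$approved_ids), sort(scr$approved_ids))
})

test_that("the recovery experiment returns per-seed metrics with medians", {
  tab <- recovery_experiment(c(21, 22, 23), n_decoys = 80, n_actives = 5,
                             pool_size = 16)
  expect_identical(nrow(tab), 3L)
  expect_true(all(tab$first_hit_rank >= 1))
  expect_true(all(tab$hit_rate_reduction >= 0 & tab$hit_rate_reduction < 100))
  med <- attr(tab, "medians")
  expect_equal(unname(med["first_hit_rank"]), median(tab$first_hit_rank))
  expect_error(recovery_experiment(c(1, 2), n_decoys = 10, n_actives = 2,
                                   pool_size = 4),
               class = "vs_parameter_error")
})

test_that("the random-ranking null has expected first-hit rank (N+1)/(a+1)", {
  expect_equal(expected_null_first_hit(1020, 20), 1021 / 21)
  ## empirical check by simulation
  set.seed(412)
  n <- 200; a <- 10
  mins <- replicate(4000, min(which(sample(n) <= a)))
  expect_equal(mean(mins), expected_null_first_hit(n, a), tolerance = 0.05)
})
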