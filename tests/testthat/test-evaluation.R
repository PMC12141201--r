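ranked_fixture <- function(ids, pocket = 1L) {
  data.frame(rank = seq_along(ids), drug_id = ids,
             fitness = rev(seq_along(ids)), similarity = 0.5,
             binding_energy = -5, pocket_id = pocket)
}

test_that("first-hit rank finds the earliest approved drug or reports absence", {
  ranked <- ranked_fixture(sprintf("D%d", 1:60))
  expect_identical(first_hit_rank(ranked, c("D52")), 52L)
  expect_identical(first_hit_rank(ranked, c("D1")), 1L)
  expect_identical(first_hit_rank(ranked, c("D7", "D30")), 7L)
  expect_true(is.na(first_hit_rank(ranked, c("nope"))))
  expect_error(first_hit_rank(ranked, character(0)), class = "vs_evaluation_error")
})

test_that("hit rate reduction follows 100*(1 - r/N) and is monotone in r", {
  expect_equal(hit_rate_reduction(1, 100), 99)
  expect_equal(hit_rate_reduction(100, 100), 0)
  expect_equal(hit_rate_reduction(250, 1000), 75)
  expect_error(hit_rate_reduction(11, 10), class = "vs_parameter_error")
  r <- 1:50
  hrr <- vapply(r, hit_rate_reduction, numeric(1), n_library = 50)
  expect_true(all(diff(hrr) < 0))
  expect_true(all(hrr >= 0 & hrr < 100))
})

test_that("top-k docking simulation issues exactly first-hit-rank engine calls", {
  mols <- fixture_molecules()[1:6]
  ids <- vapply(mols, `[[`, character(1), "id")
  prot <- vscreenr:::synthetic_protein(4)
  pockets <- vscreenr:::synthetic_pockets(vscreenr:::synthetic_protein())
  calls <- 0L
  counting <- structure(list(kind = "mock", tag = "count",
                             fn = function(protein, mol, box, pocket_id) {
                               calls <<- calls + 1L
                               list(list(coords3d = NULL, energy = -5))
                             }), class = "docking_engine")
  ranked <- ranked_fixture(ids)
  res <- simulate_topk_docking(ranked, approved = ids[3], prot, counting,
                               mols, pockets)
  expect_identical(res$k, 3L)
  expect_identical(calls, 3L)
  expect_length(res$results, 3)
  calls <- 0L
  res <- simulate_topk_docking(ranked, approved = ids[1], prot, counting,
                               mols, pockets)
  expect_identical(res$k, 1L); expect_identical(calls, 1L)
  calls <- 0L
  res <- simulate_topk_docking(ranked, approved = "absent_drug", prot, counting,
                               mols, pockets)
  expect_true(is.na(res$k)); expect_identical(calls, 0L)
})

test_that("drug-likeness profiles report the structural descriptors correctly", {
  mols <- molecules_from_smiles(c("c1ccccc1", "CCO", "c1ccc2ccccc2c1"),
                                c("benzene", "ethanol", "naphthalene"))
  tab <- druglikeness_profile(mols)
  expect_identical(nrow(tab), 3L)
  b <- tab[tab$mol_id == "benzene", ]
  expect_identical(b$heavy_atoms, 6L)
  expect_identical(b$aromatic_rings, 1L)
  expect_equal(b$rotatable_bonds, 0)
  expect_equal(b$hbd, 0)
  e <- tab[tab$mol_id == "ethanol", ]
  expect_identical(e$heavy_atoms, 3L)
  expect_equal(e$hba, 1)
  expect_equal(e$hbd, 1)
  expect_equal(e$mw, 46.07, tolerance = 1e-3)
  expect_identical(tab[tab$mol_id == "naphthalene", "aromatic_rings"], 2L)
  ## QED and the accessibility estimate stay in their documented ranges
  expect_true(all(tab$qed > 0 & tab$qed < 1))
  expect_true(all(tab$sa_score >= 1 & tab$sa_score <= 10))
  expect_s3_class(attr(tab, "summary"), "data.frame")
})

test_that("screen reports expose the headline metrics and serialize to JSON", {
  ranked <- ranked_fixture(c("a", "b", "act", "c"))
  rep <- vscreenr:::new_screen_report("tgt", ranked, approved_ids = "act",
                                      n_library = 4, k_docked = 3L, seed = 1L)
  expect_identical(rep$first_hit_rank, 3L)
  expect_equal(rep$hit_rate_reduction, 25)
  tf <- tempfile(fileext = ".json")
  write_screen_report(rep, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_identical(back$first_hit_rank, 3L)
  expect_equal(back$hit_rate_reduction, 25)
  expect_identical(nrow(back$ranked), 4L)
  expect_output(print(rep), "hit rate reduction")
})
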