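test_that("SMILES library reading parses records in order, skipping malformed ones", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("# header comment", "CCO ethanol", "c1ccccc1 benzene"), tf)
  mols <- read_molecules(tf, "smiles")
  expect_length(mols, 2)
  expect_identical(vapply(mols, `[[`, character(1), "id"),
                   c("ethanol", "benzene"))
  expect_identical(attr(mols, "n_skipped"), 0L)

  writeLines(c("C(C broken", "CCO ok"), tf)
  mols <- read_molecules(tf, "smiles")
  expect_length(mols, 1)
  expect_identical(mols[[1]]$id, "ok")
  expect_identical(attr(mols, "n_skipped"), 1L)

  expect_error(read_molecules(tempfile(), "smiles"), class = "vs_input_error")
  writeLines("C(C only_bad", tf)
  expect_error(read_molecules(tf, "smiles"), class = "vs_input_error")
})

test_that("identical molecules written differently canonicalize identically", {
  m <- molecules_from_smiles(c("OCC", "CCO"), c("a", "b"))
  expect_identical(m[[1]]$smiles, m[[2]]$smiles)
  ## canonical form round-trips to itself
  expect_identical(canonical_smiles(m[[1]]$smiles), m[[1]]$smiles)
})

test_that("molecule invariants hold on the fixture set", {
  for (m in fixture_molecules()) {
    expect_true(all(m$bonds$i >= 1 & m$bonds$i <= nrow(m$atoms)))
    expect_true(all(m$bonds$j >= 1 & m$bonds$j <= nrow(m$atoms)))
    expect_identical(canonical_smiles(m$smiles), m$smiles)
  }
})

test_that("SDF write/read round-trips ids and canonical SMILES in order", {
  mols <- fixture_molecules()
  tf <- tempfile(fileext = ".sdf")
  expect_identical(write_molecules(mols, tf, "sdf"), length(mols))
  back <- read_molecules(tf, "sdf")
  expect_identical(vapply(back, `[[`, character(1), "id"),
                   vapply(mols, `[[`, character(1), "id"))
  expect_identical(vapply(back, `[[`, character(1), "smiles"),
                   vapply(mols, `[[`, character(1), "smiles"))
})

test_that("SMILES write/read over random edited molecules preserves the canonical multiset", {
  provider <- synthetic_provider(5)
  mols <- provider$generate(50, 1, 1L)
  tf <- tempfile(fileext = ".smi")
  expect_identical(write_molecules(mols, tf, "smiles"), 50L)
  back <- read_molecules(tf, "smiles")
  expect_identical(sort(vapply(back, `[[`, character(1), "smiles")),
                   sort(vapply(mols, `[[`, character(1), "smiles")))
  ## empty write is the identity case
  tf2 <- tempfile(fileext = ".smi")
  expect_identical(write_molecules(list(), tf2, "smiles"), 0L)
  expect_identical(length(readLines(tf2)), 0L)
})

test_that("molecular weights match atomic-mass arithmetic", {
  m <- molecules_from_smiles(c("CCO", "O", "c1ccccc1"))
  expect_equal(molecular_weight(m[[1]]), 46.07, tolerance = 1e-3)
  expect_equal(molecular_weight(m[[2]]), 18.015, tolerance = 1e-3)
  expect_equal(molecular_weight(m[[3]]), 78.11, tolerance = 1e-3)
})

test_that("PDB reading loads first-model ATOM records and infers elements", {
  tf <- tempfile(fileext = ".pdb")
  prot <- vscreenr:::synthetic_protein(3)  # 21 atoms, deterministic
  vscreenr:::write_protein_pdb(prot, tf)
  p <- read_protein(tf)
  expect_s3_class(p, "protein_structure")
  expect_identical(nrow(p$atoms), 21L)
  expect_identical(p$chains, "A")
  expect_false(anyDuplicated(p$atoms$serial) > 0)

  ## multi-MODEL: only MODEL 1 is loaded
  writeLines(c(
    "MODEL        1",
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, 1:3 * 1.0, 0, 0),
    "ENDMDL", "MODEL        2",
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            1:3, 1:3, 1:3 * 2.0, 5, 5),
    "ENDMDL", "END"), tf)
  p <- read_protein(tf)
  expect_identical(nrow(p$atoms), 3L)
  expect_equal(p$atoms$x, c(1, 2, 3))

  ## HETATM-only file: excluded by default -> structure error; toggle keeps it
  writeLines(c("HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
               "END"), tf)
  expect_error(read_protein(tf), class = "vs_structure_error")
  expect_identical(nrow(read_protein(tf, include_het = TRUE)$atoms), 1L)
})

test_that("3D embedding aligns coordinates with the atom table and pdbqt stub is written", {
  m <- molecules_from_smiles("CCO", "eth")[[1]]
  m3 <- embed_3d(m)
  expect_identical(dim(m3$coords3d), c(3L, 3L))
  expect_true(all(is.finite(m3$coords3d)))
  tf <- tempfile(fileext = ".pdbqt")
  expect_identical(write_molecules(list(m3), tf, "pdbqt_stub"), 1L)
  expect_true(any(grepl("^ATOM", readLines(tf))))
})
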