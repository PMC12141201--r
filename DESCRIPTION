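Package: vscreenr
Title: Surrogate-Ligand Virtual Screening for Target-Centric Drug Repurposing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-phase virtual screening pipeline for target-centric drug
    repurposing. Phase 1 turns predicted binding pockets of a protein into a
    pool of pocket-conditioned candidate ligands with docking binding
    energies; Phase 2 retrieves approved-drug candidates from a compound
    library by structural similarity to that ligand pool (binary circular
    fingerprints with Tanimoto similarity, count fingerprints or graph
    embeddings with cosine similarity), combines similarity and inherited
    binding energy through a rank-sum weighted multi-objective fitness, and
    docks the top-ranked candidates. Includes adapters for Fpocket output and
    AutoDock Vina style engines, a deterministic mock docking engine, a
    seeded synthetic ligand generator and screen builder for offline
    benchmarking, and enrichment metrics (first-hit rank, hit rate
    reduction) plus drug-likeness property profiling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
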