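# vscreenr — surrogate-ligand virtual screening for drug repurposing

`vscreenr` implements a two-phase, target-centric virtual screening
pipeline for drug repurposing: given nothing but a protein structure, it
prioritizes the compounds of an approved-drug library that are most likely
to bind it — without any known actives for the target.

**Phase 1 (ligand generation).** Candidate binding pockets of the protein
are taken from an Fpocket-style cavity detection run (the package parses
the on-disk output; it does not re-detect cavities). For each pocket a
generator proposes candidate ligands — in production an external
pocket-conditioned generative model through the file adapter, offline the
package's seeded scaffold-editing provider — and each ligand is docked into
its pocket (AutoDock Vina style adapter, or a deterministic mock engine) to
obtain a binding energy (BE, kcal/mol, lower is better).

**Phase 2 (drug retrieval and ranking).** Each library drug `x` is assigned
its most similar generated ligand under a chosen molecular encoding —
binary circular (Morgan-type) fingerprints with the Tanimoto coefficient,
count fingerprints or graph embeddings with cosine similarity — and
inherits that ligand's binding energy and pocket. Drugs are then ranked by
the rank-sum weighted multi-objective fitness

```
f(x) = w1 * f1(x) / E(f1^2)  -  w2 * f2(x) / E(f2^2),    wi = 2(n+1-i) / (n(n+1))
```

where `f1(x)` is the similarity score, `f2(x)` the inherited binding
energy, `E(.)` the mean over the drug set, and, with `n = 2` criteria,
`(w1, w2) = (2/3, 1/3)`. High similarity and strongly negative binding
energy both increase `f(x)`. Finally the top-ranked candidates are docked —
either a fixed top-k, or iteratively until the first validated hit.

Enrichment is measured by the rank `k` of the first approved drug and the
**hit rate reduction** `100 * (1 - k/N)`: the fraction of an `N`-compound
library that never needs to be docked. A drug-likeness profiler (molecular
weight, QED, synthetic-accessibility estimate, rings, rotatable bonds,
HBA/HBD, TPSA) characterizes generated versus library compounds.

## Worked example

Everything below runs offline: the synthetic screen builder plants
"approved" actives that are near-duplicates of the generated-ligand pool
inside a decoy library, and the mock engine supplies deterministic
energies.

```r
library(vscreenr)

scr <- make_screen(seed = 11, n_decoys = 300, n_actives = 10, pool_size = 30)
scr
#> <synthetic screen seed 11> library 310 (10 approved), pool 30, 2 pockets

asg    <- assign_surrogates(scr$library, scr$pool, mode = "tanimoto")
ranked <- rank_candidates(fitness_scores(asg, mode = "ss_plus_be"), asg)
head(ranked[, c("rank", "drug_id", "fitness", "similarity", "binding_energy", "pocket_id")], 5)
#>   rank    drug_id  fitness similarity binding_energy pocket_id
#> 1    1 active_003 14.50610  0.6666667      -3.428571         2
#> 2    2 active_004 13.29917  0.6111111      -3.282051         2
#> 3    3 active_001 12.26260  0.5625000      -4.571429         1
#> 4    4 active_006 11.25688  0.5161290      -4.571429         1
#> 5    5 active_007 10.88666  0.5000000      -3.086957         2

r <- first_hit_rank(ranked, scr$approved_ids)
r                                            #> 1
hit_rate_reduction(r, length(scr$library))   #> 99.67742
```

The top five candidates are all planted actives; the first approved drug
sits at rank 1, so 99.7% of the 310-compound library never needs docking,
and the screening-cost simulation

```r
simulate_topk_docking(ranked, scr$approved_ids, scr$protein,
                      mock_engine(11), scr$library, scr$pockets)$k
#> 1
```

confirms a single docking call reaches it.

The same stages run file-to-file: `pipeline_config()` +
`run_pipeline()` consume a protein PDB, a SMILES/SDF library and an
Fpocket output directory, and persist the pool SDF, assignment CSV, ranked
CSV and report JSON (see `?pipeline_config`; `inst/cli/vscreenr.R` is a
thin command-line front end with `phase1` / `screen` / `run` / `eval` /
`make-fixture` subcommands).

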