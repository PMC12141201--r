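---
title: "Surrogate-ligand virtual screening: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-ligand virtual screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vscreenr)
options(vscreenr.quiet = TRUE)
```

## The screening model

Target-centric drug repurposing asks: given a protein structure and a
library of approved drugs, which drugs are most likely to bind the target?
When no actives are known, ligand-based similarity search has no reference
compound. The pipeline implemented here substitutes *generated* ligands as
the references ("surrogates"): candidate molecules proposed for each
predicted binding pocket of the target, each docked once to obtain a
binding energy. A library drug is then judged by (i) how similar it is to
its nearest surrogate and (ii) how strongly that surrogate bound.

Formally, phase 1 produces a pool of generated ligands, each a triple
(molecule, pocket, binding energy). Phase 2 assigns every library drug
$x$ the pool ligand maximizing the chosen similarity, giving two criteria:
$f_1(x)$, the similarity score, and $f_2(x)$, the inherited binding energy
in kcal/mol (negative is favourable). The combined fitness is

$$f(x) = w_1 \frac{f_1(x)}{E[f_1^2]} - w_2 \frac{f_2(x)}{E[f_2^2]},
  \qquad w_i = \frac{2(n+1-i)}{n(n+1)},$$

with expectations taken as arithmetic means over the drug set being ranked
and, for $n = 2$ criteria, $(w_1, w_2) = (2/3, 1/3)$. Criterion 1 is
similarity and criterion 2 binding energy, in that priority order; the
minus sign makes strongly negative energies raise the fitness. Candidates
are sorted by descending $f(x)$, and the top of the list is docked.

Two single-objective ablations are provided: ranking by similarity alone
(`mode = "ss"`, $f = f_1$) and by inherited energy alone (`mode = "be"`,
$f = -f_2$).

### Numerical and design choices in the fitness

* **Normalization.** The denominator is implemented exactly as the mean of
  squares $E[f_i^2]$. This makes the two terms dimensionally asymmetric
  (each term has the unit of $1/f_i$), and a natural variant divides by the
  root mean square instead; both are available
  (`normalization = "mean_square"` (default) or `"rms"`). The default was
  chosen to follow the fitness as defined rather than a cleaned-up
  variant; the switch exists for sensitivity analysis. Note the joint
  scale-invariance property (scaling both criteria by $c$ scales every
  fitness by $1/c$ and preserves the ordering) holds for the default form
  and is enforced by property tests.
* **Degenerate inputs.** If every $f_1$ (or every $f_2$) is exactly zero
  the normalizer vanishes; this raises an error naming the criterion
  rather than producing infinities.
* **Tie-breaks.** Surrogate assignment breaks similarity ties by lower
  (better) binding energy, then lexicographically smaller ligand id.
  Ranking breaks fitness ties by higher $f_1$, then drug id. Both orders
  are therefore total and deterministic; repeated runs are identical.
* **Classical rank-sum.** The textbook rank-sum method ranks drugs *per
  criterion* and sums the ranks; the fitness here instead combines
  normalized raw values using rank-sum *criterion weights*. The
  raw-value form is what this package implements.

## Molecular encoders

Three interchangeable encodings drive the similarity search:

* `tanimoto` — binary circular (Morgan-style) fingerprints, radius 2,
  2048 bits (the de-facto standard), compared with the Tanimoto
  (Jaccard) coefficient.
* `morgan_cosine` — the same circular substructures kept with their
  multiplicities (count vectors), compared with cosine similarity. Count
  vectors were chosen over binary ones so that cosine is informative on
  dense fingerprints.
* `graph_cosine` — a deterministic, seeded, *untrained* message-passing
  graph encoder filling the neural-encoder slot (the place a trained
  GNN/GAT/EGNN/Equiformer-class model would occupy): one-hot element (16
  common elements + other) ⊕ one-hot degree (clamped 0–5) ⊕ aromatic flag;
  two rounds of neighbour-sum, fixed seeded random linear map and tanh;
  atom-sum pooling and a seeded projection to 64 dimensions. It is
  permutation invariant and a pure function of (canonical SMILES,
  parameters, seed).

The fingerprint implementation follows the standard iterative
circular-substructure hashing but uses its own 31-bit hash; bit positions
are deterministic and reproducible across processes, yet deliberately not
interchangeable with other toolkits' bit assignments. Atom and bond
invariants treat any bond between two aromatic atoms as an aromatic bond
class, so fingerprints do not depend on which kekulized form the IO
backend emitted (verified by SMILES-versus-SDF round-trip tests).

Known limitations: the reference graph encoder is untrained — it measures
graph-topological similarity, not learned chemistry — and it ignores 3D
coordinates, so the geometric-encoder slot (models that would consume
conformers) is represented only through the same contract, not through an
equivariant architecture.

## Pockets, boxes and docking

Cavity detection is external: the package parses an Fpocket-style output
directory (per-pocket `pocket<N>_atm.pdb` files plus an `*_info.txt` with
per-pocket `Score :` lines). Pockets are ordered by descending detector
score with ties broken by ascending pocket number, and by default *all*
pockets are used (`top_m = Inf`), matching the generate-per-pocket loop of
the pipeline; `top_m` exists because using a top subset is a common
economy.

A docking search box is centred on the pocket centroid with edge
`extent + 2 * margin`, floored at a minimum edge. Defaults: margin 4 Å,
minimum edge 10 Å — conventional screening values, fully configurable;
box construction is not prescribed by the screening model itself.

Docking engines are adapters. The external adapter writes PDBQT stubs and
a `key = value` config (exhaustiveness 8, modes 9 by default — engine
defaults, configurable) and parses the engine's `mode | affinity` table.
The mock engine used throughout the tests is a pure function of
(seed, canonical SMILES, pocket id) mapped into [−12, −2] kcal/mol — the
typical span of screening outputs — or, when a similarity oracle is
supplied, `−2 − 10 · oracle(mol)`, which lets synthetic screens plant a
recoverable signal. Downstream code treats energies only as
"lower is better".

## The synthetic-data generator: what it emulates

`make_screen()` builds a fully self-contained screening instance. Its
defaults — **1000 decoys, 20 planted actives, a pool of 50 generated
ligands, at most 2 extra edits between an active and its source pool
ligand** — are the package's study conditions: large enough that a random
ranking would need ~49 docking attempts to reach an active (the null
expectation $(N+1)/(a+1)$), small enough to run end-to-end in well under a
minute per instance on one CPU.

Construction, per seed:

1. a deterministic helix-like protein fixture (~180 atoms) with two
   hand-placed pockets, exported in the Fpocket dialect so parser and
   geometry code run on realistic files (no docking realism is claimed);
2. a generated-ligand pool drawn by the seeded scaffold-edit provider from
   a fixed set of drug-like cores, docked with the similarity-aware mock
   engine;
3. actives derived **from** the pool by 1–2 further local edits — the
   direction matters: the hypothesis under test is that generated ligands
   retrieve approved drugs, so the actives must be the derived objects;
4. decoys drawn from a disjoint, deliberately unrelated scaffold family
   (aliphatic/saturated cores).

The synthetic provider applies random local edits (atom substitution among
C/N/O/S/F/Cl, valence-preserving single-bond addition, connectivity-
preserving ring-bond removal, attachment of small fragments from a fixed
table); every draw must survive the canonicalization backend's valence
check, with bounded resampling. The provider ignores pocket geometry
except for tagging — pocket-conditioned generation is precisely the
externalized component, and the planted-similarity structure of the screen
is what makes recovery measurable instead.

What passing the recovery tests shows: the pipeline's retrieval,
normalization, ranking and evaluation machinery finds a planted
structural signal far above the random-ranking null, deterministically.
What it does not show: performance on real chemistry — real libraries are
more diverse than two scaffold families, real actives are not literal
edits of generated ligands, and real docking scores are far noisier than
the mock engine's oracle. The synthetic screen validates the machinery,
not the screening hypothesis itself.

## Drug-likeness profiling

`druglikeness_profile()` reports molecular weight (from standard atomic
masses plus implicit hydrogens), heavy atoms, aromatic rings (circuit rank
of the aromatic-bond subgraph), rotatable bonds, HBA/HBD, TPSA and logP
(computed by the conversion backend), a QED score, and a synthetic-
accessibility estimate.

* **QED** uses the published asymmetric-double-sigmoid desirability
  parameters and property weights. Two deviations are documented: the
  lipophilicity input is the backend's logP model (not the original
  atom-contribution ALOGP), and the structural-alerts count is treated as
  zero for every molecule (no SMARTS matcher is wired into this stack), so
  absolute QED values sit slightly higher than other implementations
  would report; comparisons *within* a run are unaffected.
* **The synthetic-accessibility estimate** is the package's own
  self-contained analogue of fragment-based accessibility scoring: the
  published score requires an external multi-megabyte fragment-frequency
  database, so commonness is instead measured over circular fragments of
  the analysed set itself, combined with size and ring-complexity
  penalties and mapped to the conventional 1 (easy) – 10 (hard) range. It
  is monotone in fragment rarity and complexity but is not numerically
  comparable with the published score.

## Problem sizes and tolerances used by the test suite

Unit and property tests run on instances of up to a few hundred drugs;
oracle-equivalence checks use 100–1000 random instances with exact rank
agreement and 1e-9 numeric tolerance (1e-12 where arithmetic is exact).
The end-to-end recovery block and the acceptance script both use the
default study conditions over ten seeds; with those defaults the whole
suite completes in a few minutes on one CPU. Wall-clock figures (docking
time in the top-k simulation) are reported in outputs but never asserted.

## Error handling and the CLI

Every failure carries a condition class naming the stage
(`vs_input_error`, `vs_pocket_error`, `vs_generation_error`,
`vs_docking_error`, `vs_search_error`, ...). The command-line front end
(`inst/cli/vscreenr.R`) maps these to exit codes (input 2, pocket 3,
generation 4, docking 5, search/ranking 6). Library readers skip and count
unparseable records rather than failing — large drug libraries routinely
contain a few — while an entirely unparseable library is an error.
Molecule identity is always the backend's canonical SMILES; explicit
hydrogens are stripped on read and re-added only for 3D embedding, keeping
fingerprints stable across input sources.
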