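---
title: "Mining target set-dependent activity cliffs with matched molecular pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining target set-dependent activity cliffs with matched molecular pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acmine)
```

## The problem

An *activity cliff* (AC) is a pair of structurally similar compounds with a
large potency difference against the same target — the most information-dense
objects in structure–activity relationship (SAR) analysis, because a small
chemical change produces a large biological effect. Two questions must be
fixed before cliffs can be mined systematically:

1. **What counts as "similar"?** acmine uses the matched molecular pair
   (MMP) formalism: two compounds form an MMP if they differ only by the
   exchange of one substructure at a single site (a *transformation*). MMPs
   are restricted to R-group-sized transformations (*tsr*): the shared core
   must have at least twice the heavy atoms of each exchanged substituent,
   the substituents may differ by at most 8 heavy atoms, and neither may
   exceed 13 heavy atoms.
2. **What counts as a "large" potency difference?** The classical answer is
   a constant 100-fold cutoff (2 pK~i~ units). But potency spreads differ
   strongly between targets, so acmine's central statistic is the *target
   set-dependent* threshold
   $$t_{\text{set}} = \overline{|\Delta pK_i|} + 2\,\sigma(|\Delta pK_i|),$$
   the mean plus two (sample) standard deviations of the absolute potency
   differences over **all** size-restricted pairs of the set — cliffs are
   the statistically most extreme pairs *of that set* (sd cliffs).

Two extensions follow. *Retrosynthetic* MMPs (RMMPs) restrict the cut bonds
to standard-reaction environments (amide, ester, ether, biaryl, ...), giving
chemistry-aware transformations; RMMPs are a subset of MMPs by construction.
And confirmed *inactive* screening compounds are drawn in: since no
potency difference exists for an inactive partner, the active partner must
instead reach the set's **AC-relevant potency** (ACRP) — the median pK~i~
of the unique highly potent sd-cliff partners. A size-restricted pair of an
ACRP compound and an inactive analog is an *isd cliff*.

Cliff compounds and cliffs form a network whose connected components with
more than two nodes are *clusters* of coordinated cliffs (2-node components
are isolated pairs). Comparing the sd-only network with the sd+isd network
shows what the inactives contribute: entirely *new* clusters and
*extensions* of existing ones.

## The pipeline

`run_pipeline()` executes, per MMP family:

1. qualify target sets (enough actives, broad enough potency distribution);
2. generate MMPs/RMMPs by single-cut fragmentation + fragment indexing,
   apply the tsr filter, and require a minimum pair count;
3. compute the set threshold and call sd cliffs (the constant-threshold
   "original" cliffs are called alongside for comparison);
4. derive the ACRP median and compound set;
5. search ACRP-compound/inactive pairs for isd cliffs, build and compare
   networks, and write cliff tables, per-family deposition files, network
   exports (TSV + GraphML) and a filter-cascade summary.

sd cliffs are computed for **all** qualifying sets; the availability of
inactives gates only the isd stage.

## Key parameters

| parameter | default | meaning |
|---|---|---|
| `min_compounds` | 50 | minimum actives for set qualification |
| `min_sigma` | 1.0 log units | minimum sd of the set's pK~i~ values |
| `min_pairs` | 100 | minimum tsr pairs for cliff eligibility |
| tsr | 2×, 8, 13 heavy atoms | core ratio, max size difference, max substituent |
| `original_cutoff` | 2.0 pK~i~ | constant first-generation cliff cutoff |

All cliff boundaries are inclusive (`>=`): "at least two orders of
magnitude" and "equal to or greater than the median" are inclusive
formulations, and the set threshold is applied the same way for
consistency. The threshold's σ is the *sample* standard deviation (n−1);
at n = 1 it is defined as 0 so the invariant threshold ≥ mean holds. The
median over an even number of unique potent partners is the mean of the two
central values.

The qualification rule is a configurable proxy (the reference procedure for
"statistically significant potency variation" lives in external work): any
`function(set) -> logical` can replace it via the `criterion` argument of
`qualify_target_set()`.

## Chemistry layer: scope and guarantees

No cheminformatics toolkit is assumed. The package includes a purpose-built
SMILES layer:

- a parser for the organic subset, bracket atoms (charge, explicit H),
  branches, ring closures and dot-separated components;
- canonicalization by exact graph canonical labeling (BLISS, via igraph) on
  a bond-subdivided colored graph: two parsed molecules produce the same
  canonical SMILES **iff** their labeled molecular graphs are isomorphic
  (element, aromatic flag, charge, structural H, bond orders);
- single-cut fragmentation of acyclic single bonds between heavy atoms
  (ring bonds are bridges of the bond graph and are never cut), with
  attachment points carried as `[*]` dummies.

Deliberate simplifications, documented as limitations:

- **Stereochemistry is ignored** (`@`, `/`, `\` are parsed and dropped).
  Configuration does not define a transformation site, so stereoisomers
  must compare equal for MMP purposes; dropping stereo realizes exactly
  that.
- **No aromaticity perception or kekulization**: aromatic rings must be
  written in lowercase aromatic form consistently. Everything the package
  emits is canonical and consistent; mixed-form external input would not
  match.
- **No valence model**: implicit hydrogen counts are never computed. For
  aliphatic uncharged organic-subset atoms an explicit bracket H count
  (e.g. the `[C@H]` left behind by stereo stripping) is treated as
  implicit; explicit H remains structural for aromatic atoms (`[nH]`) and
  charged/exotic atoms.

During development, canonical equality was cross-checked against an
independent toolkit on a 26-molecule fixture (325 pairwise comparisons, all
agreeing); the fixture's equivalence classes are frozen in the test suite.

MMP generation indexes every fragment of every cut in both orientations
(either side may serve as the shared core), then keeps, per compound pair,
the pair with the **largest shared core** — the smallest transformation,
matching the chemical reading of "a change at a single site". Ties break on
canonical core string, then substituent strings, so results are independent
of input order. An exhaustive O(n²) pairwise core-intersection oracle in
the test helpers must agree exactly with the index on randomized sets.

### Retrosynthetic rules

The shipped rule file (`inst/extdata/retro_rules.tsv`) is a RECAP-style
stand-in, not a reproduction of any published inventory, and is fully
configurable. A rule names the two atoms of a cuttable bond with optional
neighbor conditions, e.g. `amide  C{=O}-N`. Matching is symmetric; the
first matching rule is recorded as provenance.

## The synthetic world

`generate_target_set()` emulates what curated activity classes look like
from the MMP perspective: *analog series* — one scaffold substituted with
distinct R-groups at a single fixed site — so that every within-series pair
is a tsrMMP by construction.

Potency follows a hierarchical Gaussian model, clamped to the plausible
bioactivity range [3, 12] pK~i~:

- series means ~ N(`potency_mean` = 7, `series_sigma`² = 1.2²),
- compound potencies ~ N(series mean, `potency_sigma`² = 0.5²).

A single i.i.d. sigma cannot satisfy both constraints the emulated world
imposes: set-level sd must reach the qualification cutoff (≥ 1.0), while
the set threshold — driven by *within-series* differences, since
between-series pairs share no large core — must fall in the 0.9–2.7 range
reported for real target sets. The hierarchy decouples the two: set sd
≈ √(1.2² + 0.5²) ≈ 1.3, and for Gaussian within-series potencies the
threshold is ≈ 2.8 × `potency_sigma` ≈ 1.4 before planting.

**Planted cliffs** give ground truth: disjoint within-series pairs whose
potencies are set symmetrically around the series mean with an exact gap
(`planted_delta` = 3.5). Planting is a perturbation of the world it is
planted in: each planted compound also pairs with its ordinary series
siblings at deltas ≈ `planted_delta`/2, so a large planted fraction drags
the mean+2σ threshold up toward — and past — the planted gap itself. At the
default fraction 0.01 (≈ 4 pairs per default set) the contamination
arithmetic gives a realized threshold around 2.4–2.5, inside the reported
band and clearly below 3.5; observed thresholds across seeds are 2.2–2.5.

**Inactives** are drawn two ways: structural analogs (same core, fresh
R-group — exactly what isd cliffs require), and a fraction of structurally
unrelated "diverse" molecules mimicking screening decks, which should
(and do) almost never form MMPs with the actives. At least one active per
series is guaranteed, and planted compounds stay active.

The default scaffold library is constructed so that **no core contains
another core's principal ring system**: otherwise cross-series pairs can
share a large fragment, pass tsr, and leak between-series potency
differences into the Δ distribution (observed as threshold inflation to
≈ 3.9 with an early library that contained both biphenyl and a biphenyl
carboxamide). With unique ring systems, cross-series shared fragments are
small and tsr rejects those pairs. When more series than scaffolds are
requested, cores are reused in a balanced round-robin with disjoint
R-group sets, keeping structures unique within a set.

What a green test on this world does **not** establish: real ChEMBL
chemistry (ring-system diversity, multiple substitution sites, correlated
assay noise, non-Gaussian potency distributions) is not modeled; the
generator validates the *machinery* — pair finding against an oracle,
threshold statistics, ACRP/isd logic, network semantics, determinism — not
the empirical cliff counts of any real database snapshot.

## Numerical and format choices

- Potency is pK~i~ = −log₁₀(K~i~ [mol/L]) throughout; readers can convert
  K~i~ in nM via `pki = 9 − log10(Ki)`.
- Replicate measurements per compound/target are averaged; a compound whose
  replicates spread over > 1 log unit is discarded for that target.
- Deposition files and all TSV outputs serialize numbers as `%.17g`, so
  doubles survive the write/read round trip exactly and reruns are
  byte-identical.
- Cliff sets, ACRP sets and networks are exactly invariant under a constant
  shift of all potencies (only differences enter); the threshold itself is
  reproduced to ~1e-12 (floating-point shift association).
- Ties in the core-versus-substituent orientation (equal fragment sizes)
  break toward the lexicographically smaller canonical SMILES under C
  collation; such pairs cannot pass tsr anyway (the core must be twice each
  substituent).

## Known limitations

- Single-cut fragmentation only (by design — multi-cut MMPs exchange core
  fragments and are not chemically read as cliffs); no double/triple cuts.
- The SMILES dialect covers what the domain needs (drug-like organic
  molecules); isotopes are dropped, unusual elements in the organic layer
  are rejected loudly.
- isd cliffs carry no potency difference, so network edge weights exist
  only for sd/original edges.
- The qualification criterion is a proxy; users reproducing a specific
  external protocol should supply their own `criterion` function.
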