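---
title: "Phylogenetic structure of alien floras: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic structure of alien floras: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alienflora)
```

## The scientific problem

Alien plants reach a new region, some establish self-replacing populations
(naturalize), and a fraction of those spread aggressively (become
invasive). The three stages are nested: invasive ⊆ naturalized ⊆ alien.
`alienflora` asks a community-phylogenetics question about this
continuum: are the species at each stage a random phylogenetic sample of
the regional alien pool, or are they clustered into particular clades?
Clustering at the invasive stage — invaders concentrated in a few
lineages — would mean phylogeny carries predictive signal for invasion
risk screening.

## Data model and status algebra

A checklist is one row per species: name, family, genus, lifeform,
origin region(s) on the TDWG level-1 scheme, introduction pathway, and a
single `status` column holding the *highest* stage attained. Storing only
the highest stage makes inconsistent flag combinations (an "invasive but
not naturalized" species) unrepresentable; the five assemblages — alien,
casual, naturalized, NNI (naturalized but not invasive), invasive — are
always derived by set algebra, never stored, and the derivation enforces
the partition identities `|casual| + |naturalized| = |alien|` and
`|nni| + |invasive| = |naturalized|` exactly.

Tokens are case-insensitive on input and canonicalized to lower case.
Biennials are folded into perennials by `normalize_lifeform()` (they are
rare in alien floras and are conventionally lumped); growth-form tokens
such as `shrub`, `tree`, `vine`, `aquatic` map onto the canonical
`woody`/`other` classes through a user-overridable table, with shrubs and
trees treated as woody and vines and aquatics as `other` (vines may be
herbaceous, aquatics span growth forms). In tabulations a species counts
once per category, except for origins: a species native to two regions
counts once in *each*, so origin proportions can legitimately sum to more
than 100%. Proportions are kept at full precision; rendering to one
decimal is left to reports.

## Nearest-taxon statistics

All phylogenetic statistics consume the dense patristic matrix (tip-pair
path lengths, in the tree's branch-length units, typically Myr). The
matrix, not any particular traversal, is the contract; at regional
checklist scale (a few thousand tips) a dense matrix is a few tens of
megabytes. MNTD of an assemblage is the mean distance of each member to
its nearest co-member. Between assemblages, `comdistnt()` matches every
taxon of each set to its nearest taxon of the other set and averages all
|A| + |B| nearest distances.

Conspecifics: a species shared between two assemblages contributes a
nearest distance of zero by default, which mirrors the convention of the
standard implementation of this statistic. The choice is consequential
here, because the assemblages are nested — shared species pull
between-stage distances toward zero — so the flag
`exclude_conspecifics` is exposed, the pipeline records which mode was
used, and tests cover both. The default stays with the conventional
inclusion.

## The null model and NTI

The reference pool is the alien species list (every species that reached
the region). The null preserves richness: a null assemblage is a uniform
draw, without replacement, of the same number of species from the pool,
ignoring all checklist attributes. NTI is the negative standardized
effect size of MNTD against that null,

NTI = −(MNTD~obs~ − mean MNTD~null~) / sd MNTD~null~,

using the sample (n−1) standard deviation, as standard SES
implementations do. Positive values mean the observed members are closer
relatives than random draws (clustering); negative values mean
overdispersion. Because numerator and denominator are both linear in
branch length, NTI is exactly invariant to rescaling the tree, while
MNTD scales linearly — both properties are tested.

Numerical and algorithmic choices:

* **Exhaustive vs Monte Carlo.** When the number of distinct
  same-richness subsets `choose(|pool|, k)` is at most 10,000 the null is
  enumerated exhaustively (deterministic, exact); otherwise 1000
  Monte-Carlo draws by default. The draw loop is a small C++ kernel, as
  the inner loop of every null draw dominates runtime.
* **Degenerate nulls.** If the null is constant (sd = 0) NTI is
  undefined and reported as `NA` with a diagnostic — never 0 or ±∞. The
  canonical case is the alien assemblage itself: it *is* the pool, so the
  only richness-preserving draw reproduces it exactly. An alternative
  resolution draws the null with replacement
  (`degenerate = "bootstrap"`); note that duplicated taxa then contribute
  zero nearest distances, which biases that SES strongly negative for
  pool-sized assemblages — it keeps the value defined (useful when a
  complete ranking is needed) but its magnitude is not comparable to the
  without-replacement NTI, and the default remains the honest `NA`.
* **Seeds.** A master seed drives everything; `nti_all()` derives one
  sub-seed per assemblage as `seed + index` in the fixed order (alien,
  casual, naturalized, nni, invasive), so adding or removing an
  assemblage never shifts another's draws. All seeds are logged.

## Ordination

The 5×5 between-assemblage nearest-taxon distance matrix is embedded by
classical scaling (`stats::cmdscale` behind `pcoa()`): Gower
double-centering of −d²/2, symmetric eigendecomposition, coordinates
scaled by √eigenvalue. Axes are retained for positive eigenvalues only;
variance explained is relative to the sum of positive eigenvalues;
negative eigenvalues (expected, since nearest-taxon distances between
nested sets violate the triangle inequality) are dropped without
Cailliez/Lingoes correction and their total magnitude is reported. Axis
signs are fixed by making each axis's largest-magnitude coordinate
positive, so output is fully deterministic. One caveat discovered while
testing: duplicating a point in a distance matrix adds a zero eigenvalue
and leaves the embedding intact, but it *does* change variance fractions,
because the duplicated point doubles its weight in the centering — the
round-trip property, not fraction invariance, is the reliable check.

## What the synthetic generator emulates

`simulate_dataset()` stands in for a real checklist and mega-tree:

* **Tree:** a forward Yule (pure-birth) simulation — two lineages at the
  root, Exponential(k·λ) waits, uniform lineage splits — stopped one
  further exponential interval after reaching `n_tips`, so terminal
  branches are positive and the tree is exactly ultrametric. Yule rather
  than birth–death because the trees exist to exercise statistics, not to
  be realistic; λ defaults to 1 (arbitrary time units).
* **Assemblages:** nested sampling mirrors the continuum — naturalized
  species are drawn from within the alien set, invasive from within the
  naturalized. Each stage uses `sample_clustered()`: with probability
  ρ the nearest not-yet-chosen relative of the current set is added
  (ties broken by label order for determinism), otherwise a uniform pick.
  ρ = 0 is exactly uniform sampling; ρ = 1 is fully greedy clade capture.
  Defaults ρ(alien) = 0, ρ(naturalized) = 0.3, ρ(invasive) = 0.8,
  giving the qualitative stage ranking seen in large regional floras.
  `sample_overdispersed()` (greedy maximin) is the negative-NTI control.
* **Sizes and marginals:** defaults are 1686 alien / 1198 naturalized /
  232 invasive. Lifeform, pathway and origin are i.i.d. categoricals per
  status. The invasive vectors carry published-scale invasive marginals
  directly (annual 62.1%, perennial 26.3%; America 57.8%, tropical Asia
  3.9%); the casual/NNI vectors were solved once so the alien-level
  mixture lands on the alien marginals (annual 33.6%, perennial 49.0%,
  ornamental pathway ≈ 57%), and the remaining probability mass was
  spread plausibly across the other categories. These are fixed study
  conditions, not tuning knobs.
* **Taxonomy:** pseudo-families and pseudo-genera are the clades obtained
  by cutting the ultrametric tree at 50% and 75% of its height
  (single-linkage clustering of patristic distances at the corresponding
  threshold), so taxonomy correlates with phylogeny as in real floras and
  per-family transition rates are testable. Genera nest within families
  by construction.
* **Origins** are drawn as a single region per species, so synthetic
  origin tabulations sum to 1; the once-per-region counting rule for
  multi-origin species is exercised with hand-built fixtures instead.

What the generator does **not** emulate: real biogeography, trait
evolution, correlated pathways and origins, polytomies, or name-matching
noise between checklist and tree. Passing tests therefore demonstrate
the statistical machinery and its calibration, not conclusions about any
real flora.

## Pipeline behaviour

`run_pipeline()` is staged (load, tip matching, tabulation, NTI,
between-assemblage distances, PCoA); any failure aborts with a
stage-tagged message and removes partial outputs. Checklist names are
matched to tips exactly after space→underscore translation; unmatched
species are dropped and logged, with a hard error when more than 20% of
any assemblage (configurable) is lost. The JSON-lines log carries
stages, counts and seeds but no wall-clock fields, so identical inputs
and seed yield byte-identical output files — a property the tests assert
with checksums.

## Problem sizes used in the test suite

The suite exercises full-scale status algebra (1686 species) but keeps
simulation-heavy checks at deliberately chosen smaller scales: null
calibration on a 200-tip tree (200 assemblages of 30, 1000 draws each),
sign recovery with k = 20 on fresh 200-tip trees (100 replicates per
direction), oracle equivalence on 1000 random trees of 4–10 tips against
brute-force enumeration (tolerance 1e−9), and the end-to-end ranking
check at 400 tips (400/280/56, invasive ρ = 0.8, 300 draws, 50
replicates). These sizes give binomial/Monte-Carlo error well inside the
asserted bounds while keeping the suite quick to run.

## Known limitations

* MPD/NRI (mean pairwise distance and its SES) are deliberately out of
  the tested surface; only nearest-taxon statistics are provided.
* Only the richness-maintaining pool-draw null is implemented; swap-based
  nulls are not.
* The checklist is taken at face value: no taxonomic name resolution,
  and tree construction (mega-tree grafting) is upstream of this package.
* NTI for an assemblage equal to its pool is undefined under the
  without-replacement null; both provided resolutions (flagging, literal
  bootstrap) have interpretive caveats described above.
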