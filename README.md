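# alienflora

Community-phylogenetic analysis of regional alien floras along the
introduction–naturalization–invasion continuum, for invasion ecologists
working from a species checklist and a dated phylogeny.

A checklist stores one row per alien species with its family, genus,
lifeform, origin region(s) (TDWG level-1), introduction pathway and the
**highest invasion stage attained** (`casual`, `naturalized`, `invasive`).
Because invasive species are a subset of naturalized species, and
naturalized species a subset of aliens, five nested assemblages follow by
algebra alone:

- alien = all species; naturalized = status ∈ {naturalized, invasive};
  invasive = status invasive
- casual = alien \ naturalized; NNI (naturalized-but-not-invasive) =
  naturalized \ invasive

The phylogenetic core works on the patristic distance matrix *d* of the
tree:

- **MNTD** of an assemblage *S*: mean over taxa *t* ∈ *S* of
  min<sub>s≠t</sub> *d*(t, s) — the mean distance to the nearest relative
  within the assemblage.
- **NTI** (nearest taxon index): the standardized effect size
  NTI = −(MNTD<sub>obs</sub> − mean MNTD<sub>null</sub>) / sd MNTD<sub>null</sub>,
  where the null draws equally rich assemblages uniformly, without
  replacement, from the alien reference pool (1000 draws by default, or
  exhaustive enumeration when feasible; sample sd). NTI > 0 means
  phylogenetic clustering, NTI < 0 overdispersion, 0 randomness.
- **comdistnt**: between two assemblages, each taxon is matched to its
  nearest taxon in the other set and the |A|+|B| nearest distances are
  averaged; shared taxa count as distance 0 unless conspecifics are
  excluded. The 5×5 between-assemblage matrix is ordinated by **PCoA**
  (classical scaling; negative eigenvalues dropped and reported).

A synthetic-data module (Yule tree simulator, clade-biased and maximin
assemblage samplers, checklist generator whose defaults mirror a large
regional alien flora of 1686 alien / 1198 naturalized / 232 invasive
species) makes every pipeline stage testable without external data.

## Worked example

```r
library(alienflora)

# a synthetic flora: 300 alien species, clustering only mild at the
# naturalized stage (rho 0.3) and strong at the invasive stage (rho 0.8)
cfg <- synthetic_config(n_tips = 300, n_alien = 300, n_naturalized = 210,
                        n_invasive = 40,
                        clustering_rho = c(alien = 0, naturalized = 0.3,
                                           invasive = 0.8),
                        seed = 42)
ds <- simulate_dataset(cfg)
dir <- tempfile(); dir.create(dir)
ape::write.tree(ds$tree, file.path(dir, "tree.nwk"))
write_checklist(ds$checklist, file.path(dir, "checklist.csv"))

summ <- run_pipeline(run_config(file.path(dir, "checklist.csv"),
                                file.path(dir, "tree.nwk"),
                                file.path(dir, "out"),
                                n_draws = 1000, seed = 1))
print(summ)
```

```
Alien-flora phylogenetic analysis
  assemblage sizes: alien 300, casual 90, naturalized 210, nni 170, invasive 40 
  NTI by assemblage:
    alien        undefined (degenerate null)
    casual       1.884
    naturalized  2.594
    nni          2.162
    invasive     7.135
  PCoA axes 1-2 variance explained: 100%
```

Reading the output: the invasive assemblage was simulated with strong
clade bias, and its NTI (7.1) towers over the other stages — its members
are far more closely related than random same-richness draws from the
alien pool. The alien assemblage *is* the reference pool, so every
richness-preserving draw reproduces it exactly: the null sd is 0 and its
NTI is reported as undefined rather than forced to a number (a
bootstrap-with-replacement alternative is available via
`degenerate_null = "bootstrap"`). The five-point between-assemblage
nearest-taxon distance matrix embeds almost perfectly in two PCoA axes.
`run_pipeline()` also writes `tabulations.csv` (family / lifeform /
origin / pathway composition per assemblage), `transition_rates.csv`
(per-family naturalization and invasion rates), `nti.csv`/`nti.json`,
`assemblage_distances.csv`, PCoA coordinates/eigenvalues and a
deterministic JSON-lines log; identical inputs and seed give
byte-identical outputs.

A thin command-line wrapper (`inst/scripts/alienflora.R`) exposes `run`
and `simulate` subcommands over the same functions.

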