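# wolfdemog

Spatially and temporally explicit demographic inference for Northern
Hemisphere grey wolves from dated mitochondrial genomes.

Ancient-DNA studies indicate that all modern wolves descend from a single
Late Pleistocene population, but modern genomes alone cannot locate that
source population or date its spread. This package implements a
structured-coalescent modelling framework for panels of dated (ancient +
modern) mitogenomes: the wolf range is modelled as seven demes — Europe,
Middle East, Central North Eurasia, East Eurasia, Beringia, Arctic North
America, North America — connected by gene flow along a nine-edge
neighbour network, and competing demographic histories are compared by
Approximate Bayesian Computation (ABC).

## The model

Backwards in time, lineages in a deme coalesce pairwise at rate $1/K(t)$
($K$ = mean within-deme pairwise coalescence time, ky), and each lineage
migrates at rate $m$ per ky to a uniformly chosen neighbouring deme.
Samples enter at their ages (ky BP). Sixteen candidate scenarios arise
from four families:

1. **static** — constant $K$ (the null);
2. **bottleneck** — epoch sizes $K_1$ (0–15 ky), $K_2$ (15–40 ky),
   $K_3$ (>40 ky BP);
3. **expansion** — a range expansion out of one origin deme starting at
   $T$ ky BP, advancing one graph hop per $\Delta T$ ky; colonization
   replaces each indigenous population and applies an instantaneous
   founder bottleneck in which every lineage pair coalesces with
   probability $x$; backwards in time lineages are force-migrated into a
   source deme (7 origins × with/without epoch sizes = 14 scenarios);
4. **expansion + bottleneck** — both.

A genealogy (simulated, or an observed dated tree) is reduced to nine
summary statistics: mean pairwise TMRCA within and between the groups
EUR, ME, EAS (Central North Eurasia + East Eurasia + Beringia) and AME
(Arctic + continental North America), with the within-ME entry masked.
ABC draws parameters from the study priors, accepts the 10% of
simulations closest to the observation in squared-Euclidean distance, and
ranks scenarios by a kernel estimate of each scenario's marginal
likelihood at the observed statistics (Bayes factors relative to the
best). The package also provides the supporting population-structure
analyses — Mantel isolation-by-distance on Haversine great-circle vs
p-distances, and one-level AMOVA with permutation tests — and a
synthetic-data generator that emulates the study design (90 modern + 45
ancient samples, ~15.5 kb alignments with ~8% variable sites) with known
ground truth.

## Worked example

```r
library(wolfdemog)

graph  <- deme_graph()                      # the seven-deme network
design <- make_design(graph, seed = 1)      # 90 modern + 45 ancient samples
truth  <- default_truth_scenario()          # expansion out of Beringia @ 25 ky
po     <- make_pseudo_observed(design, truth, seed = 2, graph = graph)

obs <- tmrca_summary(po$genealogy, graph)   # nine TMRCA statistics (ky)
res <- run_abc(obs, graph, design, n_sims = 20000, seed = 1)
res$table[1:3, c("name", "bayes_factor")]
```

On the synthetic data set written by `analysis/01_synthesize_data.R`
(seed 1), the full pipeline (`scripts/acceptance.R --seed 1`) prints:

```
alignment_length_bp          15466
variable_site_percent        11.9
ibd_mantel_rho               0.367      (p = 1e-04, modern Eurasia)
amova_among_deme_percent     34.5       (p = 1e-04)
static_bayes_factor          5.2e-14
bottleneck_only_bayes_factor 5.1e-13
beringia_origin_rank         2
replacement_time_median_ky   12.4       (95% interval 9.2 - 15.8)
```

Read: the synthetic mitogenome alignment shows clear isolation by
distance and a third of its variance between demes, and the ABC rejects
the two null-like scenarios overwhelmingly (Bayes factors far below 0.1) —
an expansion is unambiguous. The *origin*, however, is resolved only
coarsely from a single genetic locus: on this particular data set the
best-supported scenario is a neighbouring-origin expansion and the true
origin (Beringia) ranks second, so the reported replacement time is drawn
from the wrong origin's restricted prior. Replicate data sets move the
ranking around (the published analysis likewise found East Eurasia nearly
tied with Beringia); scenario-family discrimination is the robust signal,
origin ranking is not.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data, writing tables and JSON manifests under `results/`:

| script | does |
|---|---|
| `01_synthesize_data.R` | design, pseudo-observed dated genealogy, alignment |
| `02_population_structure.R` | Mantel IBD + AMOVA |
| `03_abc_scenario_selection.R` | 16-scenario ABC, Bayes factors, posteriors |
| `04_recovery_experiment.R` | repeated scenario/parameter recovery |

Each takes an optional seed argument (`Rscript analysis/01_synthesize_data.R 1`).

## Methods

See the methods vignette (`vignettes/wolf-demography.Rmd`) for the model
assumptions, the founder-bottleneck mechanism, prior choices, the
kernel-likelihood approximation and its relation to abctoolbox, numerical
tie-breaking rules, what the synthetic-data generator does and does not
emulate, and known limitations.
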