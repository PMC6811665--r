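---
title: "Metabolic overlap: model, assumptions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic overlap: model, assumptions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metoverlap)
```

## The metric

Metabolic overlap (MO) between two genomes is the number of compounds both
can *utilize*, computed from their genome-derived reaction networks. Each
genome is reduced to a **reactant profile**: the union, over all reactions
it encodes, of the consumed-side compounds of each reaction. For a genome
pair $(i, j)$ with profiles $S_i, S_j$,

$$\mathrm{MO}(i, j) = |S_i \cap S_j|.$$

Counting shared *reactants* rather than shared *reactions* is deliberate:
two organisms can degrade the same substrate through different routes, and
reactant counting still registers that their niches overlap. The canonical
toy example is a complete denitrifier (nitrate → nitrite → nitric oxide →
nitrous oxide → dinitrogen, four reduction reactions, profile
$\{NO_3^-, NO_2^-, NO, N_2O\}$) against a partial denitrifier encoding only
the nitrite and nitric-oxide reduction steps (profile $\{NO_2^-, NO\}$):
their MO is 2, regardless of the rest of their metabolism.

```{r example}
tf <- tempfile(fileext = ".tsv")
writeLines(c("reaction_id\tsubstrates\tproducts\tdirection\tsubsystems",
             "den1\tNO3\tNO2\tforward\tNitrogen",
             "den2\tNO2\tNO\tforward\tNitrogen",
             "den3\tNO\tN2O\tforward\tNitrogen",
             "den4\tN2O\tN2\tforward\tNitrogen"), tf)
db <- load_reaction_db(tf)
full <- reactant_profile(c("den1", "den2", "den3", "den4"), db)
partial <- reactant_profile(c("den2", "den3"), db)
pairwise_mo(full, partial)
```

For a community (all genomes assembled from one study), all pairwise MO
values are stored in a symmetric overlap matrix whose diagonal holds each
genome's profile size; the community-level MO is the median (default) or
mean of the $n(n-1)/2$ off-diagonal pairs, and the genome-size-normalized
MO divides that by the community's **median genome size in base pairs**
(units: compounds·bp⁻¹), so that communities of large-genome and
small-genome organisms can be compared.

## Assumptions and the choices behind them

Several aspects of the metric are underdetermined by its verbal definition;
these are the package's resolutions, each exposed as an argument so the
sensitivity of a result to the choice can be measured:

* **Reversible reactions contribute both sides** to the reactant set
  (`reversible = "union"`): a reversible enzyme can consume either side.
  `reversible = "substrates"` restricts to the annotated substrate side.
* **No currency-compound exclusion by default.** Water, protons, ATP and
  the like are counted if present in the database; `exclude_compounds`
  accepts an explicit list for analyses that want them removed.
* **Stoichiometry is ignored.** MO is presence-based counting; equation
  coefficients and compartment tags are stripped at parse time.
* **Central statistic.** Both median and mean are available
  (`statistic =`); the median is the default because it is robust to the
  long upper tail produced by a few highly versatile genomes.
* **Normalization divisor** is the *median* member genome size (not the
  mean), consistent with the robust central statistic; normalized values
  on realistic inputs land in the 1e-6 to 1e-4 compounds·bp⁻¹ range.
* **Completeness threshold** defaults to 50%, the floor of commonly
  accepted metagenome-assembled genomes; it is a flag because threshold
  sensitivity is itself an analysis one may want to run. Studies
  contributing a single genome are excluded (no pairs to compare;
  `min_members = 2`).
* **Lenient annotation ingestion** by default: rows citing reaction ids
  absent from the database are kept with a warning (MAG annotation tables
  routinely cite deprecated ids); `strict = TRUE` drops or errors instead.
* **Subsystem restriction** intersects a genome's reactions with those
  carrying a category label before profiling, so subsystem MO is always
  bounded above by full MO. A label matching nothing is an error rather
  than a silent empty result, to distinguish typos from biology.
* **Denitrification pathway mapping.** The four reduction steps are
  defined by compound pairs, not hard-coded reaction ids; the shipped
  default scans the loaded database for reactions converting
  NO3→NO2→NO→N2O→N2 (reversible reactions qualify in either orientation),
  and a pathway TSV can override the mapping entirely. A genome is a
  *complete* denitrifier iff every step is covered by at least one
  reaction, *partial* iff at least one but not all are, *absent*
  otherwise. Ratios of complete to partial denitrifiers are `Inf` when a
  group has no partials and flagged `NaN` when it has neither.

## Statistics

The association between phylogenetic distance and MO is tested two ways,
reported side by side by the survey:

1. `mantel_test()` — a permutation Mantel test. The statistic is the
   Spearman (default) or Pearson correlation of the strict lower triangles
   of the cophenetic-distance and overlap matrices; the null distribution
   permutes rows and columns of one matrix simultaneously, and the
   two-sided p-value uses the add-one correction
   $(\#\{|r_\pi| \ge |r_{\mathrm{obs}}|\} + 1) / (n_\pi + 1)$. The default
   is 999 permutations; the p-value is exactly uniform under the null by
   construction. The seed is recorded in the result.
2. `pairwise_scatter_correlation()` — the plain rank correlation over the
   pooled pairwise comparisons, with the large-sample p approximation; it
   ignores the non-independence of pairs sharing a genome, which is why
   the Mantel test is the inferential instrument and this one the
   descriptive coefficient.

Cophenetic distances are extracted with `ape` from newick trees with
branch lengths; genomes present in the MO matrix but missing from the tree
are dropped pairwise with a logged count.

Ecosystem contrasts use Kruskal–Wallis (chi-squared approximation with tie
correction, via `stats::kruskal.test`) followed by hand-coded Dunn z
post-hoc tests on the pooled ranks, Holm-adjusted by default
(Benjamini–Hochberg and unadjusted are selectable). Richness–MO and
size–MO relationships are Kendall and Spearman rank correlations; a
constant response yields a flagged degenerate result rather than an error.
Genome-size differences across ecosystems get an ordinary one-way F test.

## The synthetic-data generator

Real survey inputs are large external downloads; every pipeline stage is
therefore exercised on synthetic data with *planted* structure:

* `generate_reaction_db()` — a uniform random reaction universe; defaults
  of 400 reactions over 300 compounds, 1–3 substrates and products each,
  20% reversible, subsystem labels rotated through the 13 metabolism
  categories, plus the four denitrification reactions.
* `generate_tree()` — random sequential pairwise joins with exponential(1)
  branch lengths; 30 tips by default.
* `evolve_genomes()` — a 150-reaction root repertoire evolves along the
  tree under a per-reaction two-state Markov process: over a branch of
  length $t$ a present reaction is lost with probability
  $1 - e^{-\lambda t}$ and an absent one gained with probability
  $1 - e^{-\gamma t}$, defaults $\lambda = 0.3$, $\gamma = 0.05$. This is
  the simplest process producing the distance-decay of overlap the Mantel
  machinery must detect: closely related tips share more repertoire.
* `generate_metadata()` — genome size = 10,000 bp per encoded reaction
  plus Gaussian noise (sd 100,000 bp), floored at 1; completeness uniform
  on [50, 100), matching the range of accepted MAGs. This plants the
  positive size–MO coupling.
* `plant_denitrification()` — exact class fractions (default 0.3
  complete, 0.2 partial) by largest-remainder rounding; partial genomes
  receive a random proper non-empty step subset and are purged of the
  other steps' reactions, so planted truth is recovered exactly.
* `generate_survey()` — a whole multi-study bundle on disk (database,
  annotations, metadata, per-study trees, pathway, YAML config). Study
  richness varies, and `couple_richness` scales the loss rate with
  richness so that more diverse communities diverge more — the programmed
  negative richness–MO dependence.

What the generator does **not** emulate: real metabolic-network topology
(no mass balance, no pathway gap-filling, no hub compounds), annotation
error structure, uneven taxon sampling, and horizontal gene transfer
(gains are independent of the donor pool). Green tests on synthetic data
therefore demonstrate that the *machinery* — parsing, set algebra, matrix
construction, permutation inference — is correct and calibrated, not that
any particular biological effect size in real data will be reproduced.

## Numerical and degenerate-input choices

* Overlap matrices are computed as an integer cross-product of the
  genome × compound incidence matrix — exact integer arithmetic, no
  tolerance needed — and stored dense (communities are at most hundreds of
  genomes).
* Empty genomes are legal everywhere: empty profile, zero MO row, absent
  pathway status. A community still needs ≥ 2 members.
* Constant vectors in any correlation return a flagged `NA` result
  (`degenerate = TRUE`) instead of erroring, so survey loops keep going.
* Ties in rank statistics use midranks; the Kruskal–Wallis H and Dunn
  standard errors carry the standard tie corrections.
* All generators take explicit integer seeds and are deterministic given
  one; the survey runner threads a single seed through every stochastic
  stage and records it in the run log.

## Problem sizes used in the test suite

The shipped tests run the whole battery at deliberately modest scale,
chosen to make the planted effects detectable with comfortable margins:
oracle-equivalence sweeps use up to 50 genomes × 200 reactions over 100
random communities; Mantel recovery uses the generator defaults (30 tips)
over 50 seeded replicates at 999 permutations; null calibration uses 200
Mantel replicates at 199 permutations and 500 Kruskal–Wallis replicates.
The full suite completes in well under a minute on one CPU.

## Known limitations

MO is a genome-potential metric: it knows nothing of expression,
regulation, transporter affinity, or organism abundance, and inherits all
upstream annotation error. The Mantel test here is the plain two-matrix
version (no partial Mantel / covariate control). The CLI is a thin wrapper
over the same functions — identical numbers, no extra capability.
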