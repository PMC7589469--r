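---
title: "Classifying lifespan epistasis in multi-gene mutants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying lifespan epistasis in multi-gene mutants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilifespan)
```

## The problem

Hundreds of longevity-associated genes (LAGs) are known in *C. elegans*,
*D. melanogaster* and *M. musculus*, but genes rarely modulate lifespan
independently: combining two or more interventions is usually not additive.
Curated lifespan records for double, triple and quadruple mutants make it
possible to classify these interactions, provided the classification is
done carefully — against the right control, within a single experiment, and
with explicit rules for what counts as synergy when most intermediary
strains were never assayed.

`epilifespan` implements that classification engine. A dataset is a table
of strain-cohort observations: organism, the intervened genes (with alleles
and intervention types), a lifespan value in days, temperature, diet and
the source study. Strains are named canonically — gene symbols sorted
alphabetically and joined with `";"`, so `daf-2;daf-16` and `daf-16;daf-2`
are the same model — and identified at the gene level: alleles are recorded
for audit but do not split models, matching how the field aggregates
strain-level reports into gene-combination pages.

## Effects and the five-way pair classifier

All effects are percent lifespan changes against the wild type **of the
same experiment**:

$$\Delta G = \frac{LS(G) - LS(WT)}{LS(WT)} \times 100.$$

For a double mutant with single effects $\Delta G_1$, $\Delta G_2$ and
combined effect $\Delta(G_1,G_2)$, classification proceeds only when both
single interventions move lifespan in the same direction (a zero effect has
no direction; mixed directions are reported as not assessable). With
magnitudes $a_1, a_2, a_{12}$:

* **synergistic**: $a_{12} > a_1 + a_2$;
* **additive**: $a_{12} = a_1 + a_2$;
* **almost additive**: $\max(a_1, a_2) < a_{12} < a_1 + a_2$;
* **dependent**: $\min(a_1, a_2) \le a_{12} \le \max(a_1, a_2)$;
* **antagonistic**: $a_{12} < \min(a_1, a_2)$, and also whenever the double
  mutant's effect flips sign against the shared direction of the singles
  (reported with phenotype direction `"opposite"`).

The dependent band is closed on both ends, so the five categories partition
the real line of $a_{12}$ values exactly. Exact additivity is a knife edge
— essentially theoretical with real measurements — so it is recognised
within a relative tolerance `additive_epsilon` (default `1e-9`, i.e.
numerically exact; raise it to treat near-sums as additive).

```{r pair-demo}
classify_pair(30, 20, 60)   # beats the sum of 50
classify_pair(30, 20, 25)   # between the singles
classify_pair(30, 20, -5)   # flipped: antagonistic, opposite
```

## Full synergism for n-mutants

For more than two genes, an n-mutant is **fully synergistic** when its
effect magnitude beats $|\Delta(S)| + |\Delta(\bar S)|$ for *every*
bipartition of its gene set into two non-empty disjoint subsets — which
requires every intermediary mutant to have been assayed in the same
experiment; otherwise the call is `insufficient_data`. For pairs this
reduces exactly to the five-way classifier (a tested invariant).

Two design boundaries are worth making explicit:

* **Detailed categories stop at pairs.** For $n > 2$ the five-way labels
  are not well defined by the bipartition rule alone, so calls report
  `synergistic` versus `not_synergistic`, the most violated bipartition,
  and the pair-style category of the combination against that bipartition
  as a diagnostic.
* **Flexible versus strict.** The default (flexible) rule constrains only
  bipartitions of the full gene set, keeping combinations that are
  synergistic only at the top level. A stricter reading — every
  sub-combination must itself be fully synergistic — is available via
  `strict = TRUE`. The two differ in a subtle way: flexible full synergism
  does **not** imply simple synergism. With singles $(10, 10, 10)$ and all
  pairs at $5$, a triple at $16$ beats every bipartition sum ($15$) yet
  falls far short of the singles' sum ($30$). Under `strict = TRUE` the
  implication holds and is exercised in the test suite over an exhaustive
  3-gene grid.

## Simple synergism and its false positives

**Simple synergism** compares the combination only against the sum of the
$n$ single effects — the popular definition, needing no intermediary data.
Its price is masking: a strongly synergistic sub-group can hide a negative
contribution of the remaining genes. The packaged fixture
`synthetic_masked_triple.csv` (a constructed example, as its name says)
shows the failure mode: singles of $+50, +20, +15$% and a triple at $+90$%
look simple-synergistic ($90 > 85$), but the pair data reveal doubles at
$+120$ and $+110$% — longer-lived than the triple — and full evaluation
refutes the synergy, naming the violated bipartition.

```{r masked}
fixture <- system.file("extdata", "synthetic_masked_triple.csv",
                       package = "epilifespan")
grp <- experiment_groups(read_lifespan_data(fixture))[[1]]
simple_synergy(grp, "g1;g2;g3")[, c("category", "phenotype_direction")]
full_synergy(grp, "g1;g2;g3")[, c("category", "violated_bipartition")]
```

## Partially known monotony

An n-mutant can be constructed along $n!$ orders of interventions. When
intermediary data are incomplete, the package checks monotony only along
the **assayed** paths: a path is monotonic-positive when each added
intervention strictly increases the lifespan of the previously constructed
mutant. One non-monotonic known path means the gene set contains dependency
relationships; zero complete paths means no verdict. Ties are
non-monotonic at the default `tie_tolerance = 0` days ("increases" is read
strictly); a small positive tolerance treats near-ties as flat, i.e. also
non-monotonic, symmetric in both directions.

## Same-experiment discipline and grouping

Every epistasis call uses observations from a single experiment group,
because wild-type lifespans vary substantially between labs and conditions
(for *C. elegans*, recorded WT lifespans span roughly 17–35 days at 15 °C).
The grouping key defaults to `(study_id, temperature_c, diet)` — the
conditions recorded per cohort — and can be overridden via
`experiment_key_fields` when a dump encodes its experiment structure
differently. Cross-experiment epistasis inference is deliberately not
offered: with inter-lab WT variation of this size, mixing controls across
studies manufactures artefactual calls. The one sanctioned cross-study
computation is the display **effect interval**: for experiments without
their own WT, the mutant is bracketed against the species-wide minimum and
maximum WT lifespan, restricted to the mutant's temperature stratum when WT
data exist there (per-temperature WT ranges differ enough that pooling
inflates the bracket; `temperature_stratified = FALSE` gives the pooled
variant for comparison).

Multiple cohorts of one strain within one group are averaged
(arithmetic mean) before any effect is computed; the per-cohort rows are
retained for QC.

## Curation screen

`inclusion_filter()` mirrors the curation rules for admitting an
experiment: (a) at least one multi-gene mutant must be comparable to a
strain from which it was incrementally constructed — an assayed
$(n-1)$-mutant inside the same group; and (b) at least one mutant cohort
must exceed the group's wild type by strictly more than 10% (exactly +10%
fails). Rule (a) is applied existentially, and rule (b) compares against
the *minimum* WT cohort, so the screen is monotone in evidence: adding an
observation can never turn a passing group into a failing one (a property
the tests enforce). For groups lacking a WT control,
`assume_prior_lag = TRUE` records the curator's assertion that one
intervention is a previously established LAG and waives (b).

## The synthetic-data generator

`generator_config()` + `generate_dataset()` produce datasets with known
ground truth so every stage is testable without downloads. Defaults are
fixed to a realistic *C. elegans* assay: WT lifespan 18.8 days at 20 °C and
a between-cohort coefficient of variation of 0.18 — the magnitude of
inter-study WT variation in curated worm data (SD ≈ 4.4 d on a ≈ 23.7 d
mean at 15 °C). Noise is multiplicative log-normal with mean one,
parameterised by that CV: it keeps lifespans positive and scales with the
mean, which is how between-cohort variation behaves.

Interaction models: `additive_deltas` (percent effects add),
`multiplicative_lifespans` (lifespan ratios multiply — already mildly
synergistic on the percent scale), `masking` (the largest-magnitude single
effect carries the combination; the analytic category is `dependent`, a
closed-boundary case), and `custom_table` / `interaction_overrides` for
arbitrary per-subset effects. `completeness` controls the assayed fraction
of intermediary mutants, emulating the real situation where most
intermediate strains are never measured; WT, all singles and the full
n-mutant are always emitted.

What the generator does **not** emulate: survival curves and censoring
(only summary lifespan values exist, matching the data model), cohort
sizes, correlated lab effects across experiments, pathology-driven early
deaths, and allele-specific effect differences. Recovery results on
synthetic data therefore validate the classification logic and its noise
sensitivity, not the curation quality of any real dataset.

`recovery_experiment()` measures the fraction of calls matching ground
truth across noise levels. Noise-free recovery is 100% away from category
boundaries; at the WT-derived CV of 0.18 a clearly synergistic pair
(margin +30 percentage points) is recovered in roughly 40–50% of single
replicates — a useful reminder that single-study categories near any
boundary are fragile.

## Numerical and interface choices

* Canonical names sort case-insensitively with a byte-order tie-break
  (radix sort; locale-independent).
* Zero single effects have no direction and make a combination
  not assessable, rather than being forced into either branch.
* Boundary equalities follow the printed rule shapes: the dependent band is
  closed, strict inequalities elsewhere; `additive_epsilon` is the only
  tolerance and is relative.
* Ground-truth categories in the generator come from the same printed
  rules applied to noise-free effects — analytically, not by running the
  classifier on generated data.
* The CSV/JSON dump dialects use the exact column set
  `organism, genes, alleles, intervention_types, lifespan_days,
  lifespan_metric, temperature_c, diet, study_id` with `";"` reserved as
  the in-field list separator; a `column_map` adapts foreign headers, since
  deposited dumps are not guaranteed to use these names. SQL dumps are not
  parsed (documented limitation). When a study reports both mean and
  median lifespan, store the mean; the metric is recorded per observation
  so the choice is auditable.
* Writers order rows deterministically, so serialisation is byte-stable
  and load/write round-trips preserve the observation multiset.

## Problem sizes used in the checks

The shipped verification suite sweeps the pair classifier at 0.5% steps
over ±200%, checks the pair reduction on 10,000 random effect triples,
the strict-implies-simple property on an exhaustive 648-instance 3-gene
grid, the $n!$ path law on complete lattices up to $n = 6$ (720 paths)
with randomized node deletions against a permutation oracle, and recovery
at 1,000 replicates per noise level. These sizes were chosen to exercise
the combinatorics convincingly while keeping a full run in the order of a
minute or two on one core.

## Known limitations

* Classification uses point estimates only; no survival-curve statistics
  (log-rank or otherwise) are computed, so "synergistic" is a statement
  about reported means/medians, not about significance.
* Missing intermediates are never imputed from other studies.
* For $n > 2$, the five-way vocabulary is intentionally not extended
  beyond synergistic / not-synergistic (see above).
* The database summary's "Total" rows are row sums across organisms;
  distinctness of genes and articles is computed within organism.
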