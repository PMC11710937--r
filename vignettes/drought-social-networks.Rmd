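---
title: "Association networks, multimodal signal networks and activity budgets: methods"
author: "socioscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Association networks, multimodal signal networks and activity budgets: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socioscope)
```

`socioscope` analyses how stable social groups — harems of plains zebras and
similar group-living equids — reorganise their social associations, their
multimodal communication and their activity budgets between two observation
periods (for example a typical dry season versus a severe drought).  This
vignette documents the models and procedures, the parameters that matter and
their defaults, the numerical choices, and the limits of what the synthetic
data can show.

## Data model

Three data streams enter the pipeline:

* **Scan samples** (`read_scan_table()`): at each sampling occasion every
  member of a harem is recorded with its behaviour and its *nearest
  neighbour* — an individual within one body length — or an explicit `NONE`
  token when no harem member was that close.  `NONE` is deliberately not an
  empty cell: it asserts "observed alone", which carries information for the
  association index, whereas a blank is a data-entry gap and is rejected at
  ingest.
* **Coded interactions** (`read_interaction_table()`): an interaction is an
  ordered sequence of *multimodal postures*, each posture the set of signal
  components (visual, acoustic, tactile, chemical) produced concurrently.
  The ethogram (`read_ethogram()`) partitions components into mutually
  exclusive *morphological groups* — the states of one body part, of which
  at most one can be held at a time — and flags baseline *neutral states*
  such as "eyes open".
* **Focal activity intervals** (`read_activity_table()`): coded behaviour
  within three 5-minute subsample windows per 30-minute focal video, plus
  step counts and interaction events.

## Association analysis

### The simple ratio index

For each within-harem dyad the simple ratio index is

$$\mathrm{SRI} = \frac{x}{y_a + y_b + y_{ab} + x}$$

where `x` counts sampling periods with the pair in association, `y_a` and
`y_b` periods with each member observed alone, and `y_ab` periods with both
observed but not in association.  The nearest-neighbour relation is
symmetrised: a dyad is "in association" in a period if either member named
the other.  Because "observed alone" admits two readings, both are
implemented (`alone_rule`):

* `"scan"` (default): an individual is alone when its record carries the
  `NONE` token and nobody named it as neighbour.  An individual absent from
  a period contributes nothing for that period.  A period in which both
  members were present but, say, each associated with a third animal falls
  to `y_ab`; a period in which both were simultaneously alone is also
  counted once as `y_ab` ("both observed but not in association") so the
  denominator remains a count of periods.
* `"presence"`: the classical formulation — `y_a` counts periods in which
  only `a` was observed — under which the four counts exactly partition the
  periods in which at least one member was observed.

The two rules give identical SRI values whenever joint presence implies
joint observability; they differ only in how solitary observations are
booked.  When a network is restricted to an age class (below), a neighbour
outside the analysed node set (e.g. a young foal) is treated as no
neighbour among the analysed nodes.

### Networks and metrics

`build_harem_network()` takes the dyad tallies for one harem and period.
Nodes are members older than one year (high first-year mortality makes
younger animals transient; unknown ages are assumed adult); edges carry
positive SRI weights.  Per node it reports degree (number of positive-SRI
associates) and the mean and coefficient of variation (CV) of the node's
dyadic SRI values; per harem, network density (edges over possible pairs)
and the harem-level CV of dyadic SRI values.  CVs use the sample standard
deviation (n − 1), a deliberate small-sample choice recorded in the
network's settings; a population-SD variant is available in
`coefficient_of_variation()`.  By default the mean/CV computations include
the structural zeros of co-resident dyads never seen in association
(`include_zero_dyads = TRUE`): excluding them would conflate density with
heterogeneity, but the toggle is provided because field studies differ on
this point.

### Preferred associates

A harem whose members associate indiscriminately shows a low CV of
association strengths; preferred associates inflate it.
`preferred_associate_test()` judges the observed harem CV against a null
distribution, restricted to harems with more than four members (in smaller
harems strong bonds with everyone are attainable and the CV is
uninformative).  Two null models are provided, and the choice matters:

* **Edge randomization** (`null = "edges"`): each replicate places the
  observed multiset of SRI weights on a uniformly random simple graph with
  the same node and edge counts, and recomputes the CV over the dyads among
  the randomized network's *connected* nodes (structural zeros included).
  Because the weight multiset is held fixed, the only thing this null can
  vary is how many nodes the random graph leaves isolated; any statistic
  that is a pure function of the weight multiset would be constant across
  replicates.  The procedure is retained as the literal
  network-permutation null, but it should be understood as descriptive: it
  has essentially no power against dyadic preference, because the evidence
  for preference lives in the weights themselves, which this null
  conditions on.
* **Scan permutation** (`null = "scans"`, the data-stream approach): each
  replicate independently relabels the identities of the individuals
  present within every sampling period, then retallies the SRIs and the
  harem CV.  Group size per period, solitary records and the per-period
  association structure are all preserved; only the identity of who is
  bonded with whom across periods is broken.  This is the null to use for
  inference, and the one under which the packaged calibration and
  planted-preference recovery experiments run.

P-values use the count/n convention (nulls at least as extreme as the
observed, over the number of randomizations), with ties counted toward the
tail; the (count + 1)/(n + 1) variant is available via `convention`.

Cross-period persistence of bonds is quantified by an ordinary least
squares regression of late dyadic SRI on pre dyadic SRI over shared dyads
(`cross_period_dyad_regression()`), and `compare_periods()` emits the
paired harem/node/dyad table that standard paired tests (e.g. Wilcoxon
signed-rank) consume; those tests themselves are deliberately left to
`stats`.

## Multimodal communication analysis

### Cleaning

Components observed in fewer than two distinct interactions are too rare to
characterise; `clean_postures()` removes every posture containing one.
Removing postures can push another component below the threshold, so the
filter iterates to a fixed point by default (`iterate = FALSE` gives the
single-pass variant); the report records postures in/out, passes, and the
dropped components.

### Network, diversity, adjusted density

`build_comm_network()` joins two components with weight equal to the number
of postures in which they co-occurred (postures are the coded unit of
concurrency; an interaction-level weighting is available via
`weight_unit`).  *Component diversity* is the number of connected nodes —
components with at least one co-occurrence partner.  Ordinary graph density
is misleading here because states of one morphological group can never
co-occur, so `adjusted_density()` divides the observed edges by
`choose(n, 2)` minus the impossible within-group pairs
(`impossible_pairs()`, $\sum_g n_g (n_g - 1) / 2$ over the groups present
in the node set at hand — node-subsampled networks recompute group sizes
from the subset).

### Resampling nulls

Both cross-period comparisons are judged two-tailed against the 0.025 and
0.975 percentiles of a resampling null, ties resolved conservatively as
non-significant:

* `diversity_jackknife()` draws repeated subsamples of the reference
  period's postures, equal in number to the comparison period's postures,
  and records the diversity of each rebuilt network: the null of a
  repertoire that only *looks* smaller because fewer postures were
  sampled.  Subsampling is without replacement; subsampled networks are not
  re-cleaned.
* `density_node_subsample_null()` induces subgraphs of the reference
  network on random node subsets of the comparison period's size and
  recomputes adjusted density: the null of a repertoire that shrank
  without losing combinatorial flexibility among the retained signals.

### Modules

`detect_modules()` runs greedy agglomerative (fast-greedy) modularity
maximisation on the weighted graph, cutting the merge tree explicitly at
the modularity-maximising step; vertices are processed in lexicographic
order so results are reproducible.  The modularity score Q is reported, and
the conventional Q > 0.3 threshold for "discrete modules" is interpretive
annotation only — it never filters anything.  `compare_modules()` aligns
late modules to pre modules by plurality overlap and classifies every
component as retained, reassigned, lost or new, the table behind
alluvial-style module-flow plots; `modality_loss_summary()` counts lost
components per sensory modality.

## Activity budgets

`compute_budget()` turns coded intervals into per-focal, per-period
proportions of coded time over the behaviour taxonomy
(`default_taxonomy()`: self-maintenance; passive social = proximity-based
behaviour concurrent with maintenance, i.e. social grazing and social rest;
active social = dedicated interactions).  Passive social categories
supersede the concurrent maintenance category, so no second is counted
twice.  Only coded time enters the denominator; uncodeable time is excluded
(a documented, deliberate choice — off-camera travel logged as `traveling`
intervals is merged in when supplied).  `interaction_rate()` counts
*active* social interactions per 30-minute block; passive association never
counts as an interaction.  `partner_shift_table()` builds the juvenile
mother/non-maternal partner contingency table for a chi-square test, which,
like the other routine comparisons (Mann–Whitney, mixed models), is left to
standard routines on the emitted tables.

## Synthetic data and what it can show

The generators (`simulate_scans()`, `simulate_interactions()`,
`simulate_budgets()`) emulate the study conditions: 21 harems of 2–13
members (sizes 2 + Poisson(3), mean ≈ 5), members present in a scan with
probability 0.9 and alone with probability 0.25, defaults chosen once as
field-realistic; preferred dyads are planted by multiplying a pair's
mutual nearest-neighbour choice weight.  Interactions sample a latent
context (an aggression-, greeting- or affiliation-like module) and include
each component with probability 0.4 inside its context and 0.02 outside,
scaled by a per-component base rate — the rarity dial behind the cleaning
and diversity experiments; neutral states join any posture with
probability 0.6, reproducing their high centrality.  Group exclusivity
holds by construction, and every generated dataset passes ingest
validation.  The end-to-end simulated dataset gives components a
log-spaced abundance spectrum, so rare signals, cleaning and repertoire
loss all occur.

The generators do not simulate movement ecology, spatial structure,
observation effort biases, or temporal autocorrelation within a day.
Passing recovery tests therefore shows that the estimators and nulls do
what they claim under the stated generative model — not that field data
meet that model.

## Numerical choices and experiment sizes

* Every stochastic operation takes an explicit integer seed; the pipeline
  derives stage seeds deterministically from one master seed, and repeated
  runs are byte-identical.
* Permutation defaults are 1000 replicates; the packaged validation
  experiments use 200 replicates per test with 400–500 dataset replicates
  for size (calibration) checks and 200 for power (recovery) checks, sizes
  chosen to estimate a 5% rate with a usefully narrow exact binomial
  interval while keeping the suite quick on one core.
* Calibration experiments generate one posture per interaction: posture
  subsampling is then exchangeable with fresh sampling, isolating the
  resampling null from interaction-level clustering.  They also run on
  uncleaned postures, so they measure the resampling test itself rather
  than its interaction with the cleaning filter.
* Degenerate inputs are defined, not crashed: an all-zero SRI denominator
  yields 0 with a warning; CVs need two values and a positive mean, else
  `NA`; harems under two eligible members report missing density; edgeless
  graphs get singleton modules with Q = 0; empty neutral sets make
  `neutral_subgraph()` the identity with a warning.

## Known limitations

* **The edge-randomization null is descriptive, not inferential.**  As
  explained above, holding the weight multiset fixed leaves nothing for a
  weight-based statistic to vary over except isolated-node dropout.  Use
  `null = "scans"` to test for preferred associates.
* **The node-subsampling density null understates sampling noise.**  It
  conditions on the reference network's realised edges, so the only
  variance it represents is node choice.  An independently collected
  comparison dataset additionally carries edge-sampling noise (rare pairs
  flicker in and out with sample size), which the null cannot see: in the
  packaged calibration experiment its rejection rate under a true null is
  far above the nominal 5% even at equal sample sizes.  Its verdicts
  should be read as "outside the range explainable by node count alone
  given the reference wiring", not as calibrated p-values.  The posture
  jackknife for diversity does not share this problem — subsampling
  postures reproduces the sampling process — and is calibrated in the same
  experiment.
* The diversity jackknife subsamples without replacement from a finite
  reference, mildly narrowing the null when the subsample is a large
  fraction of the reference; with the study-scale ratio (~0.3) the effect
  is small.
* Module alignment across periods uses plurality overlap, which is
  descriptive; module labels themselves carry no meaning.

## Interfaces

The package is driven from R: `run_pipeline()` executes the full analysis
(ingest or simulate → association networks and tests → communication
networks and nulls → budgets) from one list or YAML config, writes CSV
tables, GraphML networks and a JSON results manifest, and is deterministic
given inputs, seed and flags.  `scripts/acceptance.R` reruns the pipeline
at study-scale defaults and writes the headline quantities as JSON.
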