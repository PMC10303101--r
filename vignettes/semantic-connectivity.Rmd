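---
title: "Semantic connectivity mapping of cardiometabolic and hair-element variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic connectivity mapping of cardiometabolic and hair-element variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(autocmap)
library(ggplot2)
```

## The problem this package addresses

Hair element analysis (the "hair mineralogram") is a cheap, non-invasive
read-out of medium-term exposure to toxic metals and of trace-element status.
In adults with overweight-obesity, the interplay between the metal body
burden, metabolic syndrome (MetS) and cardiovascular (CV) risk involves many
weakly and non-linearly coupled variables, which frustrates conventional
regression modelling. `autocmap` implements an unsupervised workflow for this
setting:

1. encode every variable of a subjects-by-variables cohort table onto a
   common `[0, 1]` scale (dichotomization by default);
2. train an **Auto-Contractive Map (Auto-CM)**, a three-layer contractive
   neural network that learns a variable-by-variable weight matrix capturing
   the simultaneous, non-linear association structure;
3. normalise the trained weights into **link strengths** in `[0, 1]`, turn
   them into distances `d = 1 - s`, and extract the **minimum spanning
   tree** — the *semantic connectivity map*, in which adjacent nodes have
   the highest mutual affinity and highly connected nodes act as hubs;
4. perturb the learned system with an **Activation and Competition System
   (ACS)**: clamp one variable at maximal activation and report the order and
   intensity with which the remaining variables respond.

Because the cohort that motivated this design is not publicly available, the
package ships a calibrated synthetic-cohort generator that reproduces the
published summary statistics of that 95-subject population and plants the
correlation structure the analysis is meant to discover. Everything the
package demonstrates about recovery therefore refers to this generator, not
to the original patient data.

## The synthetic cohort generator

`default_study_spec()` encodes the emulated study population:

* the 25 published clinical variables (21 sampled primitives plus four
  derived indices), each with mean, SD, minimum, maximum and median;
* the 31 hair elements (13 toxic, 18 essential), modelled as truncated
  lognormals — hair concentrations are positive and strongly right-skewed;
* auxiliary variables needed by the index formulas but absent from the
  published tables: age (51 ± 12 y, truncated to 30–79, the domain of the
  VAI cutoffs and the Framingham tables), sex (Bernoulli 0.5), HDL
  cholesterol (52 ± 13 mg/dL), GGT (lognormal, mean 30, SD 20 U/L), smoking
  (0.25) and antihypertensive treatment (0.2). These are *not* calibrated to
  the emulated study (which does not report them) and are overridable.

### Calibration

For each sampled variable the generator matches the distribution *after*
truncation to the published `[min, max]`: the location parameter is solved by
root finding so that the truncated mean equals the published mean exactly,
and the scale parameter is then chosen to minimise the squared error in the
truncated SD (analytic truncated-normal and truncated-lognormal moment
formulas). Matching the *untruncated* lognormal by the closed-form method of
moments (`lognormal_params_from_moments()`, kept as the documented
primitive) and then truncating would bias the realised means of the
heavy-tailed elements by several percent — for Barium, roughly 1.24 instead
of the published 1.29 ug/g — which is why the calibration targets the
truncated moments.

A published mean that coincides with the published minimum (a rounding
artifact, e.g. Germanium) is nudged just inside the attainable range. For a
few extremely skewed elements the best-fitting truncated lognormal is an
extreme-tail shape whose acceptance region is essentially unreachable by
rejection; sampling therefore uses rejection first (it preserves the
interior shape and the planted factor contribution) and falls back to an
exact inverse-CDF truncated draw for any value rejection cannot place. SDs
are reproduced as closely as the truncation allows; means are reproduced
within Monte-Carlo error:

```{r calibration}
spec <- default_study_spec()
ba <- sample_marginal(spec, "Ba", 20000, seed = 1)
c(mean = mean(ba), published = 1.29)
```

### Planted correlation structure

Correlation is induced on the latent z-scale: each variable is driven by
shared standard-normal factors plus idiosyncratic noise, standardised to unit
variance so the calibrated marginals are untouched by the loadings. The
default structure has a *metabolic* factor (WC, BMI, TG, insulin, glycaemia,
HbA1c, fibrinogen, uric acid; loading 0.6) and an *exposure* factor (the 13
toxic elements; loading 0.6) — the two arms the semantic map is expected to
organise around. Derived indices (FLI, VAI, Framingham points, MetS, obesity,
toxicity index) are always computed from the sampled primitives, never
sampled, so their associations with their inputs are structural, as in real
data.

What the generator does *not* emulate: measurement error and laboratory
batch effects, missingness, the discreteness of counts, non-Gaussian copulas
between blocks, and any real causal structure. Passing recovery tests on
these cohorts shows the pipeline can find a planted two-block association
structure at realistic sample sizes — not that the original study's map is
correct.

## Composite indices

All study indices are implemented from their published definitions:

* **Fatty liver index** (`fatty_liver_index()`): logistic score in
  `[0, 100]` from TG, BMI, GGT and WC; `< 30` rules fatty liver out,
  `>= 60` rules it in.
* **Visceral adiposity index** (`visceral_adiposity_index()`): sex-specific
  product form; TG and HDL in mmol/L (converters provided and a unit guard
  rejects TG values that look like mg/dL). Age-specific reference cutoffs
  follow the printed bands; the printed band edges (41/42, 65/66) are
  half-open on the right, `[30, 42), [42, 52), [52, 66), [66, Inf)`, which
  makes the lookup total while reproducing every printed value.
* **Framingham risk** (`framingham_risk()`): the office-based ATP III
  sex-specific point tables, embedded as data, with the published
  points-to-risk lookup. Risks printed as "<1%" are encoded 0.5 and
  ">=30%" as 30. Diabetes is a CHD risk equivalent rather than a point-table
  entry; with `diabetes = TRUE` the risk percentage is floored at 20.
* **MetS** (`mets_atpiii()`): at least 3 of the 5 ATP III components (2005
  revision, fasting glucose >= 100 mg/dL). Missing components raise an
  error; nothing is imputed silently.
* **Toxicity index** (`toxicity_index()`): weighted average
  `sum(w c) / sum(w)` over the 13 toxic elements. The original laboratory's
  per-gram relative-toxicity weights are proprietary, so the default
  operationalises "relative toxicity per gram" as the inverse of the
  tolerated hair level, `w = 1 / reference_upper`. This is a reimplementation
  choice; any positive weight vector can be supplied.
* The Italian "Progetto Cuore" CV risk charts are not reproduced;
  `progetto_cuore_risk()` is a documented pluggable stub passing through a
  Framingham-derived percentage.

```{r indices}
cohort <- simulate_cohort(spec, seed = 1)
idx <- cohort_indices(cohort)
dplyr::glimpse(idx[1, ])
```

## Preprocessing

The mapping stage needs every variable on a proportional scale.
`dichotomize()` binarizes at the per-variable median (the most balanced
achievable split; ties at the median go to 0), which is the package's
reading of "high versus low" encoding; a per-variable split override and a
`minmax` mode are available. Constant variables raise a degenerate-variable
error rather than being encoded silently; `encode_cohort()` drops them (and
variables with more than 10% missing values) with a warning and imputes the
remaining missing entries by the variable median. The default variable panel
is the full study set — 25 clinical variables, all 31 elements, the derived
toxicity/MetS/obesity flags and age — with *no pruning*, matching the
hypothesis-free design of the mapping stage.

## The Auto-Contractive Map

Three layers of `N` units. For each record `m_s` in `[0, 1]^N`:

* hidden contraction: `m_h = m_s * (1 - v/C)`, with adaptation
  `dv = lr * (m_s - m_h) * (1 - v/C)`;
* output contraction through the `N x N` matrix `w`:
  `net_i = sum_j m_h[j] * (1 - w[i,j]/C)`, `m_t = m_h * (1 - net/C)`, with
  adaptation `dw[i,j] = lr * (m_h[i] - m_t[i]) * (1 - w[i,j]/C) * m_h[j]`.

All weights grow monotonically toward the contraction parameter `C`, every
factor `(1 - ./C)` stays in `[0, 1]`, and training converges when the hidden
signal vanishes. Numerical choices, all overridable via `autocm_params()`:

* `C = N` (the variable count), which guarantees `net <= C` and hence
  non-negative output contractions for any `[0, 1]` input;
* learning rate 0.1, tolerance 1e-6 on the mean absolute weight change per
  epoch, at most 2000 epochs;
* all weights initialised to the same small positive value (0.01): a zero
  initialisation is a fixed point of the `v` update, and a common value
  keeps training deterministic and symmetric across variables;
* records are presented in fixed dataset order, no shuffling — training is
  bit-reproducible.

Pairs of variables that are repeatedly co-active accumulate larger `w`
entries. `link_strengths()` symmetrises `w` by the arithmetic mean (the map
is undirected), divides by the global maximum, and sets the diagonal to 1,
yielding strengths in `[0, 1]` invariant to any rescaling of `w`.

```{r train}
enc <- encode_cohort(cohort)
model <- train_autocm(enc)
glance(model)
```

## The semantic connectivity map

Distances `d = 1 - s` feed a minimum spanning tree. Kruskal's algorithm is
used with a fully deterministic tie-break (edges ordered lexicographically by
distance, then by the two node labels), so equal-weight instances always
yield the same tree. Hub scores are node degree and summed incident
strength; the central node maximises degree, with summed strength as the
tie-break.

```{r map, fig.width = 7, fig.height = 6}
map <- semantic_map(strengths_to_distances(link_strengths(model)))
glance(map)
head(tidy(map))
autoplot(map, label_edges = FALSE)
```

Maps export to GraphML (round-trippable), Graphviz DOT (strength labels to
two decimals, central node highlighted) and a flat edge CSV.

## The Activation and Competition System

The ACS probes the learned association structure: one variable is clamped at
activation 1, every other unit starts at a resting level `r` and evolves by

```
a_i <- clip_[0,1]( a_i + g * [ sum_j s_ij (a_j - a_i) - lambda (a_i - r) ] )
```

Excitation flows through the positive couplings; the `lambda` leak is the
competitive force pulling units back to rest, so only units with strong
enough paths to the clamped source stay activated. The step gain `g` is
divided by the largest total coupling of any unit, a normalisation that
keeps the discrete dynamics contractive for dense strength matrices without
moving any fixed point. Defaults: `r = 0.5`, `g = 0.1`, `lambda = 0.5`,
steady tolerance 1e-5, at most 5000 iterations, first-passage threshold
`r + 0.1`.

Useful closed forms, used as test oracles: with zero couplings the system is
inert at rest, and in the 2-node system with coupling `s` the free node's
steady state is `(s + lambda r) / (s + lambda)`, strictly increasing in `s`.

The published exposition of the Auto-CM/ACS pair fixes the behavioural
contract (clamping, `[0, 1]` activations, competition, steady-state stop)
without a full update-rule listing in the text available to us; the rule
above is this package's formulation satisfying that contract, and its fixed
points are documented so users can reason about it exactly.

`activation_hierarchy()` ranks the non-clamped variables by first-passage
iteration (ties by steady intensity); variables that never cross the
threshold are listed last as non-responders. The hierarchy describes
*activation timing only* — the package attaches no causal claim to it.

```{r acs, fig.width = 7, fig.height = 4}
strengths <- link_strengths(model)
acs_res <- run_acs(strengths, acs_params("framingham"))
head(activation_hierarchy(acs_res))
autoplot(acs_res)
```

Mirroring the published perturbation design, the pipeline can prune the 31
single-element variables from the ACS stage (`exclude_elements = TRUE`)
while keeping the composite toxicity index; the semantic map itself is never
pruned.

## Design choices where the design was open

* **Which variables enter the map.** The default panel is the 25 published
  clinical variables plus all 31 elements plus the derived flags and age;
  configurable via `encode_cohort(variables = )`.
* **ACS couplings.** The ACS reuses the Auto-CM link strengths rather than
  training a separate auto-associative network; any strength matrix can be
  passed to `run_acs()` directly.
* **Dichotomization split.** The median, as the most balanced "high/low"
  cut; per-variable overrides accepted.
* **VAI band edges** and **toxicity weights**: see above.

## Problem sizes used in the tests

The structure-recovery checks use planted two-factor cohorts of 10 variables
(five per factor, loadings 0.7) at n = 2000 subjects, 50 replicates, against
a 1000-resample permutation baseline on the recovered trees; marginal
calibration is checked at n = 100000 draws per element. These sizes give
stable Monte-Carlo behaviour for the properties being tested and are the
package's standing choices.

## Known limitations

* The semantic map is a tree: it shows each variable's strongest affiliation
  path, not the full correlation graph; near-ties can flip peripheral edges
  between seeds.
* Link strengths are relative (normalised by the global maximum within a
  run) and should not be compared across cohorts.
* Dichotomization discards within-half variation; rare binary variables
  carry little signal at n = 95.
* The toxicity index depends on the chosen weights; the default inverse
  reference-limit weighting is a transparent stand-in for a proprietary
  scheme and will not reproduce laboratory-issued TI values.
* The ACS hierarchy is a property of the learned association matrix; it is
  not evidence of causal direction.
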