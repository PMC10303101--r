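# autocmap

Auto-Contractive Map semantic connectivity analysis for cardiometabolic
cohorts with hair trace-element panels.

## What it is for

In adults with overweight–obesity, metabolic syndrome (MetS), cardiovascular
(CV) risk and the metal body burden measured by hair mineralograms form a
densely and non-linearly coupled variable system that is awkward to model
with standard regression. `autocmap` provides the unsupervised workflow used
in that setting, end to end:

- a **synthetic cohort generator** calibrated to the published summary
  statistics of a 95-subject overweight–obesity study population (25
  clinical variables, 31 hair elements with their reference intervals),
  with a planted latent-factor correlation structure — for method
  development and validation when the real patient data are unavailable;
- **composite cardiometabolic indices**: fatty liver index (FLI), visceral
  adiposity index (VAI) with age-specific cutoffs, the ATP III Framingham
  point score, ATP III metabolic syndrome, an obesity flag, and a hair
  **toxicity index** (TI) as a weighted average of the 13 toxic-element
  concentrations;
- the **Auto-Contractive Map (Auto-CM)**: a three-layer contractive neural
  network trained on `[0,1]`-encoded variables. Weights adapt by
  `dw[i,j] = lr * (m_h[i] - m_t[i]) * (1 - w[i,j]/C) * m_h[j]`, growing
  monotonically toward the contraction parameter `C`; the trained matrix is
  symmetrised and normalised into **link strengths** `s ∈ [0,1]`;
- the **semantic connectivity map**: the minimum spanning tree over
  distances `d = 1 - s`, with hub statistics, GraphML/DOT/CSV export and a
  ggplot `autoplot()`;
- the **Activation and Competition System (ACS)**: clamp one variable at
  activation 1 and iterate
  `a_i <- clip[0,1](a_i + g (Σ_j s_ij (a_j - a_i) - λ (a_i - r)))`
  to a steady state, reporting the activation hierarchy (first-passage
  order and steady intensities).

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods, and a
`run_pipeline()` orchestrator emits all artifacts of a run reproducibly from
one seed.

## Worked example

```r
library(autocmap)

cohort <- simulate_cohort(default_study_spec(), seed = 1)   # 95 subjects
idx    <- cohort_indices(cohort)
idx[1:4, c("subject_id", "fli", "fli_class", "vai", "framingham_points", "mets", "ti")]
#>   subject_id   fli fli_class               vai framingham_points mets      ti
#> 1 S001        46.7 indeterminate         1.99                 14 FALSE 0.503
#> 2 S002        47.2 indeterminate         0.673                12 TRUE  0.191
#> 3 S003        33.3 indeterminate         0.531                 3 FALSE 0.0752
#> 4 S004        84.3 fatty liver indicated 2.76                 12 TRUE  0.0593

enc   <- encode_cohort(cohort)            # median dichotomization, no pruning
model <- train_autocm(enc)
glance(model)
#>   n_variables n_records contraction epochs_run converged final_delta
#> 1          60        95          60        204 TRUE      0.000000990

map <- semantic_map(strengths_to_distances(link_strengths(model)))
map
#> <semantic_map> 60 nodes, 59 edges; central node: ti
#>    from       to      distance strength
#>  1 bmi        obesity   0.0553    0.945
#>  2 tg         vai       0.0919    0.908
#>  3 fli        wc        0.0972    0.903
#>  4 glycaemia  mets      0.0999    0.900
#>  5 Cd         ti        0.102     0.898
#>  ...
```

The strongest tree edges tie BMI to the obesity flag, triglycerides to the
VAI, the FLI to waist circumference, glycaemia to MetS, and the toxic metals
(Cd, Ni, Hg) to the toxicity index — the planted metabolic and exposure
clusters re-emerging from the trained map. Clamping the Framingham score
then ranks the other variables by response timing:

```r
acs <- run_acs(link_strengths(model), acs_params("framingham"))
head(activation_hierarchy(acs), 3)
#>   variable first_passage steady_intensity responder  rank
#> 1 age                170            0.782 TRUE          1
#> 2 cv_risk            171            0.782 TRUE          2
#> 3 tg                 172            0.782 TRUE          3
```

`autoplot(map)` and `autoplot(acs)` draw the tree and the activation curves.
A thin command-line wrapper with `simulate` / `indices` / `map` / `acs` /
`all` subcommands lives at `inst/scripts/run_pipeline.R`.

## Notes

- The toxicity-index weights of the original laboratory are proprietary; the
  default here is the inverse reference upper limit per element, documented
  as a reimplementation choice and fully overridable.
- The Italian "Progetto Cuore" CV risk charts are not reproduced;
  `progetto_cuore_risk()` is a pluggable stub.
- See `vignettes/semantic-connectivity.Rmd` for the model details, numerical
  choices and known limitations.
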