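# cytoclassify

Supervised classification of individual flow-cytometry (FCM) events
against a library of predefined cell and bead standards, with downstream
community composition, similarity, diversity and biomass estimation.

## Who this is for

Microbiologists and bioprocess/environmental scientists who want to turn
raw multiparametric FCM event data — seven parameters per particle
(FITC-A, FITC-H, FSC-A, FSC-H, SSC-A, SSC-H, Width) — into quantitative
"cell type" profiles of microbial communities within minutes of
acquisition, as a rapid complement to amplicon sequencing. You measure a
set of *standards* (pure strains, growth states, calibration beads) once;
the package learns their optical signatures; every later sample is
classified event by event against those classes.

## The method

Events are filtered per parameter to `[lower, upper]` raw-intensity bounds
(default 100 to 1e7), log10-transformed, and — for standards with several
visible subpopulations — split by rectangular gates in FITC-H/SSC-H/FSC-H.
Each standard is subsampled to *n* = 10,000 events; two *anchor* events at
the log bounds pin the min–max scaling to [−1, 1] so scaling constants are
a function of the filter, not of the data. A feed-forward network

- 7 input nodes → 20 logistic hidden nodes → K softmax output nodes,

is trained by full-batch scaled conjugate gradient on the categorical
cross-entropy over a random 50/25/25 train/validation/test split, stopping
at 1000 cycles, gradient norm < 1e-6, or 6 consecutive validation
failures (best-validation weights kept). The whole procedure is repeated
five times with independent seeds; every reported figure is a mean ± SD
over the replicate classifiers.

Each event is assigned to its highest-probability class (argmax of the
softmax). Downstream:

- recall_k = 100·C[k,k]/Σ_j C[k,j], precision_k = 100·C[k,k]/Σ_i C[i,k]
  from the confusion matrix C, plus one-vs-rest ROC curves;
- *correct predicted classification* (CPC) = attributed events in the
  target class(es) as % of the spiked count (may exceed 100%);
- *classification similarity score* = 100 × (mean winning probability of
  query cells in a class) / (mean winning probability of the standard's
  own cells), e.g. 100 × 0.806/0.994 ≈ 81%;
- richness (classes > 0.05% relative abundance), Shannon index
  H = −Σ p ln p, and pairwise Bray–Curtis dissimilarities on counts;
- biomass via the allometric law m_b = 435·V^0.86 (fg dry weight from
  µm³ biovolume; carbon = m_b/2), summed over classified counts, and
  yields as g biomass-C per g substrate-C; absolute densities from
  volumetric counting.

A synthetic-data module generates 7-parameter log-scale Gaussian standards
(optionally with subpopulations) and mixed communities with per-event
truth, so every pipeline stage is testable without instrument data.

## Worked example

Train a five-replicate ensemble on the bundled five-standard synthetic
fixture and evaluate on freshly generated held-out events:

```r
library(cytoclassify)

specs     <- demo_standard_specs(n_events = 5000)
standards <- lapply(seq_along(specs), function(i)
  generate_standard(specs[[i]], seed = i))
ens <- train_ensemble(standards, 5000, training_config(seed = 1),
                      n_replicates = 5)
#> <classifier_ensemble> 5 replicate models, test accuracy 1.000 +/- 0.000

held  <- lapply(seq_along(specs), function(i)
  generate_standard(specs[[i]], seed = 100 + i, n_events = 1000))
truth <- rep(names(specs), each = 1000)
met <- ensemble_metrics(truth, classify_events(ens, bind_events(held)))
met$per_class
#>   class recall_mean recall_sd precision_mean precision_sd
#> 1   AJH         100         0            100            0
#> 2  ECL1         100         0            100            0
#> 3  ECL2         100         0            100            0
#> 4  PVR1         100         0            100            0
#> 5  PVR2         100         0            100            0
```

At more than 6 pooled SD of cluster separation the fixture is recovered
perfectly; recall degrades gracefully as clusters merge:

```r
base <- synthetic_standard_spec("base", rep(4, 7), sd = 0.15)
separability_sweep(base, c(0, 2, 4, 8), training_config(seed = 7),
                   n_per_standard = 2000, n_eval = 1000, seed = 7)
#>   separation recall_A recall_B mean_recall
#> 1          0      9.6     90.3       49.95
#> 2          2     86.5     81.7       84.10
#> 3          4     98.4     97.6       98.00
#> 4          8    100.0    100.0      100.00
```

At separation 0 the two "classes" share one distribution, so per-class
recall is arbitrary but their mean sits at chance (50%); at 8 SD the
classifier is perfect. Similarity scoring and biomass work on any
classified sample:

```r
classification_similarity_score(0.806, 0.994)$rounded  # 81 (%)
allometric_biomass(1)                                  # 435 (fg dry weight)
absolute_density(5000, analyzed_volume = 20, dilution_factor = 100)
#> 2.5e+07  (cells per ml)
```

A thin command-line wrapper over the same functions ships at
`inst/cli/cytoclassify.R` (subcommands `train`, `classify`, `evaluate`,
`diversity`, `biomass`, driven by a YAML standards manifest).

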