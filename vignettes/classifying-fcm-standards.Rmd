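---
title: "Classifying flow-cytometry events against cell and bead standards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying flow-cytometry events against cell and bead standards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytoclassify)
```

## The problem and the model

Flow cytometry records a handful of optical measurements per particle at
tens of thousands of particles per second, but those measurements carry no
direct taxonomic meaning. cytoclassify treats the question "what is this
cell?" as supervised classification: a library of *standards* — pure strain
cultures and calibration beads, each measured individually on the same
instrument with the same stain — defines the output classes, and a small
feed-forward neural network learns to map a single event's seven parameters
(FITC-A/H for SYBR Green I fluorescence, FSC-A/H and SSC-A/H scatter, and
pulse Width) to a probability vector over the K classes.

The network is deliberately small: 7 inputs, one hidden layer of 20
logistic units, and a K-unit softmax output, trained by full-batch scaled
conjugate gradient on the categorical cross-entropy. With seven inputs and
clusters that are roughly ellipsoidal in log10 intensity space, this
capacity is sufficient; anything larger mostly invites overfitting of the
within-standard heterogeneity that is the true limit on accuracy.

## Data pretreatment

Raw exports are filtered per parameter between a lower bound (100 by
default) and an upper bound (default 1e7; instruments typically saturate
between 1e5 and 1e7) and then log10-transformed. The lower bound also
guarantees the logarithm is defined. Standards whose log-scale clouds show
several distinct subpopulations are split by rectangular gates in the three
height parameters (FITC-H, SSC-H, FSC-H), inclusive on both bounds; each
gated subpopulation that holds at least 5% of the standard's events becomes
its own class. Gate discovery is manual by design — the subpopulations are
identified by eye on 2D log-scale plots — and events matching several gates
go to the first matching gate in manifest order, a deterministic rule in
place of manual judgement.

## Anchoring and scaling

Each standard is randomly subsampled to the same size (10,000 events by
default) so classes are balanced. Before concatenation, two synthetic
events are appended to the first standard: one with every parameter at the
log10 lower filter bound, one with every parameter at the upper bound.
These *anchors* pin the per-parameter minimum and maximum of the combined
matrix, so the subsequent min-max scaling to [-1, 1] is a fixed function of
the filter configuration rather than of the biological data. Any two
training sets built under the same filter therefore share identical scaling
constants, and a stored model can be applied to new samples without
re-deriving scale factors. Two composite anchor rows suffice to pin all
seven ranges; they carry the first standard's class label (2 events out of
10,000 is negligible contamination of that class) and are flagged so they
can be excluded from every reported metric. One side effect is worth
knowing: because the anchors are labelled, the decision regions around the
all-low and all-high corners of parameter space — far from any real
training cluster — tend to belong to the first class, so events in those
otherwise-empty corners are attributed to it. At prediction time, events
falling outside the scaled range are clipped to [-1, 1] with a warning
count.

## Training, early stopping, replicates

The concatenated, scaled events are randomly partitioned 50/25/25 into
training, validation and test blocks. Weights start at small uniform random
values (seeded, so a fit is reproducible), and scaled conjugate gradient
runs for up to 1000 cycles, evaluating the validation cross-entropy once
per cycle. Training stops at the cycle limit, when the gradient norm drops
below 1e-6, or when the validation loss has failed to improve for 6
consecutive cycles; the returned weights are those of the best validation
point. The optimizer is recorded in the training log; the scientific
content lies in the stopping and validation semantics, not in line-search
details, so any deterministic full-batch minimizer honouring those rules
would be admissible.

Because subsampling, splitting and initialization are all stochastic, the
whole procedure is repeated five times with independent seeds, giving an
ensemble of slightly different classifiers. All reported performance
numbers are means ± SD over the replicates — never pooled counts — so the
SD honestly reflects training variability.

## Reading the outputs

Each event is assigned to its highest-probability class (ties, which arise
only with degenerate weights, go to the lowest class index). Aggregating
assignments gives a community profile; the softmax maximum of each event —
its *winning probability*, always at least 1/K — is the raw material for
similarity analysis. The mean winning probability of cells attributed to a
class, divided by the mean winning probability of the standard's own cells
in that class, is the *classification similarity score* (in percent): 100%
for the standard itself, lower for lookalikes. Accuracy is reported both as
the mean of per-class recall and as overall accuracy (confusion-matrix
trace over total), clearly labelled, because the two differ whenever class
sizes differ.

*Correct predicted classification* (CPC) for spike-in experiments is the
number of events attributed to the target class (or class group, e.g. all
subpopulations of one strain) as a percentage of the number spiked; it can
exceed 100% when background events are co-attributed.

Diversity summaries use assigned-class counts: richness counts classes
above a relative abundance threshold (0.0005, i.e. 0.05%, by default),
the Shannon index uses natural logarithms with 0·ln 0 = 0, and Bray-Curtis
dissimilarity is computed on counts as 1 − 2·Σmin/Σtotal.

## Biomass and density

Per-cell biovolume V (µm³, from 3D imaging, supplied as a table) converts
to dry mass by the allometric power law m_b = 435·V^0.86 fg, and to carbon
at half the dry mass. Community biomass multiplies each class's (mean)
event count by its per-cell carbon mass and sums; lower/upper bounds come
from pushing mean ∓ SD biovolume through the same power law, per class,
then summing. Bead classes are excluded from biomass totals by default —
polystyrene is not biomass — but can be included (flagged, using the same
power law on bead volume as a proxy) because unknown cells are routinely
attributed to bead classes. Yield divides net produced biomass carbon by
added substrate carbon; both a raw and a control-subtracted value can be
formed by the caller, since whether to subtract an unamended control is a
study-design question, not a package decision. Volumetric counting gives
absolute densities directly: events / analyzed volume × dilution.

## The synthetic generator

Real standards are multi-hundred-thousand-event datasets tied to one
instrument. For development and testing, `synthetic_standard_spec()` and
`generate_standard()` draw standards as (mixtures of) multivariate
Gaussians in log10 space, truncated to the filter bounds by rejection
sampling — emulating the ellipsoidal clusters real standards show on
log-scale cytograms, including multi-subpopulation standards.
`generate_community()` pools weighted components with per-event truth
labels ("unknown" for background), and `demo_standard_specs()` ships a
five-standard fixture (one single-population class plus two two-subpopulation
strains' worth of classes, mutual separations above 6 pooled SD within the
default bounds) mirroring a three-species proof-of-concept community.

What the generator does **not** emulate: instrument noise structure,
saturation pile-ups at the bounds, doublets, within-run drift, or the
heavy-tailed, correlated spreads of real strain standards. Passing tests on
synthetic data therefore demonstrate that the machinery is correct and that
separable classes are recovered — not that any particular real community
will be classified at a given accuracy, which depends on how distinct the
chosen standards' optical signatures are.

## Numerical choices and problem sizes

Softmax is computed with row-max subtraction; cross-entropy clamps
probabilities away from zero before the log. Rejection sampling aborts with
a clear error if a requested cluster has (numerically) no mass inside the
bounds. Subsampled row order is kept sorted so a subsample is a
row-subset of its source. Model files are JSON with doubles printed as
`%.17g`, which reloads bit-exactly.

The test suite trains on reduced problem sizes chosen to exercise the same
code paths at desk scale: the end-to-end ensemble check uses the full
10,000 events per standard; chance-floor and separability checks use
1,500–2,000 events per class, where a nearest-centroid oracle already
achieves the reference recall at 8 SD separation and chance behaviour is
measurable to well under the tolerance.

## Known limitations

- Classes are forced-choice: every event, including genuinely novel cell
  types, is attributed to some standard. Similarity scores mitigate but do
  not remove this.
- Probability-distribution comparisons beyond the mean (thresholding or
  binning of the winning-probability histograms) are exposed as data but no
  distance statistic is imposed.
- FCS binary files are not parsed; events enter as delimited exports (the
  instrument's CSV export, or any table with the seven named columns).
- Gates are axis-aligned boxes; curved or density-based gating is out of
  scope.
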