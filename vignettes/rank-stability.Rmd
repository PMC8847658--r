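---
title: "Ranked network-feature stability: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranked network-feature stability: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rankstab)
```

## The model

`rankstab` treats a multichannel recording as a sequence of weighted
functional networks: the recording (N channels × l samples) is cut into
⌊l/w⌋ non-overlapping windows of w samples, and within each window the
weight between channels j and k is the absolute Pearson correlation of
their samples.  Every network is complete — no thresholding or pruning —
so weak links contribute to node-level features.

Per window we extract one ranked feature:

* the **strongest link** (the unordered channel pair of maximal weight);
* the **top-m link set** (the m largest-weight links, as an unordered set —
  ranking within the set is allowed to fluctuate);
* the **most central node** (largest strength centrality, i.e. largest
  incident weight sum);
* the **highest-clustering node** (largest weighted local clustering,
  computed as the geometric-mean triangle intensity on weights normalised
  by the network maximum, with the (N−1)(N−2) complete-graph denominator,
  so a uniform network has clustering exactly 1 at every node).

The temporal persistence of a feature is scored against a null in which
consecutive networks are completely independent.  If the modal identity
(the value the feature takes most often) occurs k times in n windows, and a
single random draw would hit a fixed identity with probability p, then

  π = B(n, p, k)

is the probability of a modal streak at least that large arising by
chance.  We work with ln π throughout; more negative is more stable.  The
per-trial probability p is uniform over the identity space: 1/(N(N−1)/2)
for links, 1/N for nodes, and 1/C(N(N−1)/2, m) for top-m sets.  The node
and set values extend the link formula by the same uniform-counting
argument; success for a set means exact set equality with the modal set.

B(n, p, k) is implemented as the upper tail P(X ≥ k): π is interpreted as
a p value, and a p value is a tail area.  The point-mass alternative is
available as `mode = "pmf"` in `ln_binomial_tail()`.  The computation stays
in log space end to end (binomial tail via the incomplete-beta route of
`pbinom(log.p = TRUE)`), so there is no underflow even for n ~ 10⁶ windows;
the test suite checks it against an independent high-precision summation
oracle to 10⁻⁸ relative error.

Scanning ln π over a grid of window lengths yields a **stability
profile**; its minimum locates the timescale at which the feature is most
persistent.  The grid default is 30 log-spaced points between 10 and
1000 ms — spanning from few-sample windows, where estimates are
noise-dominated, up to second-scale windows where resting activity has
decorrelated; the minima of interest in resting EEG sit in the tens of
milliseconds, so the grid is densest there on the log scale.  Grid points
whose window holds fewer than 2 samples are skipped with a warning.

A companion statistic, the **rank gap** Δ = log₂(s₁/s₂) between the two
largest link weights in a window, measures how far the strongest link
leads the ranking; its profile is averaged per window, and windows with
s₂ = 0 are excluded and counted.  (Averaging per window, rather than
tracking the gap of the modal link only, uses all of the data and is the
natural summary when the leader changes identity across windows.)

## Tie handling and degenerate inputs

Correlation weights are continuous, so exact ties have measure zero in
real data; they still occur in constructed or degenerate inputs, and every
ranking in the package resolves them deterministically toward the
lexicographically smallest identity (smallest (j, k) pair, smallest node
index, set-lexicographic order for link sets).  Zero-variance channels in
a window would make Pearson correlation undefined; their links get weight
0 and a warning, keeping the per-window ranking total.  An all-zero
network reports link (1, 2) with a degeneracy flag, and clustering on an
all-zero network is defined as 0.  Channel indices are 1-based, following
R convention; identities are reported as `"j-k"` link keys and node
indices on the channel order of the input file, which is preserved
exactly.

## Group-level aggregation

Group curves are pointwise means of per-subject ln π profiles, with peak
summaries read off the mean curve; a leave-one-subject-out envelope
(extrema of the peak summaries over deletions of each subject) provides a
sensitivity band.  Per-subject peaks are kept alongside, because the
distributional comparisons (two-sample Kolmogorov–Smirnov on optimal
window lengths) and the classifier consume per-subject values — whether a
"group peak" means the peak of the mean curve or the distribution of
per-subject peaks is genuinely ambiguous, so both are computed and
labelled.

**Intra-group stability** pools the per-window identities of all subjects
of a group into one trial sequence (n = Σ ⌊l_s/w⌋) and scores the globally
modal identity with the same binomial tail, measuring whether the *same*
link or node dominates across subjects.

**Upsampling** splits each recording into five equal contiguous parts
(floor division, remainder discarded) and treats each part as a virtual
subject — a device for checking that results are stable over time and
survive shorter recordings.

## Covariates and classification

The six per-subject metrics — (min ln π, best w) for strongest link, most
central node, highest-clustering node — are related to demographic and
cognitive covariates by Spearman rank correlation (pairwise deletion of
missing values, significance flagged at α = 0.01 on raw p values, no
further multiplicity correction) and by the R² of an OLS fit of each
covariate on all six metrics (complete cases; a constant response reports
R² = 0 with a degeneracy flag).

Group discrimination uses a random forest (100 trees, default feature
subsampling) under leave-one-out cross-validation, averaged over 100
realisations that differ in the forest's internal randomness.  Three
six-feature baselines calibrate the score: label shuffling (chance),
weights of six random links, and a mixed draw of two random links plus the
centrality and clustering of two random nodes.  Baseline link weights are
taken from the subject's mean-over-windows network at a reference window
length — a choice, since a per-window value would be arbitrary — and
random identities are redrawn once per realisation.  Feature importance is
the drop in mean accuracy when an independent model is trained without the
feature.  Groups of unequal size are classified as-is and the
majority-class rate is reported next to the accuracy.  If every training
feature is constant the forest is uninformative; the implementation then
predicts the training majority class directly, which is also what makes
the degenerate case deterministic.

## The synthetic-data generator

The generator's defaults emulate the targeted acquisition: 32 channels at
500 Hz for 480 s — 240,000 samples per channel — of unit-variance iid
Gaussian noise.  Planted structure provides ground truth:

* a **planted pair** shares a latent Gaussian with mixing √ρ, so the
  within-epoch population correlation is exactly ρ; the recording is
  partitioned into epochs of `epoch_ms`, each independently active with
  probability q (Bernoulli), giving mean active fraction q and a
  well-defined target timescale.  The square-wave epoch structure (rather
  than smooth modulation) is deliberate: it makes "best window ≈ epoch
  length" a falsifiable recovery target.
* a **planted hub** mixes the hub signal into each peripheral with
  coefficient ρ (hub–peripheral correlation ρ, peripheral–peripheral ρ²).

Per-subject seeds are derived deterministically from a master seed, and
generation never disturbs the caller's RNG stream.  What the generator
does *not* emulate: 1/f spectra, volume conduction, non-stationary
artifacts, reference effects.  Passing the recovery and calibration tests
therefore shows the *pipeline* is correct and calibrated under its own
null — not that any particular clinical effect will reproduce.

## Numerical and scale choices in the tests

The suite exercises the pipeline at desk scale: null-calibration uses 500
noise recordings of 8 channels × 200 windows against a multinomial-maximum
oracle (two-sample KS below the 1% critical value); planted recovery uses
50 subjects of 32 channels × 48 s with ρ = 0.9, q = 0.8, 30 ms epochs on a
9-point grid from 10 to 244 ms; classification uses 20 planted vs 20 null
subjects of 24 s each.  These sizes were chosen as the smallest cohorts at
which the binomial scores separate planted from null structure by orders
of magnitude, so the checks are strict while remaining quick; recordings at
the full 8-minute default behave identically, only with larger n per grid
point.

## Known limitations

* Absolute Pearson correlation is the only shipped connectivity estimator
  (a pluggable weight function is accepted); coherence, phase-locking or
  directed measures are out of scope.
* Non-overlapping windows only; overlapping windows would correlate trials
  and invalidate the binomial null as constructed.
* The null assumes exchangeable identities (uniform p); channel-dependent
  noise levels in real data bend this slightly, which is one reason the
  probabilities are best read comparatively (between groups or window
  lengths) rather than as literal p values.
* EDF support covers the continuous-recording subset (uniform rate, 16-bit
  samples, no annotation channels).
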