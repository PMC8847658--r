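# rankstab

Ranked network-feature stability for dynamic functional networks.

## The problem

Comparing functional brain networks across subjects or clinical groups is
hard: networks differ in size and density, thresholding discards weak links
that carry information, and the multiplicity of topological metrics invites
multiple-comparison trouble. `rankstab` implements a deliberately minimal
alternative: instead of comparing whole networks, it asks *how persistently
the top-ranked feature of the network keeps its identity over time*, and at
*which timescale* that persistence peaks.

Given a multichannel recording (e.g. 32-channel resting-state EEG at
500 Hz), the pipeline is:

1. Split each channel's time series of length *l* into non-overlapping
   windows of size *w*; build one fully connected weighted network per
   window, with the link weight between channels *j* and *k* the absolute
   Pearson correlation of their samples in that window.
2. Per window, extract a ranked feature: the strongest link, the set of the
   *m* strongest links, the node of highest strength centrality, or the node
   of highest weighted local clustering (geometric-mean triangle intensity
   on max-normalised weights).
3. Find the **modal identity** — the feature value occurring most often over
   the ⌊*l*/*w*⌋ windows — and score its persistence against a binomial null
   of completely independent networks:

   π = B(n, p, k),  reported as ln π,

   with *n* = ⌊*l*/*w*⌋ trials, *k* the modal count, and *p* the chance of
   hitting one fixed identity per trial (1/(N(N−1)/2) for links, 1/N for
   nodes, 1/C(L, m) for top-m sets).  π is the p value of the observed
   persistence under the null, so ln π ≪ 0 means a strongly stable feature.
4. Scan a grid of window lengths; the minimising *w* is the timescale at
   which the feature's persistence is strongest.

Six metrics per subject — (min ln π, best *w*) for the strongest link, the
most central node, and the highest-clustering node — feed group comparison
(mean curves with leave-one-subject-out envelopes, pooled intra-group
stability, Kolmogorov–Smirnov tests on optimal windows), covariate analysis
(Spearman correlations, OLS R²), and a random-forest classification
protocol with chance and random-feature baselines.

## Worked example

```r
library(rankstab)

# a synthetic subject: 8 channels, 20 s at 500 Hz, with a persistent
# coupling (rho = 0.9) planted on channels 2-6 in 30 ms epochs, active 80%
# of the time
sp <- synthetic_spec(N = 8, duration_s = 20, seed = 5,
                     planted_pairs = list(list(2, 6, 0.9, 0.8, 30)))
rec <- generate_planted(sp)$recording

fit <- stability_profile(rec, "strongest_link",
                         grid_ms = c(10, 20, 30, 60, 120, 240))
fit
#> <stability_profile> subject 'planted_seed5', feature strongest_link
#>   6 window lengths in [10, 240] ms
#>   best window 20 ms, min ln pi -1940.66
fit$grid
#>   window_ms n_windows modal    k          p     ln_pi
#> 1        10      2000   2-6  839 0.03571429 -1481.643
#> 2        20      1000   2-6  748 0.03571429 -1940.658
#> 3        30       666   2-6  545 0.03571429 -1508.021
#> 4        60       333   2-6  276 0.03571429  -772.175
#> 5       120       166   2-6  161 0.03571429  -515.954
#> 6       240        83   2-6   83 0.03571429  -276.573
```

The planted pair `2-6` is the modal strongest link at every window length;
`ln pi` bottoms out near the planted 30 ms epoch, orders of magnitude below
anything a pure-noise recording of the same size produces.  `stability_summary(rec)` returns
the six metrics used downstream; `plot(fit)` draws the profile.

A command-line driver covers the same pipeline for batches of recordings
(EDF or delimited text):

```sh
exec/rankstab simulate  --out sim --n_subjects 4 --planted 2,6,0.9,0.8,30
exec/rankstab stability --input sim --out stab --grid_ms 10,20,40,80
exec/rankstab group     --profiles stab/profiles.csv --metadata meta.csv --out grp
exec/rankstab classify  --summaries stab/summaries.csv --metadata meta.csv --out cls
exec/rankstab correlate --summaries stab/summaries.csv --metadata meta.csv --out cor
```

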