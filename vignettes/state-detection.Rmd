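---
title: "Detecting functional states in multichannel EEG with statedetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting functional states in multichannel EEG with statedetect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(statedetect)
```

## The problem

Long unstructured recordings — a meditation session, sleep, anaesthesia —
often pass through a sequence of *functional states*: stretches of tens of
seconds to minutes during which the multichannel signal is roughly
stationary, separated by change points. No external annotation marks the
transitions, so the partition has to come from the data alone, and it must
be *time-continuous*: a state is a contiguous run of epochs, not an
arbitrary cluster.

Ordinary clustering fails this requirement — clusters interleave and
overlap in time. `statedetect` implements an ensemble change-point method
(the state-detecting algorithm, SDA) that turns connectivity-constrained
hierarchical clustering into a boundary-candidate generator, pools
candidates over a hyperparameter ensemble, and distils them into one
partition per requested state count. Around it the package ships the full
feature recipe the method expects, and a validation suite that works
without ground truth.

## Pipeline at a glance

1. **Epoching** (`epoch_signal`): the continuous recording is cut into
   non-overlapping 1-s epochs, the atomic unit of everything downstream.
2. **Features** (`compute_feature_set`): per epoch —
   * band power: adaptive multitaper PSD per channel, averaged over five
     bands (delta 0.9–4, theta 4–8, alpha 8–14, beta 14–25, gamma
     25–40 Hz; half-open intervals, gamma closed at 40) and
     channel-averaged within 15 scalp regions → 75 columns;
   * 16 ratios of linear band powers per region → 240 columns;
   * coherence and phase-locking value per channel pair from
     cross-spectra over a 5-epoch sliding window (clamped inward at
     record edges so every epoch keeps a full-window feature row) → 703
     pairs × 5 bands per measure;
   * connectivity indices: per channel, the count of partners with
     synchrony ≥ P for P ∈ {0.6, 0.7, 0.8}, region-averaged → 225 columns
     per measure;
   * region-pair synchrony averages (descriptive only) → 525 per measure.
3. **Cleaning** (`reject_artifact_epochs`): an epoch is dropped when any
   of the 75 raw power columns deviates more than 3 SD from its
   recording-wide mean. Statistics come from the full table in a single
   pass; retained epochs are reindexed contiguously and all later indices
   refer to the retained sequence.
4. **Reduction** (`fit_feature_transform`): log on power-like columns,
   z-score everything, project on 15 principal components (20 for the
   classifier check). Component signs are fixed by making each loading's
   largest entry positive, so results are platform-stable.
5. **SDA** (`run_sda`): described next.
6. **Validation** (`state_adapted_scores`, `pairwise_state_tests`,
   `state_vs_median_tests`, `iv_report`, `fit_state_classifiers`).

A note on counts: the construction "3 thresholds × 5 bands × 15 regions"
yields 225 index columns per measure, hence 765 SDA-input and 1,815
analysis columns on the standard montage. Reports of this feature set
sometimes quote 255/825/1,875; those totals are inconsistent with the
construction's own arithmetic, and the package follows the construction.

## The state-detecting algorithm

**Phase 1 — boundary candidates.** For every triple (N, K, L) of a
hyperparameter grid (`sda_grid`; defaults: N ∈ [2, 20] Ward clusters,
K ∈ [20, 50] epochs of temporal connectivity, L ∈ {0, 20, 40, 60} minimum
state length):

* Ward agglomeration restricted to merges between clusters that contain
  at least one pair of epochs within K of each other
  (`ward_connectivity_cluster`). The Ward distance is the within-variance
  increase `(n_a n_b / (n_a + n_b)) ||mu_a − mu_b||²`. One agglomeration
  per K serves all N cuts.
* Cluster extents become a time-continuous tiling: each cluster
  contributes its leftmost index and one past its rightmost
  (`clusters_to_segments`). Interleaved clusters therefore yield a finer
  tiling — exactly the behaviour that makes the boundaries useful even
  when the clusters themselves are not contiguous.
* Segments of ≤ L epochs merge into their Ward-nearest neighbour
  (`merge_short_segments`; shortest first, ties leftmost); then adjacent
  segments merge while the minimum adjacent Ward distance is ≤ W times
  the current average (W = 0.3, recomputed after every merge;
  `merge_close_segments`).

The default grid runs 19 × 31 × 4 = 2,356 triples; the interior
boundaries of each result are the candidates, and their multiplicity
across triples measures stability.

**Phase 2 — pooling and selection.** For each (N_max, K_max, L) subset the
candidate arrays with N ≤ N_max, K ≤ K_max at fixed L are pooled as a
multiset (duplicates kept — K-means then weights by frequency). The pooled
indices are clustered with K-means (N_KM ∈ [2, 15], k-means++
initialisation under the run seed, 10 restarts) and with 1-D DBSCAN on
indices normalised by the record length (radius E_DBS ∈
{0.02, 0.025, 0.03}, `min_samples = 5`). From every clustering three
boundary sets are read off — mean, median and mode centers, rounded
half-up, mode ties to the smallest index. For each target state count the
configuration whose (deduplicated) boundary count matches competes on the
**state-adapted Silhouette**: the mean two-cluster Silhouette over all
pairs of time-adjacent states. Ties break to the first configuration in
enumeration order (L, N_max, K_max, then method/parameter, then center
type). The tool reports *every* state count with its five quality
measures — Silhouette, Calinski-Harabasz, Davies-Bouldin, Ward and
centroid distance, all pair-averaged — and deliberately leaves the final
choice of state count to the analyst.

Why pair-averaged indices? A global validity index punishes recordings
whose non-adjacent states are similar (states may recur). Only the
separation between *temporal neighbours* matters for change-point quality,
so each adjacent pair is scored as a two-cluster problem and averaged. A
point alone in its cluster scores Silhouette 0 by convention; the
two-cluster Calinski-Harabasz keeps its (n − 2) degrees-of-freedom factor.

## Ground-truth-free validation

* **Nonparametric tests** (`pairwise_state_tests`,
  `state_vs_median_tests`): Mann-Whitney U between every state pair and
  one-sample Wilcoxon of each state against the recording-wide feature
  median, over all analysis columns, Bonferroni-corrected by the number
  of features within each comparison family (the strictest reading).
  Reported as the percentage of significant features at corrected
  p < 0.01. Sliding-window synchrony features are serially dependent
  across adjacent epochs; the caveat travels in the result object.
* **Information value** (`woe_iv`, `iv_report`): per state, the
  membership indicator is a binary target; each feature is cut into
  quantile bins on its pooled distribution, and
  IV = Σ (event share − non-event share) · ln(event share / non-event
  share). The +0.5-per-class smoothing is applied only when a bin has a
  zero count in either class, so clean tables reproduce textbook values
  exactly. The bin count is occupancy-aware — at most 10, reduced so the
  rarer class keeps roughly ten expected observations per bin — because
  with only a handful of events per bin the WoE noise alone pushes IV
  past the interpretation thresholds (a fixed 10-bin rule on a 50-epoch
  state reports sizeable IV on pure noise); `adaptive = FALSE` restores
  fixed binning. Bands: < 0.2 useless, 0.2–0.4 weak, 0.4–0.6 medium,
  0.6–1 strong, > 1 suspicious — deliberately higher cut-offs than
  credit-scoring practice because serial dependence inflates IV. Because
  IV uses quantile bins it is invariant under monotone transforms of a
  feature.
* **Predictive check** (`fit_state_classifiers`): can the states be
  predicted from power features alone? Synchrony columns are excluded
  (their 5-epoch windows leak across a random split). The protocol — IV
  filter (≥ 0.4) fitted on the training split, z-score + 20-component
  projection fitted on the training split, stratified 0.4 hold-out,
  3-fold stratified CV over small grids for a max-margin classifier,
  regularised logistic regression and gradient-boosted trees — reports
  multiclass accuracy/macro-F1 and per-state balanced accuracy/ROC AUC.
  Epoch-level random splitting matches the reference protocol even though
  temporal autocorrelation inflates absolute scores; a `split = "block"`
  option holds out the tail of each state instead and is off by default.

## The synthetic-data generator

`generate_recording` builds piecewise-stationary multichannel recordings:
each channel is a 1/f background plus five FIR band-passed noise
components (the zero-phase FIR response applied in the frequency domain)
whose amplitudes follow the active state's per-band — optionally
per-region — gains, plus a shared per-band driver mixed in proportion to
the state's synchrony level, plus white noise. Optional ingredients make
the statistics realistic: a synchrony floor (`base_synchrony`), an
instantaneous spatial-mixing option (`conduction`) emulating volume
conduction, and a common per-epoch amplitude modulation
(`epoch_modulation_sd`) standing in for vigilance/arousal fluctuation —
the ingredient that makes artifact-like epochs deviate in many power
columns at once rather than independently. The canonical recipe keeps
that modulation iid across epochs: an autocorrelated version is
available, but temporal drift inside a state contradicts the
piecewise-stationarity the planted ground truth asserts.

`contrast_recipe` is the canonical validation recipe: eight states of
85–120 one-second epochs on the standard 38-channel montage. Its design
went through several deliberate calibrations, each driven by how the
*measured* features behave, and none by any single test outcome:

* **Gain scale.** Per-epoch band power carries multiplicative,
  chi-square-like noise, so the usable contrast scale is the
  within-state SD: amplitude gains of 1.25×/0.8× (≈1.6×/0.64× power)
  shift a power column by roughly one within-state SD — the few-fold
  regime real functional states show. Much stronger gains park entire
  states beyond the 3-SD rejection rule, which at these settings removes
  a realistic 15–20% of epochs.
* **Resolvable cues.** On 1-s epochs the taper half-bandwidth (4 Hz)
  blurs delta into theta, so the two low bands always move together as
  one "low" group; signatures only contrast cues the estimator can
  actually resolve (low, alpha, beta, gamma × anterior/posterior).
* **Balanced signatures.** The eight states take their up/down gains
  from the rows of an 8 × 8 Hadamard matrix over those band-group ×
  scalp-half cells, so *every* pair of states differs in exactly four
  cells. Because rearrangement can make any pair adjacent, and the
  merge rule compares each adjacent Ward distance with the *average*,
  unbalanced designs would let strong pairs starve the weakest one; the
  balanced design keeps all possible adjacent distances the same size.
* **Synchrony placement.** Planted synchrony sits at 0.5: clearly
  visible in the raw coherence/PLV features, but — after the taper
  bandwidth dilutes narrowband coherence — safely below the 0.6 index
  threshold. Synchrony *at* a threshold would make the thresholded
  counts toggle with the shared driver's envelope, an estimator
  bistability that masquerades as internal state structure.

With this recipe the full pipeline recovers all planted boundaries to
within a couple of epochs across seeds, and the pair-averaged Silhouette
of the detected partition is an order of magnitude above its
epoch-shuffled surrogate.

`make_surrogate` applies one random permutation to epochs and feature rows
alike — identical marginals, no temporal structure — and
`rearrange_states` permutes whole state blocks, returning the expected
permuted boundaries so recovery can be scored.

What the generator does *not* emulate: dipolar source geometry and
electrode mixing, non-stationarity within states, real artifact
morphology (blinks, EMG), line noise. Passing tests on this substrate
show the pipeline recovers the statistical structure its features
measure; they do not certify performance on any particular real
recording.

## Numerical and design choices

* Multitaper: Slepian tapers from the symmetric tridiagonal eigenproblem,
  time-half-bandwidth 4, 7 tapers on a 1-s epoch, Thomson adaptive
  weighting for PSD; cross-spectra use uniform taper averaging. Band
  averages are means over the frequency bins inside each band.
* Coherence is `|mean CSD|² / (mean PSD_x · mean PSD_y)` over the window's
  epoch × taper ensemble; the PLV averages the unit-normalised per-taper
  cross-spectrum first. Both are bounded in [0, 1]; a copied channel
  scores exactly 1.
* Edge epochs keep full-length synchrony windows clamped inward (epoch 1
  uses epochs 1–5) rather than truncated ones, so the feature table has
  one row per retained epoch *and* every row pools the same number of
  cross-spectral segments. Truncated edge windows would inflate
  coherence/PLV exactly at the record ends and turn the first/last
  epochs into systematic outliers.
* Artifact rejection is a single pass with statistics from the uncleaned
  table; zero-SD columns never flag. All-epochs-rejected is an error.
* K-means on heavily duplicated candidate multisets can defeat random
  initialisation; the fallback is deterministic quantile seeding over the
  unique values, and configurations that cannot support the requested
  cluster count are skipped rather than fudged.
* Determinism: `run_sda`, the generator, surrogates and classifiers take
  explicit seeds, save and restore the caller's RNG state, and produce
  identical output for identical input + seed.
* Problem sizes used by the shipped validation runs: the test-suite and
  acceptance fixtures simulate the eight-state recipe at a 100-Hz
  sampling rate (all bands sit below the 50-Hz Nyquist, and the 1-s epoch
  grid — the unit every result is expressed in — is unchanged); the
  boundary-recovery run uses the full default grid with 2,356 phase-1
  triples.

## Known limitations

* The connectivity constraint is defined on the *retained* epoch sequence;
  rejection gaps shorten apparent temporal distances across them.
* Phase-2 center extraction can emit boundary pairs one epoch apart on
  pathological (e.g. shuffled) data, creating near-singleton states whose
  pair scores are erratic; comparisons against surrogates should be made
  at a matched state count, as the validation suite does.
* The Bonferroni family is the feature set within one comparison;
  correcting additionally across comparisons would be stricter.
* IV at small state sizes (tens of epochs) carries a positive
  small-sample bias; interpret the 0.4 threshold on states of roughly a
  hundred epochs or more.

## A worked miniature

```{r mini, eval = FALSE}
rois <- roi_map(list(front = c("c1", "c2"), back = c("c3", "c4")))
recipe <- sim_recipe(
  list(state_spec(60, power_gain = c(alpha = 1.5)),
       state_spec(60, power_gain = c(delta = 1.5)),
       state_spec(60, synchrony = c(beta = 0.6))),
  channels = paste0("c", 1:4), sfreq = 100, rois = rois
)
sim <- generate_recording(recipe, seed = 1)
epochs <- epoch_signal(sim$recording, 1)
fs <- compute_feature_set(epochs, rois = rois)
clean <- reject_artifact_epochs(fs$psd)
keep <- setdiff(seq_len(nrow(fs$sda_input)), rejected_epochs(clean) + 1)
tr <- fit_feature_transform(ft_subset_rows(fs$sda_input, keep),
                            n_components = 10)
x <- transform_features(ft_subset_rows(fs$sda_input, keep), tr)
res <- run_sda(x, sda_grid(N = 2:8, K = c(15, 25), L = c(0, 10),
                           N_max = 8, K_max = 25, N_KM = 2:6), seed = 1)
glance(res)
autoplot(res)
```
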