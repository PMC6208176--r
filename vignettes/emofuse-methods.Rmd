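---
title: "Methods: quadrant emotion recognition by evidence fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quadrant emotion recognition by evidence fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

emofuse classifies one-minute multichannel EEG epochs into the four
quadrants of the arousal-valence plane: Q1 (high valence, high arousal),
Q2 (low valence, high arousal), Q3 (low/low) and Q4 (high valence, low
arousal). Ratings on the 1-9 scale are binarized at the midpoint 5.0, with a
rating exactly at the cutoff counted as "low"; this cutoff is a package
convention (`cutoff` in `sim_config()` and `pipeline_config()`), since the
quadrant construction itself does not fix one.

The pipeline has four stages.

**1. Channel selection by blind source separation.** Each epoch is
decomposed with SOBI: the centered data are whitened, the covariance
matrices at lags `1..min(100, n/4)` are symmetrized, and an orthogonal joint
diagonalizer is found by Jacobi rotations (tolerance 1e-8, at most 200
sweeps; off-diagonal energy is non-increasing across sweeps, which the test
suite asserts). The lag set is a package default; lag-based separation only
requires that sources have distinct autocovariance sequences, and a dense
set of short lags is the common choice for broadband EEG. Rank-deficient
inputs drop near-zero whitening eigenvalues and return fewer components
with a warning. Each mixing column's sign is fixed by making its
largest-magnitude entry positive.

Per-channel *activity* is defined as `sum_k |mixing[c,k]| * sd(source_k)` —
the energy-weighted magnitude of each component's scalp weight on that
channel. This channel-level summary is a package convention: scalp-map
interpolation is out of scope, and the absolute value makes the statistic
invariant to the sign indeterminacy inherent in any blind decomposition
(a signed sum across components is not identifiable, because each
component's global sign is arbitrary). Activity vectors are averaged per
class and min-max normalized to [-1, 1] over the pooled class means, so
the pooled minimum maps to -1 and the pooled maximum to +1. Channels whose
absolute normalized activity exceeds a threshold (strictly) are the
"emotional channels" of that class — under this convention both extremes of
the activity range qualify, i.e. both strongly expressed and strongly quiet
channels are treated as informative — and only channels common to all four
classes are kept. The threshold defaults to 0.5 on the 0-1 scale and can be
tuned over the grid 0.1..0.9 by `tune_threshold()` against any downstream
scorer; inside cross-validation an empty intersection steps the threshold
down by 0.1 with a warning rather than aborting a fold.

A consequence of the sign-blind threshold worth knowing: with strongly
bimodal activity (a few very active channels, everything else quiet) the
per-class selections contain both tails, so the cross-class intersection
retains channels that are *consistently extreme* — the common core plus
stable class markers — rather than the active core alone. On planted
synthetic data this still yields a small, stable, discriminative channel
set, which is what the downstream stages need.

**2. Nine nonlinear features per selected channel.** Correlation dimension
(Grassberger-Procaccia slope of `log C(r)` vs `log r` between the 1st and
10th distance percentiles, Theiler window `m*tau`), Higuchi fractal
dimension (`k_max = 10`), largest Lyapunov exponent (Rosenstein
nearest-neighbor divergence, slope of the pre-saturation region, reported
per second), sample entropy (`m = 2`, `r = 0.2 * sd`, Chebyshev distance,
self-matches excluded), the four recurrence measures RR/DET/L/ENT
(recurrence radius chosen per epoch to fix RR near 0.02 so the line
statistics are comparable across epochs; `l_min = 2`; line-of-identity
excluded; both triangles scanned), and Gaussian differential entropy
`0.5*ln(2*pi*e*sigma^2)` computed broadband on the full window. Embedding
uses `m = 10` with the delay at the first autocorrelation zero crossing per
channel. All of these are package conventions, recorded in the parameter
sidecar written next to every feature table; the sources the pipeline
follows do not pin them down. Pairwise-distance statistics (CD, LLE, RQA)
run on an evenly decimated trajectory of at most `max_points = 500` points,
which bounds their cost independently of epoch length while leaving the
distance distribution essentially unchanged; sample entropy, the fractal
dimension and differential entropy use the full series, since entropies
need at least ~4000 samples for stable estimates (hence the epoch-length
invariant in `sim_config()`).

Numerical conventions for degenerate inputs: a constant series has CD 0 and
sample entropy 0; if no template pair matches at length `m+1`, sample
entropy returns the conservative upper bound `log(B)`; a recurrence matrix
with no diagonal line of length >= `l_min` reports DET = L = ENT = 0.

**3. Local subset feature selection with feature trees.** A feature tree is
a univariate binary decision tree extended with single-child *feature
nodes*; each leaf (locality) owns the feature nodes on its root path, and a
feature node above a split is shared by both descendant localities. A tree
is scored by locality-wise k-nearest-neighbor label agreement (`k = 5`):
for every training sample, the fraction of its k nearest same-locality
neighbors — distance over the locality's feature subset, all features if
the subset is empty — that share its label, averaged over the training set.
Localities smaller than `k+1` use the neighbors they have; single-sample
localities contribute zero, which mildly penalizes fragmentation.

The search treats tree construction as sequential decision making: at each
open node the available actions are "add feature node f_i", "add split node
s_i" (thresholds restricted to midpoints between consecutive sorted values,
thinned to nine quantile positions) and "terminate". An epsilon-greedy
bandit (`epsilon = 0.2`, optimistic initialization, per-state visit-count
averaging) chooses actions during rollouts; after a warm-up fifth of the
budget, half of the remaining rollouts instead apply local mutations to the
incumbent best tree (add / drop / relocate a feature node, retune or
re-select a split, and in unconstrained mode add a split or prune). The
returned tree is the best one scored, so it never scores below the
single-leaf baseline — that inequality is asserted property-style in the
tests. The default budget is 500 rollouts with `max_depth = 4`.

For the two label axes the sample space is divided once: the search is
constrained to trees with exactly two leaves (one split plus feature
nodes), run independently against binarized arousal labels and binarized
valence labels. Because a two-leaf tree factorizes — the score is the sum
of the two localities' agreements — the Monte-Carlo result is polished by a
direct optimizer: for a handful of candidate split features (the incumbent
split plus the top-weighted features from the rollouts), each threshold in
the grid is tried and each side's subset is rebuilt by greedy forward
selection. This deterministic polish is part of the search policy, not a
separate estimator; everything is reproducible from the seed. Whether the
two localities should come from one tree or two independent searches was
genuinely open; two searches were chosen because the two label axes are
scored independently and nothing couples them.

Each axis finally keeps the `n_keep = 10` features ranked by rollout
selection frequency weighted by score gain over the single-leaf baseline
(the polished final tree's features enter this ranking with the weight of a
warm-up's worth of rollouts, so the returned subsets and the returned tree
agree). The ranking rule is a package convention; "most significant" has no
canonical definition here.

**4. Two MLPs fused by Dempster-Shafer evidence theory.** Each feature
subset feeds an independent single-hidden-layer perceptron (20 logistic
hidden units, softmax output, at most 500 epochs, weight decay 1e-4, seeded
initialization; `nnet` under the hood). Before training, samples are
*relabeled* in each subset's standardized space: memberships are normalized
inverse distances to the class prototypes (per-class means), thresholded at
0.4; classes at or above the threshold form the target hypothesis, so
ambiguous samples get composite (set-valued) targets, and an empty
selection falls back to the argmax class. The inverse-distance membership
form and the 0.4 default are package choices. A composite target
contributes a uniform distribution over its member classes, implemented as
weighted row expansion — exactly equivalent under the cross-entropy loss
and usable with any posterior-producing base learner.

At test time each network's posterior vector is softmax-normalized into a
mass function on the four singletons. The printed form of the
normalization in the source material divides `exp(R_j)` by the *sum of the
scores* rather than the sum of exponentials, which cannot produce masses
summing to one; the operator is named softmax there, and the standard
softmax is what the package implements. The two singleton mass functions
are combined by Dempster's rule (`m(S) ∝ sum_{S1∩S2=S} m1(S1)m2(S2)`,
conflict `K` the mass on empty intersections, total conflict an error) and
the decision is the maximum singleton belief, ties to the lowest class
index with a message. Composite hypotheses are fully supported by the mass
machinery (the relabeling produces them during training), while test-time
masses stay singleton because the softmax assigns mass only to singletons.

## Evaluation

`confusion()` builds the 4x4 decision-by-target matrix, `confidence()` its
column-normalized percentages, and `ccr()` the trace over the grand total.
`cross_validate()` runs stratified 10-fold cross-validation with every
supervised stage — class-average activity maps, channel thresholding and
intersection, the two feature-subset searches, prototypes/relabeling, and
both MLPs — refit inside each training fold. Source separation and feature
extraction are computed once up front because they are label-free, so
nothing leaks across folds. Fold counts are pooled (not averaged) before
computing the CCR, matching the grand-total form of the rate.

## What the synthetic generator emulates — and what it does not

`generate_epochs()` produces quadrant-labeled epochs with: a fixed spatial
mixing template per class (active channels project all of that class's
sources with gains at least 3x the inactive channels' crosstalk, which has
a channel-specific level so class-average activity is graded); sources
built from the five classical EEG rhythms with class-dependent amplitude
profiles (fast rhythms and stronger chaos for high-arousal classes, slow
rhythms for low-arousal ones), per-source frequency offsets keeping the
sources of one class spectrally distinct (the identifiability condition of
lag-based separation), and a logistic-map chaotic component so the
phase-space features are non-degenerate; white sensor noise at a
configurable SNR (default 10 dB, a generous but plausible broadband-EEG
figure); and ratings drawn uniformly inside each quadrant. Defaults are 32
channels at 128 Hz and 7680-sample (one-minute) epochs.

The generator deliberately does not model inter-subject variability,
stimulus structure, volume-conduction correlations between sources,
artifacts, or 1/f background spectra. Passing tests on this data
demonstrate that each stage recovers structure it is designed to recover
and that the stages compose correctly — not that real-recording accuracy
would match; on real data the class structure is far weaker and channel
selection noisier.

Problem sizes used by the test suite and the acceptance script were chosen
to exercise every stage at meaningful scale: the end-to-end experiment uses
8 channels, 40 epochs per class and 4096-sample epochs under 10-fold
cross-validation; planted feature-recovery tables use 400 samples and 30
features; oracle-equivalence checks run on small random instances where
exhaustive computation is exact.

## Known limitations

- The channel-activity statistic is one of several defensible mappings
  from component topographies to channel scores; rankings are stable under
  it, but its absolute values are not comparable across datasets.
- The feature-tree search is stochastic; with tiny budgets it degrades
  gracefully to the single-leaf baseline but may miss planted structure.
- Dempster's rule with two near-certain, disagreeing learners produces
  high conflict; the package surfaces the per-sample conflict `K` so such
  cases are visible rather than silently normalized away.
- The MLP relabeling threshold (0.4) interacts with class geometry: far
  prototypes make composite targets rare, near prototypes make them
  common. It was fixed once and not tuned per dataset.
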