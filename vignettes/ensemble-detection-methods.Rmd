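---
title: "Detecting neuronal ensembles and tracking their stability: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting neuronal ensembles and tracking their stability: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnsembleTracker)
```

## The problem

Two-photon calcium imaging of cortex yields, after segmentation, spike
inference and binarization, a binary raster: an `N x F` matrix with one
row per neuron and one column per imaging frame (here 81 ms per frame,
3704 frames per 5-minute session by default). Groups of neurons that are
repeatedly active in the same frames — neuronal ensembles — are thought to
be functional building blocks of cortical activity. Two questions drive
this package:

1. **Detection.** Which groups of neurons coactivate more often than
   expected by chance within one session, and in which frames?
2. **Stability.** When the same cells are imaged again days or weeks
   later, are the same ensembles still present (stable), or did they
   appear in only one session (transient)? Which member neurons persist
   (core), which are lost, which are new?

All stages operate on the `BinaryRaster` class; detection returns an
`EnsembleSet`, membership demixing a `MembershipTable`, and the
cross-session comparison a `StabilityReport`.

## Detection model

### Surrogate-tested functional connectivity

For every neuron pair the coactivation count `Co[a,b]` is the number of
frames in which both are active. Its null distribution is obtained by
circularly shifting each neuron's spike train by an independent uniform
nonzero offset — a surrogate that preserves each train's rate and
autocorrelation but destroys cross-neuron timing — and recounting, 1000
times by default. The pair threshold `T[a,b]` is the
`ceiling(0.95 * 1000)`-th order statistic of the surrogate counts and an
edge requires `Co > T` strictly, so ties with the null count against
significance. Neurons active in all or no frames are shift-invariant and
can never gain edges. Each pair is tested at its own 5% level with no
multiple-testing correction; this matches the convention of functional
connectivity work in this field, and means that on fully independent data
roughly 4-5% of pairs carry chance edges. That rate is not a nuisance to
be hidden — the null-calibration test asserts it — but it shapes what the
pipeline can and cannot distinguish downstream (see *Limitations*).

Two surrogate modes are available. `shared_shift` (default) shifts every
neuron once per iteration and computes all pairwise counts with a single
matrix product; the marginal null of each pair is identical to shifting
pairs independently, and the cost drops by a factor of `N`. `per_pair`
implements the literal per-pair scheme and is retained for verification;
a test asserts that the two agree on small rasters.

### Raster filtering and population vectors

Within each frame, activity of neurons with no edge to any co-active
neuron is removed; frames left with fewer than `minCoactive = 3` active
neurons are emptied. Frames are zeroed rather than deleted so frame
indices remain valid for activity vectors and stimulus epochs; a
retained-frame mask carries the removal semantics.

The surviving columns are population vectors. Their pairwise Jaccard
similarity (`|intersection| / |union|`) feeds a single-linkage tree cut
at similarity strictly above 2/3; clusters with at least `minCluster = 2`
vectors are pooled, which keeps recurring coactivation patterns and drops
one-off frames. Skipping this selection (`vectorSelection = FALSE`)
reproduces the "all vectors" robustness variant.

### Ward clustering and the contrast index

Retained vectors are clustered by Ward linkage applied to the Jaccard
distance matrix directly. (Ward linkage formally assumes squared
Euclidean distances; applying it to Jaccard distances is a deliberate,
field-standard deviation that we document rather than "fix", because the
resulting trees are what the downstream thresholds were chosen against.)

The number of ensembles `k` is scanned over `2..kMax` (default 10) and
scored by the contrast index `CI = w - b`: the mean within-cluster
pairwise similarity minus the mean between-cluster pairwise similarity.
Two design decisions here were forced by failure modes we measured:

* **Unnormalized contrast.** The normalized variant `(w-b)/(w+b)`
  saturates near 1 whenever `b` is near 0 — exactly the situation of
  well-separated ensembles that share no neurons — and therefore cannot
  see the difference between `k` correct clusters and `k-1` clusters with
  two ensembles merged (both give `b` near 0). `w - b` penalizes mergers
  (the merged cluster's cross pairs dilute `w`) and splits (a split moves
  high similarities into `b`) symmetrically, and agrees with the
  normalized form on the canonical checks: perfect blocks give 1, a
  uniform matrix 0, 0.8-within/0.2-between blocks 0.6.
* **Plateau rule.** `which.max` over `k` chases per-mille gains from
  splitting chance micro-patterns off real clusters. Merging two real
  ensembles costs percent-level contrast; splitting noise gains well
  under one percent. We therefore take the smallest `k` whose contrast is
  within `ciTol = 1%` (relative) of the maximum — a parsimony rule in the
  spirit of the one-standard-error convention in model selection.

### Coherence of reported ensembles

Ward clustering partitions *every* retained vector. Recurring chance
coincidences of a few background neurons — duplicated triples created by
the ~5% chance edges — survive vector selection as tiny tight clusters
and then agglomerate into a residual cluster whose members are mutually
dissimilar (mean within-cluster Jaccard near 0.1, versus 0.5-0.8 for real
ensembles across participation regimes). Such a cluster is not a
recurring coactivation pattern, and reporting it as an ensemble is an
artifact of forcing a partition. Clusters whose mean internal similarity
is not above `minCoherence = 1/3` — the same minimal-identity similarity
the stability analysis uses to say two member sets describe one ensemble
— are therefore not reported; their frames are recorded as unassigned in
the result's configuration. The two regimes are separated by almost an
order of magnitude, so the rule is insensitive to the exact floor.

### Membership demixing

A cluster's provisional members (neurons active in its frames) are
refined by an ensemble-weighted coactivation test. With `V_j` the binary
activity vector of ensemble `j` and `P[j,a]` the Pearson correlation of
neuron `a` with `V_j`, the pair weight is `W = P[j,a] * P[j,b] * Co[a,b]`.
Its null replaces `Co` by a circular-shift surrogate count and both
correlations by draws from the ensemble's empirical correlation
distribution; the pair is significant if `W` strictly exceeds the 95%
order statistic of its surrogate weights, and a neuron is a member if it
has at least one significant within-ensemble pair. Because "participation"
means positive engagement, membership additionally requires
`P[j,a] > 0`; the switch `requirePositive = FALSE` restores the purely
sign-blind rule. The demixing null draws its own surrogates rather than
reusing the edge test's: reusing them couples the two tests'
Monte-Carlo errors and biases the membership threshold low for neurons
that acquired chance edges. The surrogate coactivations do not depend on
the ensemble, so one set serves all ensembles of a session.

### Coactivity-peaks variant

`detectCoactivityPeaks()` substitutes the connectivity stage with a
population-rate test: frames whose summed activity strictly exceeds the
pooled 95% quantile of surrogate per-frame coactivity are retained and
clustered identically. Because the threshold is a pooled 5% quantile,
data with non-trivial background will always leave a small percentage of
null frames above it; the planted-frame recovery test therefore asserts
exactness in the noise-free limit and containment otherwise.

## Stability model

Sessions are first restricted to common neurons. With ROI geometry,
`matchRois()` accepts a pair when the mask intersection exceeds
`0.5 * pi * radius^2` pixels and the centroid distance is strictly below
the radius (the reference protocol fixes the radius at 4 microns and its
acquisition at about 1.22 microns per pixel; because the published units
are ambiguous, the conversion is the caller's, not ours). The synthetic
generator instead uses a global integer registry, so `commonRaster()`
matches by ID.

Ensembles are detected independently per session on the common-neuron
rasters and matched one-to-one, greedily by descending member-set Jaccard
similarity. A first-session ensemble is **stable** if its match reaches
Jaccard >= 1/3 — equivalent to keeping at least 50% of the same neurons
for equal-sized ensembles — and **transient** otherwise; the boundary is
inclusive ("50% or more"). Within a stable match, neuron fate is set
algebra (`stable = A & B`, `lost = A \ B`, `new = B \ A`) with all
fractions relative to the day-1 ensemble size. Ensemble network density
is realized edges over possible edges among members; robustness is the
mean pairwise Jaccard similarity of the ensemble's activation vectors
(read from the connectivity-filtered raster, where those vectors live)
times its active-frame fraction — a single-frame ensemble has no vector
pairs, and its similarity factor is taken as 1 with a flag. Stimulus
tuning compares per-epoch active-frame fractions during stimuli against
the maximal stimulus-free intervals with a one-tailed two-sample t-test
at 5%.

The shuffle control reruns the entire comparison on circularly shuffled
copies of both rasters: per-neuron rates and autocorrelations survive,
cross-neuron structure does not, and the stable-ensemble count should
collapse. Multi-session experiments are compared pairwise against the
first session, never chained transitively.

## The synthetic generator

`generateSession()` plants `nEnsembles` member sets (disjoint by default;
`membershipOverlap` shares members) and gives each ensemble
Bernoulli-placed event frames, `eventsPerEnsemble / nFrames` per frame.
Members fire in an event with probability `participationProb`;
independent background spikes are added everywhere. The defaults are the
study conditions the package emulates: 100 neurons, 3704 frames of 81 ms,
4 ensembles of 20 neurons, participation 0.9, and a mean active-frame
fraction of 15%.

Design choices worth stating explicitly:

* **Background calibration is analytic and per neuron.** The expected
  ensemble-driven activity of a neuron is
  `pEns = 1 - prod(1 - participation * events_k / F)` over its ensembles,
  and the background rate solves
  `target = 1 - (1 - pEns) * (1 - bg)`, clipped to `[0, 1]` with a
  warning when the target is unreachable. No iterative fitting.
* **Ensemble events are mutually exclusive by default.** At the default
  activity levels (about 500 events per ensemble in 3704 frames),
  independently placed events would superpose two full ensembles in
  roughly 65 frames per ensemble pair; those mixed population vectors
  form tight clusters at Jaccard about 0.5 to both constituents and read
  out as additional ensembles. Cortical population events overwhelmingly
  alternate at the 81 ms frame scale, so exclusive placement is the
  realistic default; `allowEventOverlap = TRUE` restores independent
  placement for studying exactly that mixing.
* **Events per ensemble default to 500**, i.e. each ensemble is active in
  about 13.5% of frames (roughly 40 s per 5-minute session), between the
  reported activation times of stable and transient ensembles; at
  participation 0.9 this leaves members' background rates near 3%, so
  most of a member's activity is ensemble-driven.
* **Longitudinal structure lives in the common pool.** Later sessions
  keep `commonNeuronFraction` (default 0.42) of day-1 neurons; dropout
  neurons are replaced by fresh registry IDs rather than deleted, so
  common-neuron computation mirrors the tracking step. All planted
  ensemble members are drawn from the common pool: the analysis is
  defined on tracked neurons, so structure planted outside the pool would
  be invisible by construction and would only dilute the ground truth.
  Stable ensembles keep a fixed core of `ceiling(coreRetention * size)`
  members (default retention 0.68); the remainder is resampled each
  session *excluding* the ensemble's previous members, so rotated members
  are genuinely lost and the cross-session member intersection equals the
  core exactly. Transient ensembles appear in exactly one session.
* **Seeding.** One root seed; every sub-draw (membership, event
  placement, participation, background, turnover) consumes a documented
  sub-stream derived from it, so regenerating one stage is stable under
  changes elsewhere. Same seed, same bits.

What the generator does *not* emulate: calcium indicator kinetics and
inference errors (the input boundary is the binarized raster), slow
drifts of excitability, correlated background (background neurons are
independent Bernoulli), motion or z-drift artifacts in tracking, and any
temporal sequence structure within ensemble events. Tests passing on
synthetic data therefore validate the statistical machinery, not the
upstream imaging pipeline.

## Problem sizes used by the test suite

Unit tests run on rasters of tens of neurons and a few hundred frames
with 200-500 surrogates. The end-to-end validation uses the full
emulated geometry where the claim depends on it: single-session recovery
at 100 x 3704 with 1000 surrogates, null calibration at 50 x 2000 with
1000 surrogates over 5 seeds, longitudinal recovery at 250 neurons per
session, and a 10-seed shuffle control at 200 x 2500 with 500
surrogates. These sizes keep every stage's statistics in the regime the
defaults were designed for while completing in minutes on one CPU.

## Numerical choices and degenerate inputs

* Strict inequalities at every threshold (`Co > T`, similarity `> 2/3`,
  `W > TW`, PSNR `> 18` dB); the stability boundary `>= 1/3` is the one
  deliberate inclusive comparison ("50% or more").
* Surrogate thresholds are order statistics (`ceiling((1-alpha) * n)`),
  never interpolated percentiles; with integer-valued counts this is
  conservative under ties.
* Circular-shift offsets exclude zero: a zero shift reproduces the
  observed count and biases the null toward it.
* `cutree` at height `1/3` implements the strict similarity cut because
  `1 - 2/3` rounds up in double precision; exact-threshold pairs stay
  separate.
* Degenerate cases are errors, not silent results: all-zero vectors in a
  Jaccard matrix, constant ensemble vectors in correlations, zero
  neuropil variance in PSNR, fewer than three retained vectors in
  clustering ("insufficient coactivity" — the stability analysis catches
  this one and scores the session as having no ensembles, which is what
  a fully shuffled session should produce).
* Greedy one-to-one assignments (ROI matching by descending overlap,
  ensemble matching by descending Jaccard) break ties deterministically
  by index, making reruns bit-stable.

## Known limitations

* The per-pair 95% connectivity threshold leaves ~5% chance edges by
  construction. Downstream, neurons whose background activity happens to
  co-fluctuate with an ensemble can pass the membership test — under the
  default study conditions typically 1-3 background neurons per ensemble
  of 20, bounding achievable membership Jaccard against planted truth at
  about 0.87-0.95. The demixing test's specificity is regime-dependent:
  when an ensemble's members exceed a fraction `sqrt(alpha)` (about 22%
  at the default level) of the population under test, the resampled
  correlation products place the null's 95% quantile in the
  high-correlation band and chance members essentially vanish; below
  that fraction — and in very sparse data, where most surrogate
  coactivation counts are exactly zero — the quantile drops to the noise
  band and single chance coactivations can qualify. No planted member is
  lost in either regime. The demixing null adapts to each ensemble's
  correlation scale, so it cannot reject an ensemble that is itself
  assembled from chance structure; the coherence floor handles the
  clearest such case (the incoherent residual cluster), and the
  shuffle control quantifies what remains.
* The contrast index is our own formulation; the source methodology
  delegates it to a citation whose exact formula is not reproduced here.
  It is recorded in every result's configuration so alternatives can be
  compared.
* Robustness of a single-frame ensemble is undefined in the source
  methodology; our flagged convention (similarity taken as 1) is a
  stand-in.
* Ensemble matching assumes pre-aligned sessions (registration is out of
  scope); with real ROI masks the micron-per-pixel conversion is the
  caller's responsibility.
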