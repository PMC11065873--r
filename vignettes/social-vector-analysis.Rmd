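---
title: "Reference-frame analysis of social-spatial coding"
author: "socialvec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-frame analysis of social-spatial coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socialvec)
```

## The problem

When two mice share an arena, a hippocampal CA1 neuron recorded from one of
them may fire as a function of several different spatial variables at once:
the animal's own position in the arena (a classical place cell, *selfPC*),
the partner's position in the arena (*socialPC*), or the partner's position
*relative to* the recorded animal — either in axes fixed to the arena
(allocentric social-vector cell, *alloSVC*) or in axes that rotate with the
animal's head (egocentric social-vector cell, *egoSVC*). Disentangling these
hypotheses requires building the same cell's tuning map in all four
coordinate systems and asking, with a calibrated null, in which of them the
cell carries reliable information.

`socialvec` implements that analysis end to end for binarised calcium-event
rasters and tracked trajectories: map construction in the four reference
frames, shuffle-calibrated cell classification, naive-Bayes population
decoding, remapping statistics across partners and contexts, and the
one-dimensional angle-map analysis for pursuit sessions on an annular track.
A synthetic-session generator with known ground-truth tuning makes every
stage testable without any recorded data.

## Reference frames and the effective arena

For frame $t$, let $s_t$ be the imaged animal's position, $o_t$ the
partner's position and $\phi_t$ the imaged animal's head direction
(counter-clockwise from $+x$). The four map coordinates are

* `self_allo`: $s_t$;
* `other_allo`: $o_t$;
* `rel_allo`: $o_t - s_t$;
* `rel_ego`: $R(-\phi_t)\,(o_t - s_t)$, so that a partner directly ahead
  maps to $+x$ and a partner on the animal's left to $+y$.

The space of possible relative positions (the *effective arena*) spans twice
the physical arena per axis, four times its area, so relative maps use bins
twice as large (4 cm vs 2 cm by default). The choice of ego-axis convention
is immaterial to every statistic in the package; only consistency matters.

Trajectories are cleaned before analysis: samples outside the arena (or
non-finite) are marked invalid and bridged by linear interpolation, then a
15-point centred mean filter smooths each position axis. Head direction is
smoothed circularly (averaging unit vectors over the same window), a choice
we make because angles cannot be averaged linearly across the ±π wrap.
Invalid frames are excluded from every occupancy and count accumulation —
never imputed.

The relative-frame origin is whatever tracked point the trajectory provides
(body centroid or head, depending on the upstream tracker); the transforms
are agnostic, so the choice is the caller's configuration, not the
package's.

## Rate maps, information, stability

The raw rate in bin $i$ is $\lambda_i = c_i / t_i$ (events over seconds of
occupancy). The *smoothed* map divides the Gaussian-smoothed count map by
the Gaussian-smoothed occupancy map (kernel sd 2 bins, truncated at 3 sd):

$$\tilde\lambda_i = \frac{\sum_j w_{ij} c_j}{\sum_j w_{ij} t_j}.$$

We use this occupancy-weighted convention — the standard in the
place-field-toolbox lineage — rather than smoothing the raw rate map with
equal bin weights, because the latter lets a single event in a one-frame bin
(raw rate = frame rate!) dominate its neighbourhood in sparsely sampled
regions of the effective arena. Occupancy weighting pools the evidence
instead, without any ad-hoc occupancy threshold. Unvisited bins stay `NA`.

Spatial information (bits/event) is

$$I = \sum_i p_i \frac{\lambda_i}{\bar\lambda}
      \log_2 \frac{\lambda_i}{\bar\lambda},
  \qquad \bar\lambda = \sum_i p_i \lambda_i,$$

with $p_i$ the occupancy normalised to 1 and $0\log 0 := 0$. Taking
$\bar\lambda$ as the occupancy-weighted mean of the same map (rather than
total events over total time, which differs only through smoothing) makes
$I$ an exact weighted Kullback–Leibler divergence: non-negative, and zero
iff the rate is constant over visited bins. Information is computed on the
smoothed map by default (`use_smoothed = FALSE` switches to the raw map).

Firing fields are local maxima of the smoothed map above 0.5 events/s with
a 4-connected area above 60% of the peak; overlapping candidates merge into
the stronger peak. Two support guards apply to peaks: the peak bin needs at
least 0.1 s of occupancy, and at least 4 s of kernel-weighted occupancy
behind its smoothed estimate — below that, one or two coincident events can
by themselves clear the 0.5 events/s threshold, and the map argmax lands on
sampling noise at the sparse effective-arena fringe. (In our synthetic
validation, genuine fields carry ≥ ~30 weighted-seconds of support, so any
guard between 4 and 29 behaves identically.) `primary_field()` returns the
dominant field — the one with the largest in-field activity — which is the
robust estimator of a cell's field location.

Split-half stability is the Pearson correlation of the smoothed maps from
the two contiguous session halves, over bins visited in both. With an odd
frame count the first half takes the extra frame.

## Shuffle-calibrated classification

For each cell and frame of reference we build the true map's information and
a null distribution from 1000 circular time-shifts of the event train
(uniform shifts with a 20 s floor, so near-identity shifts never enter the
null; the event count is conserved by construction). The cutoff is the 95th
percentile of the null (linear-interpolation percentile). A cell is a
member of the frame's category when its information exceeds the cutoff
*and* its split-half stability exceeds 0.3 — the stability filter applies
per frame-of-reference map. Categories are non-exclusive: one cell may be a
selfPC and an egoSVC simultaneously. Cells with no events are excluded with
an explicit no-events status. Shuffle seeds derive from the session seed per
(cell, frame) with a counter scheme, so results do not depend on cell order
or on which other cells are analysed.

Co-membership of two categories is summarised by the overlap index
$n_{AB} / (N \, \frac{n_A}{N} \frac{n_B}{N})$ — observed joint membership
over its independence expectation — with an exact two-tailed binomial test
at probability $P = (n_A/N)(n_B/N)$.

The *shuffling-in-place* control asks whether apparent social-vector tuning
could be a by-product of self-place tuning. The physical arena is divided
into 10-cm bins; within each bin the frames the animal spent there are
stitched, the event sub-train is circularly shifted by a random amount at
least 5 s from identity (or the maximum-distance shift where coverage is too
short), and the episodes are re-placed in temporal order. This preserves the
self-place map at 10-cm resolution while destroying relative-position
tuning. Ten instances are the default (each instance needs its own
1000-shuffle classification downstream, so the count is deliberately small).
One caveat our validation makes explicit: the within-bin redistribution adds
$\approx 10^2/12\ \mathrm{cm}^2$ of positional variance per axis, so for
compact planted fields (sd 8 cm) the self-map information itself drops by
roughly a tenth — the control is conservative for fields whose width is
comparable to the 10-cm shuffle bin, and the preservation improves as fields
grow.

## Population decoding

Decoding assumes independent Poisson event counts per cell in a window of
length $\tau$ (default 0.5 s). With training-fold tuning curves $f_i(X)$
(smoothed rate maps, floored at $10^{-4}$ events/s so silent bins keep the
log-likelihood finite) and occupancy prior $P(X)$, the decoded bin is

$$\hat X = \arg\max_X \; \log P(X) + \sum_i n_i \log f_i(X)
           - \tau \sum_i f_i(X),$$

ties resolving to the lowest bin index. Cross-validation uses 5 contiguous
segments — train on four, decode the held-out one — never random splits, so
slow drifts cannot leak across folds. The error is the mean Euclidean
distance between decoded bin centre and true position (cm). The shuffled
baseline re-runs the *entire* pipeline (map fitting included) on sessions
whose positions were circularly displaced in time — the stronger null; only
shuffling test positions would leave the decoder trained on real structure.
Sessions with no cells of the tested category are skipped with an explicit
status, not an error. Cross-referent decoding fits on one partner's
relative positions and tests on the same partner (cross-validated) and on
the other (full transfer).

## Remapping

Across contexts with different geometry, maps cannot be correlated bin by
bin, so similarity is measured on normalised population vectors: each cell's
mean event rate per condition, divided by that cell's maximum over the
conditions compared, stacked into a vector and normalised to unit length;
the dot product of two such vectors is the cosine of their angle, in
$[0, 1]$ for non-negative rates. Session halves provide the within-context
reference. When two sessions are compared, the per-cell maximum is taken
over the union of their four halves. Across partners within one session,
`half_map_correlation()` correlates a first-half map for one referent with a
second-half map for the same or the other referent.

## Pursuit sessions on the annular track

On the annulus, head direction is mostly tangent to the track, so relative
position reduces to the signed along-track angle $\alpha$: the angular
separation from the imaged animal to the conspecific measured along the
travel direction, in $[0°, 360°)$ for counter-clockwise travel and negated
(in $(-360°, 0]$) for clockwise travel. Values near 0 mean "just ahead",
absolute values near 360 "just behind". Travel direction is the sign of the
angular velocity about the track centre, smoothed over 0.5 s, with a 3 deg/s
dead band inside which a frame inherits the last confident direction — wide
enough to suppress jitter at rest, narrow enough not to mask reversals.

Angle maps bin $\alpha$ into 15° bins (24 per travel-direction half),
occupancy-normalise, and smooth each half circularly and independently with
a 1-bin Gaussian. The information score applies the same bits-per-event
formula to the 48 pooled bins. Peak metrics grow the *signal region* from
the peak bin through contiguous bins at or above half the peak; the
half-width is that region's angular extent, and the signal-to-noise activity
ratio is the mean smoothed rate inside the region divided by the mean rate
over the complementary noise region (both halves). We normalise per bin
rather than per total deliberately: the share-of-total version is dominated
by the region's size and cannot distinguish sharp from broad tuning when
field mass is conserved, whereas the per-bin ratio directly measures the
contrast the statistic is named after. The share (`signal_fraction`) is
still reported.

The population autocorrelogram correlates the stacked collection of angle
maps with copies circularly shifted from −180° to +180° (each half shifted
independently, one Pearson correlation from both halves together). Its area
under the curve is normalised to the mean correlation over the shift grid so
values are comparable across grids; sharper population tuning gives a
faster-falling autocorrelogram and a smaller AUC. Group differences are
tested by shuffling the population tags of the pooled cells (1000
permutations). Sessions are labelled *naive* until the first session whose
median trial latency falls below 30% of the previous day's maximum latency;
that session and all later ones are *trained*, and the first session is
always naive. The experience curve pools maps over non-overlapping groups
of 5 consecutive sessions and tests the AUC trend with a two-tailed Pearson
correlation.

## The synthetic generator

`simulate_session()` produces sessions with known ground truth, emulating:

* **Foraging**: a smooth correlated random walk. The angular velocity is an
  Ornstein–Uhlenbeck process (time constant 0.7 s, stationary sd
  `turning_sd` = 1.5 rad/s), so the heading is differentiable — real heads
  do not teleport; a Brownian heading would be untrackable by any smoother.
  Speed relaxes toward `speed_target` (8 cm/s, ordinary mouse foraging) with
  jitter; steps that would leave the arena deflect toward its interior.
  Partners can receive a heading bias toward the imaged animal
  (`attraction`) to emulate proximity episodes.
* **Observation noise**: events are generated from the animal's *true*
  heading, while the session exposes head direction with Gaussian tracking
  noise (sd 0.2 rad, an LED-tracking error scale) passed through the
  standard cleaning filter — the analysis faces the observation model, not
  the latent state.
* **Calcium events**: per frame, a cell's rate is its baseline plus Gaussian
  field bumps evaluated in its reference frame; an event is
  Bernoulli(rate·Δt), matching the binarised suprathreshold-frame rasters
  the analysis consumes. Defaults: peak 1 event/s, field sd 8 cm, baseline
  0.05 events/s — the sparse out-of-field rate typical of deconvolved CA1
  calcium event trains; at 0.1 events/s and above, baseline events start to
  dominate split-half stability for 10-minute sessions.
* **Pursuit trials**: the leader runs the track mid-line at fixed angular
  speed, starting each trial at a random angle with direction varying by
  trial; the follower explores freely at its own angular velocity for most
  of the trial latency (the latency is the time until close following
  begins) and closes the gap exponentially in a brief final chase. This
  makes the relative angle sample the full circle in both directions, as a
  mix of free and chase epochs does.

What the generator does **not** emulate: calcium-indicator rise/decay
kernels and event-amplitude structure, wall-following and thigmotaxis,
behavioural ethograms beyond attraction, inter-animal occlusion and
tracking identity swaps, and non-Poisson spike statistics. Passing
validation on these sessions therefore demonstrates that the *analysis*
recovers what it is designed to recover under realistic sampling and
observation noise — not that real CA1 data will be as clean.

## Numerical conventions

* Percentiles use linear interpolation (R's default type 7).
* $0 \log 0 := 0$ throughout; cells with zero events give `NA` information
  and belong to no category.
* Decoder ties break to the lowest flat bin index (x fastest).
* Frame indices are 0-based on disk, 1-based in R; time runs from session
  start; annotation intervals are half-open $[on, off)$.
* One master seed fans out to per-component streams through a counter
  scheme, so adding cells never perturbs trajectories and per-cell results
  are independent of cell ordering; reruns with the same seed are
  byte-identical.
* Sub-window occupancy guards for peak statistics: 0.1 s at the peak bin,
  4 s of kernel-weighted support behind the estimate (rationale above).

## Validation problem sizes

The package validates itself on synthetic sessions at these sizes, chosen to
exercise each property at useful statistical resolution: oracle equivalence
on 100 random instances per statistic; null calibration on 100 untuned cells
× 5 seeds × 4 frames with 1000 shuffles each (the information criterion
alone must sit inside the 99% binomial interval around 5%); parameter
recovery on 50 planted cells per category in one 10-minute session; decoding
on 50-cell populations against 100-shuffle baselines; identity coding on a
36-cell three-mouse session; pursuit sharpening on 40-map populations with
1000 tag shuffles. `scripts/acceptance.R` recomputes the same quantities
from scratch at a single seed.

## Known limitations

* The in-place shuffle's information preservation is field-size dependent
  (see above); for fields much narrower than the 10-cm shuffle bin the
  control under-preserves self-map information.
* Cross-session cell identity is taken as given via matched raster rows;
  registration is upstream.
* The effective-arena fringe (relative distances near the arena diameter) is
  intrinsically under-sampled; statistics there rely on the support guards.
* The decoder's window slides at a configurable stride; the default stride
  of 1 frame is exact but costly, and validation uses stride 15 (one window
  per half second), which changes the window count, not the estimator.
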