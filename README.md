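# socialvec

Reference-frame analysis of hippocampal social-spatial coding from
calcium-imaging sessions of interacting mice.

When a mouse forages with a conspecific, a CA1 neuron may encode the
animal's own arena position (a place cell, *selfPC*), the partner's arena
position (*socialPC*), or the partner's position relative to the animal in
arena-fixed (*alloSVC*) or head-rotating (*egoSVC*) axes. `socialvec` builds
each cell's occupancy-normalised event-rate map in all four coordinate
systems, classifies cells against temporal-shuffle null distributions,
decodes position from population activity with a naive-Bayes decoder under
contiguous cross-validation, quantifies remapping across partners and
contexts, and reduces annular-track pursuit sessions to one-dimensional
angle maps with population autocorrelograms. A synthetic-session generator
with known ground-truth tuning supports end-to-end validation of every
stage.

It is aimed at systems-neuroscience analysts working with miniscope
recordings of socially interacting rodents, downstream of motion
correction, source extraction, pose tracking and event binarisation.

## The statistics at the core

Spatial information of a map (bits per event), with `p_i` the normalised
occupancy, `λ_i` the event rate in bin `i` and `λ̄ = Σ p_i λ_i`:

    I = Σ_i p_i (λ_i / λ̄) log2(λ_i / λ̄)

A cell joins a category when `I` exceeds the 95th percentile of 1000
circular time-shifts of its event train *and* its split-half map stability
exceeds 0.3. Decoding maximises the Poisson log-posterior over position
bins `X` given window counts `n_i` and training-fold tuning curves `f_i`:

    X̂ = argmax_X  log P(X) + Σ_i n_i log f_i(X) − τ Σ_i f_i(X)

The shuffling-in-place control permutes events within episodes of identical
self-location (10-cm bins), preserving the self-place map while destroying
relative-position tuning — separating genuine social-vector cells from
place-cell artifacts.

## Worked example

Simulate a 10-minute two-mouse session with a planted place cell, a planted
egocentric social-vector cell and an untuned cell, then classify:

```r
library(socialvec)

arena <- arena_geometry("circle", diameter = 70)
truth <- list(
  ground_truth_cell("self_allo", c(10, 5)),
  ground_truth_cell("rel_ego", c(15, 0), referent_gains = c(p1 = 1)),
  ground_truth_cell("self_allo", c(0, 0), peak_rate = 0.3, baseline_rate = 0.3))
session <- simulate_session(arena, duration = 600, seed = 42, truth = truth)
session
#> <social_session> circle arena, 2 animals, 3 cells x 18000 frames @ 30 Hz

cl <- classify_cells(session, n_shuffles = 1000, seed = 1)
cl[cl$member, c("cell", "category", "info", "cutoff", "stability")]
#>    cell category  info cutoff stability
#> 1     1   selfPC 0.734  0.267     0.884
#> 11    2   egoSVC 0.447  0.230     0.724
```

Cell 1 carries 0.73 bits/event about the animal's own position (null cutoff
0.27) with split-half stability 0.88 — a place cell. Cell 2 is informative
only about the partner's position in head-rotating coordinates — an
egocentric social-vector cell. The untuned cell 3 joins no category. The
planted ego field at (15, 0) cm is recovered on the effective-arena map:

```r
m <- session_rate_map(session, 2, frame_spec("rel_ego", "p1"))
m
#> <rate_map> 35x35 bins of 4 cm, 600.0 s occupancy, 72 events, peak 0.51 ev/s
map_peak(m)[c("x", "y")]
#> $x
#> [1] 20
#> $y
#> [1] 4
```

— within one 4-cm bin of the planted centre. `cross_validated_decode()`
then decodes position from member populations against a 100-shuffle
baseline, and `run_session_analysis()` writes the per-cell classification
CSV, category summary JSON and decoding JSON for a whole session.

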