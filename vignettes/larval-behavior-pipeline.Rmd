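---
title: "Quantifying larval defensive behavior: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying larval defensive behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethome)
```

# The problem

A Drosophila larva startled by an air puff or a nociceptive stimulus chooses
among a small repertoire of mutually exclusive actions: it may crawl on,
stop, hunch (retract its head), bend, back up, or escape by rolling.  Video
tracking reduces each animal to a time series of midline ("spine") points,
and a machine-learning classifier turns those into an action label per time
point.  The coarse vocabulary (Crawl, Bend, Hunch, Back, Stop, Roll),
however, lumps together actions with very different circuit interpretations:
a dynamic exploratory head cast, a sustained defensive static bend, and the
C-shaped bend that precedes rolling are all "Bend"; a hunch and a
simultaneous head-and-tail retraction are both "Hunch".  This package
implements a refinement layer that separates them, the population statistics
used to compare genotypes and stimulus conditions, and the companion
analyses (synapse-table summaries for circuit reconstruction, dF/F0
processing for calcium imaging).

Because the underlying tracking data are large and external, the package
ships a synthetic-trajectory generator with exact ground truth.  Every
downstream stage is validated end to end against that generator.

# Kinematic features

All features are computed per frame from the K spine points (head first) and
are normalized by the larva's instantaneous body length, so they are
dimensionally speeds in s^-1 and invariant to spatial scale:

* `v_head`, `v_motion`, `v_tail` -- length-normalized speeds of the head
  point, the centre of mass G (the mean of the spine points) and the tail
  point.  Velocities use central differences over one frame by default
  (`stencil` configurable); frames adjacent to tracking gaps are NA.
* `S` -- the spine order parameter, S = (3 \<cos^2 theta\> - 1) / 2, where
  theta is the angle between each spine segment and the tail-to-head body
  axis.  S = 1 for a straight larva, -0.5 if every segment is orthogonal to
  the axis.
* `lambda` -- the anisotropy (l1 - l2) / (l1 + l2) of the 2x2 covariance of
  centre-of-mass displacements over a sliding window (default 5 frames):
  0 for isotropic wander, 1 for straight-line motion.  The window length is
  a package choice; the construction (covariance of movement) is fixed.
* `len_ratio` -- |HG| / |TG|, which drops below 1 as the head retracts.
* `proj_head`, `proj_tail` -- the component of each end's velocity along the
  closest spine segment (closest-point rule on the polyline), signed
  positive toward the tail.  A min-distance formulation of this feature is
  ambiguous between the projected component and the residual distance; we
  compute both (the residual as an attribute) and default to the former.
* `cos_head`, `cos_tail` -- cosine between each end's velocity and the
  first/last spine segment.
* `bend_angle` -- signed angle between the head-end and tail-end segment
  directions (0 = straight).  We use the end-tangent construction rather
  than the centre-of-mass chord construction because the chord angle
  saturates well below 90 degrees for strongly bent postures and cannot
  express a C-shape threshold of 100 degrees.
* `dlen` -- relative length change rate, the peristalsis/startle signature.

Per-action aggregates take the mean, max and min of each feature over the
action's frames, plus context means over 5 frames before and after
(truncated and flagged at track edges) and the action duration.

A note on units: a length-normalized speed has unit s^-1 (sometimes
misprinted as s^-2 in this literature); the static-bend annotation
threshold is 0.02 s^-1 throughout.

# The two-layer refinement classifier

The refinement assumes a coarse classification already exists.  The package
provides a pluggable base layer: either externally supplied coarse intervals
(pass-through, the supported route for real tracker output) or a documented
threshold-rule stand-in on the frame features (Roll by alternating bend
side, Stop by all speeds below 0.01 s^-1, Hunch by rapid shortening of a
straight body, Back by rearward centre-of-mass motion, Bend by bend angle).
The stand-in is deliberately simple: it exists so the refinement can be
exercised end to end, not as a reimplementation of a production tracker
classifier.

Training data for the refinement are labeled by rule:

* **Head Cast**: sampled randomly (seeded) from Bends occurring before the
  stimulus, where defensive postures cannot occur.
* **Static Bend**: Bends during stimulation whose normalized motion speed
  stays below 0.02 s^-1 for at least 50% of the action's frames.  The
  threshold is deliberately low so that mislabeled dynamic bends do not
  steer the ensembles.  The 50% clause reads: below threshold for at
  least half of the action's frames.
* **Hunch / Head-and-Tail / C-shape**: classes of this kind are manually
  annotated in real workflows.  The package substitutes generator ground
  truth for manual tags, and tags take precedence over the automatic rules -- without
  that precedence, static C-shapes satisfy the Static-Bend speed rule and
  poison its label set.

Two random forests (300 trees, sqrt-features per split, alphabetical
tie-break; all configurable) are then fitted on the per-action aggregates:
layer 1 maps coarse Bends and Hunches to {Head Cast, Static Bend, new
Hunch}; layer 2 maps the new Hunches to {Hunch, Head-and-Tail, C-shape}.
C-shape can be placed in either layer; the second-layer placement is the
default and `layer1_classes = 4` promotes it to layer 1.  All other coarse labels map one-to-one
(Back becomes BackUp), so the refinement never alters anything except
Bends and Hunches, and output intervals tile the input exactly.

Head Casts are post hoc subtyped slow/fast by a tail-speed threshold
(default 0.08 s^-1), reflecting the two observed subcategories (tail moving
with the centre of mass vs. a tail-propelled lunge); the subtype is not a
trained class.

`evaluate_classification()` scores predictions frame-weighted: both interval
sets are sampled on a uniform grid so long actions count proportionally.

# Population statistics

* **Ethograms** discretize refined intervals onto a uniform grid (label at
  the bin midpoint; tracking gaps marked untracked, never a label).
* **Cumulative probabilities** count larvae performing at least one
  interval of an action overlapping a post-onset window, divided by the
  number of larvae tracked at the window start.  Larvae not tracked at
  stimulus onset enter neither numerator nor denominator.
* **Transition matrices** count transitions between consecutive distinct
  actions; adjacent same-label intervals are merged first, so
  self-transitions cannot occur.  A transition's time is the start of the
  destination interval, and the window is judged on that time (the
  conditioning convention -- all in-window transitions, not just the first
  -- is the default; the alternative is a window choice away).  Cells below
  3% are flagged hidden for display but retained in the data.
* **Tests**: Pearson chi-square without continuity correction (a flag
  restores Yates), Benjamini-Hochberg step-up FDR with a planned-comparison
  pass-through mode, and the two-sample Kolmogorov-Smirnov test with the
  asymptotic p-value (exact available).  Velocity distributions are
  visualized with Gaussian-kernel density estimates under a Scott-rule
  bandwidth (sigma n^-1/5), falling back to a fixed minimal bandwidth for
  degenerate samples.
* **Crawl-speed comparison** contrasts per-larva mean normalized
  centre-of-mass speeds during Crawls before vs. during stimulation,
  detecting stimulus-evoked fast crawling.

# Connectivity summaries

Synapse tables carry directed weighted edges plus neuron metadata (class,
side, hemilateral partner, skeleton node count, neuromere).  Fraction of
input divides a target's incoming synapse count per partner (left/right
homologs pooled by name) or per class by its total input; fractions sum to
1 with fragments and unreconstructed inputs included.  Strong partners
apply the >= 3-synapse threshold to the maximum over a hemilateral pair.
Neurons with fewer than 1,500 skeleton nodes are flagged as fragments --
not reconstructed up to recognition -- except sensory neurons, which are
recognizable regardless of reconstruction depth; fragments are excluded
from named-partner listings but stay in input-fraction denominators.
Hop distances to motor neurons run over the graph restricted to >= 3-synapse
edges (axo-axonic edges counted as ordinary directed edges), and motor
neurons are grouped by their ordered distance pair from two seed neurons.

# Calcium traces

dF/F0 uses F0 = mean fluorescence over the baseline window (default: the
pre-stimulus segment, matching the 5 s / 5 s / 5 s experiment layout);
dF/F0 = (F(t) - F0) / F0 is gain-invariant and has baseline mean 0 by
construction.  Averages equalize repetition counts across larvae by seeded
subsampling to the minimum, then report the mean with the standard error
across larvae (the across-repetition dispersion is also returned, since
figures differ in which they show).  Traces showing activity before
stimulation are excluded; "activity" is operationalized as any baseline
|dF/F0| above a threshold (default 0.3, configurable and logged) -- a
package choice, since the criterion is inherently verbal.

# The synthetic generator

`simulate_larva()` realizes each action's defining kinematics with a
two-section ("hinge") body model: two straight half-spines joined
mid-body, with a bend angle, per-section compression factors, and a
centre-of-mass velocity per motif.  The conventions (not measurements):

* Crawl: straight body, +-8% sinusoidal length oscillation at 1 Hz, forward
  speed 0.06 body lengths/s; post-onset fast crawls multiply the speed
  (default 1.5x).
* Head Cast: bend oscillates (+-50 degrees, 2 s period) with the tail
  anchored in place, so the centroid swings with the sweep and peak head
  speed exceeds 3x the centre-of-mass speed; the fast variant adds a
  0.12 L/s lateral drift of the anchor.  Anchoring the tail matters: a
  generator that pivots the posture about its centroid produces head casts
  whose motion speed sits below the static-bend annotation threshold,
  which would corrupt the auto-tagged training labels in a way real
  kinematics do not.
* Static Bend: constant 50-degree bend, zero speeds.
* Hunch: straight body, anterior compressed to 55% within 0.5 s (head-to-
  centroid distance contracts > 20%).
* Head-and-Tail: both sections compressed to 65% within 0.5 s, so the total
  length drop (35%) exceeds the Hunch drop (about 22%).
* C-shape: constant 110-degree bend, both ends still.
* Roll: bend side alternating at 2 Hz with 0.1 L/s lateral translation (a
  planar proxy; true rolling is three-dimensional).
* Back-up: rearward 0.05 L/s; Stop: immobile.

Populations draw motif sequences from epoch-dependent Markov kernels
(baseline: crawl/head-cast/stop exploration; stimulus: the avoidance
repertoire) with per-label mean durations jittered +-30%, under a protocol
whose default is an air puff at the 60th second for 30 seconds, 10 Hz
sampling, 11 spine points, 4 mm body length.  A configurable fraction of
larvae (default 10%) is untracked before stimulus onset.  Noise enters as
per-point Gaussian jitter and heading drift.

What the generator does *not* emulate: contour deformation beyond the
midline, biomechanics (peristalsis is a length oscillation, not a wave),
3-D rolling, tracker artifacts other than dropouts, and realistic
inter-larva variability of speeds and durations.  Passing
recovery tests on this generator therefore demonstrates that the pipeline's
machinery is correct and that the refined classes are separable when their
defining kinematics hold -- not that any particular accuracy will be
attained on real tracker output.

# Numerical and design choices

* Seeds: every stochastic step takes an explicit seed; the pipeline fans a
  single seed out to per-stage child seeds drawn once.  Identical
  configuration and seed give byte-identical outputs.
* Degenerate inputs: zero-length spine segments are skipped in S (all-zero
  errors); a zero movement covariance gives lambda = 0; a zero velocity
  gives NA cosines; zero-variance KDE samples fall back to a minimal
  bandwidth with a warning.
* Boundary conventions: intervals are half-open [start, end); the
  fragment rule is strict (< 1500); the static-bend rule requires >= 50%
  of frames strictly below threshold; `tracked_at` accepts the nearest
  frame within half a frame period (inclusive).
* Non-finite aggregate features are median-imputed at training time and the
  medians are stored in the model for inference.
* Problem sizes: unit tests run populations of 8-50 larvae; the recovery
  experiment uses 100 training and 200 test larvae with 90 s recordings at
  10 Hz.  These sizes are package choices balancing statistical stability
  of per-class recall against run time.

# Known limitations

The rule-based base layer fragments oscillatory actions near motif
boundaries (a documented stand-in; real deployments should pass external
coarse labels).  The refinement inherits whatever interval boundaries the
base layer provides and never re-segments.  GtACR1-style datasets, which
need a separately trained second classifier, are supported only as a
recipe: train on fixtures from that condition with the same machinery.
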