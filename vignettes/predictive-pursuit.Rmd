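---
title: "Modeling predictive pursuit with rank-constrained recurrent networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling predictive pursuit with rank-constrained recurrent networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific question

When a pursuer is not much faster than its target, catching it requires more
than running at it: the pursuer must exploit regularities in the target's
behavior to anticipate where it is going. `pursuitnet` provides a complete
simulation-and-analysis pipeline for studying how such *predictive pursuit*
emerges in recurrent neural network (RNN) agents: a task world with
controllable target statistics, a trainable RNN pursuer whose recurrent
connectivity rank can be constrained, a reactive (non-predictive) baseline
pursuer, and the behavioral and representational statistics that separate
prediction from reaction.

## The task world

Both agents move in a square arena (default 1 m x 1 m) discretized at
`dt = 0.05` s for `n_steps = 100` steps, i.e. 5 s trials. Neither the trial
duration nor the time-step has a privileged value; these defaults give paths
whose spatial scale (tens of centimeters per trial leg) matches rodent-style
pursuit arenas, and both are configurable in `arena_config()`. The boundary
is either *reflective* (solid walls) or *periodic* (a torus: leaving one
side re-enters at the opposite side, and every distance in the package then
uses the minimal image).

Two target behaviors define the task statistics:

* **Random trajectories (RTs)** come from a smooth random forager in the
  Raudies-Hasselmo style: the heading performs a Gaussian random walk (sd
  `heading_noise_sd * sqrt(dt)` per step), the speed is an AR(1) process
  around `speed_mean`, and near a reflective wall the target turns away and
  slows. Defaults (`speed_mean` 0.2 m/s, sd 0.05 m/s, heading diffusion
  1.5 rad/sqrt(s), wall avoidance within 0.1 m) produce smooth, wall-avoiding,
  unique paths. Whether the underlying speed law of the original forager is
  Gaussian-AR or Rayleigh is not critical to any analysis; the AR form was
  chosen because its stationary moments are exactly controllable, and the
  parameters are all exposed in `rt_params()`.
* **Characteristic trajectories (CTs)** repeat one of four stereotyped
  routes: from a start location on one wall, straight across the arena to
  the opposite wall, then along that wall toward its midpoint. The start
  locations are the four wall midpoints offset 0.1 m toward the origin
  corner; the verbal description "toward the middle" is ambiguous between
  the wall midpoint and the arena center, and the wall midpoint was chosen
  (the final leg then hugs the wall); both are configurable via waypoints in
  `ct_params()`. Realizations jitter in speed and heading but keep the route
  skeleton, so time-aligned CT paths of the same start are an order of
  magnitude closer to each other than RT paths are -- the repeated structure
  the analyses rely on. On the periodic arena the routes instead exit
  through the near wall and reappear at the opposite side, which is the
  torus analogue of "cross the arena" and produces the
  disappear-and-reappear episodes that make waiting strategies visible.

A trial adds a pursuer start (uniform, at least 0.1 m from the target start,
so no trial begins captured) and an input mask. Masking withholds the
target-velocity input on a fraction of steps; the default pattern is regular
temporal subsampling (keep every k-th step), realizing masking as increased
temporal spacing between inputs, with a Bernoulli option.

## The RNN agent

The pursuer is a leaky discrete-time rate network with `N` units (the
full-scale preset uses 1000; desk-scale runs here use 64) and a
rank-constrained recurrent matrix

> W = M Q' / N, with M, Q of size N x r,

so that rank(W) <= r holds *exactly*, and training -- which updates only the
factors -- can never raise it. The dynamics are

> h' = (1 - alpha) h + alpha (W tanh(h) + B u + b),

with the nonlinearity inside the recurrent product. This form was chosen
deliberately: with h(0) = 0 the hidden state stays in the span of the
columns of M and B plus b at every step, so the latent dimensionality of a
rank-r network is bounded by r + n_in + 1 as an exact algebraic fact, not an
empirical tendency. The leak is alpha = 0.5; the factor variances are set so
the largest singular value of W is about `gain` (default 1) at every rank.

Inputs (6 channels): the initial positions of both agents as a single pulse
on the first step, and the target's allocentric velocity wherever the mask
is on (zero elsewhere). The pulse encoding matters: a persistently available
position input would hand the network ground-truth spatial information,
which the task withholds by design -- position knowledge beyond t = 0 must
be built by integrating velocities.

Outputs: the agent steers with two degrees of freedom, movement direction
and speed. A literal (angle, speed) channel pair has a 2-pi discontinuity,
so the readout is a 2-vector z whose angle is the direction and whose
squashed norm `v_max * ||z|| / (1 + ||z||)` is the speed -- the same
information, smooth and bounded. The agent speed cap defaults to 0.3 m/s,
1.5x the RT target's mean speed: pure pursuit is feasible but not trivially
dominant. Headings are frozen below 1e-3 m/s so egocentric coordinates stay
defined while the agent waits.

## Training

Training is supervised backpropagation through time with Adam, on fresh
trials every epoch (75% RT / 25% CT by default). Two losses implement two
task objectives: `final_distance`, the inter-agent distance on the last
step (a capture objective, which leaves the path free), and
`mean_distance`, the average distance over all steps (which rewards
reactive shadowing). Plain rather than squared distance is used, matching
the objective of minimizing the distance itself; a squared variant is
available. Boundary resolution is treated as the identity in the backward
pass; this straight-through choice is exact whenever the rollout does not
hit a wall. Gradients are checked against finite differences in the test
suite at 1e-4 relative tolerance. Defaults (learning rate 3e-3 with a 5x
step decay over the last 30% of epochs, batch 32, 128 trials/epoch, 150
epochs, gradient-norm clip 1) were chosen so desk-scale networks (N = 64)
converge in about a minute of CPU and end in a stable minimum rather than
bouncing around one; they are recorded in every run manifest.

Unit ablation is structural: the unit's rows of M and B and its bias are
zeroed (its state stays 0) and its row of Q and readout column are zeroed
(nothing downstream sees it), so ablated checkpoints are self-contained and
the rank bound survives.

## The reactive baseline and behavioral metrics

The non-predictive control starts where the RNN-agent started and at each
step moves straight toward the target's *current* position, at the RNN's
own instantaneous speed -- a realistic reactive pursuer rather than an
optimal greedy one, and the correct baseline for asking whether the RNN
does anything beyond distance minimization. Its step is clamped to the
current distance (no overshoot oscillation near capture; the choice only
matters within one step of contact), and on the torus it chases along the
minimal-image direction, through walls -- the strongest reactive baseline.

Predictivity is quantified by:

* the **shortcut metric**: mean distance from a trajectory to the straight
  segment joining the pursuer's start to the target's final position -- the
  perfect-knowledge reference path, making 0 a lower bound;
* the **normalized deviation** between RNN and control trajectories (mean
  pointwise distance over the RNN path length; the normalizing length is a
  package choice -- the control-path variant gives the same qualitative
  picture);
* two-sample **Kolmogorov-Smirnov** tests and the order-1 **Wasserstein**
  distance between shortcut-metric distributions (asymptotic KS p-values;
  at thousands of trials exact and asymptotic are indistinguishable);
* **waiting detection**: maximal runs where the distance to the target's
  end location stays flat, the ambush signature in periodic arenas.

On the periodic arena the shortcut reference uses the minimal-image chord;
since a straight reference is geometrically questionable on a torus, those
values are not compared across boundary conditions.

## Representational analyses

Egocentric target coordinates (distance, bearing; bearing 0 = ahead,
counterclockwise positive) feed bearing-distance ratemaps and the mean
resultant length (MRL) of each unit's bearing tuning curve. Because tanh
activations are signed while the circular-concentration statistic assumes
nonnegative weights, the tuning curve is shifted by its minimum before the
resultant is taken; this makes the MRL invariant to activation offset and
positive rescaling, and maps flat tuning to 0 and single-bin tuning to 1.
Defaults: 36 bearing bins, 10 distance bins, 20-sample minimum occupancy.

A unit is an **egocentric target unit (ETU)** when its MRL exceeds the 99th
percentile of its own time-shuffle null and does so in each of two disjoint
halves of the trials. "Consistent across splits" admits two readings
(independent threshold exceedance vs correlated split MRLs); the threshold
reading is used because it yields a calibrated false-positive rate, which
the tests verify at about the nominal 1-2% on pure-noise populations.
Shuffle nulls permute activations against fixed coordinates; one
permutation per round is shared by all units, which leaves per-unit
percentiles unchanged and makes the null a single binned average per round.

Time-shift profiles re-pair activations at t with target coordinates at
t + k (prospective k > 0) and recompute MRL and ETU fractions; planted-lag
simulations in the test suite confirm the profile peaks at the true lag.

Dimensionality is measured as the number of principal components explaining
95% of activation variance and as the participation ratio
(sum lambda)^2 / sum lambda^2. For "latent variables" of a low-rank network
the package uses the r-dimensional recurrent drive Q' tanh(h) / N -- the
quantity whose dimensionality the rank constrains.

Linear decoding of task features (egocentric target distance; allocentric
target and self positions) uses closed-form ridge regression with the
penalty chosen by inner cross-validation, folds split **by trial** -- never
by time sample, which would leak within-trial autocorrelation across folds
(a leakage test with per-trial feature offsets guards this). Errors are
median absolute (Euclidean for 2-D features), in meters; the baseline
re-runs the identical pipeline on trial-permuted features.

## Scales, reproducibility, and what the tests show

Every stochastic entry point takes a seed and restores the caller's RNG
state; datasets, training runs and experiments are bit-reproducible from
their manifests. `scale_preset()` defines three problem sizes: `smoke`
(N = 32, T = 30, seconds -- contract checks), `desk` (N = 64, T = 100,
ranks {2, 8, 32, 64}, 500 evaluation trials -- the scale at which the test
suite and the acceptance script replicate the qualitative signatures on a
single CPU), and `full` (N = 1000, ranks 10-1000, 30 seeds per condition --
the full-scale configuration, intended for a cluster).

The desk-scale replication reproduces the qualitative signatures: trained
networks beat their reactive controls' shortcut metrics (KS p < 0.05 over
hundreds of trials), exploit CT structure more than RT structure (larger
Wasserstein separation on CTs), and become more shortcut-like as rank
increases. The synthetic world emulates the statistical structure the
analyses assume -- smooth wall-avoiding pseudo-random motion and repeated
low-variance routes -- but not, deliberately, sensory noise, evasive
targets, reward-driven learning, or any biophysical detail of real neurons;
conclusions from passing tests are about the model class, not about brains.

## Known limitations

* Desk-scale networks are two orders of magnitude smaller than the study
  scale; quantitative values (median end distances, ETU percentages)
  shift with scale even where every qualitative signature is stable.
* The straight-through treatment of wall clipping biases gradients on
  trajectories that ride the boundary; trained agents rarely do.
* The shortcut metric's reference path on the torus is a modeling
  convention, and periodic-arena shortcut values are not comparable to
  reflective-arena ones.
* Exact ETU counts depend on binning and occupancy thresholds; all are
  exposed as parameters and recorded in manifests.
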