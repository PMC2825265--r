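---
title: "Discovering prototypical movements: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering prototypical movements: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoproto)
```

## The problem

Continuous movement recordings — here the 6-DOF head trajectory of a flying
insect, sampled every millisecond — do not come pre-segmented into
behavioural units. ethoproto identifies recurring elementary movements
("prototypes") without predefined categories: every time step is described
by a feature vector, the feature distribution is clustered, each time step
is labelled with its nearest cluster centroid, and maximal runs of constant
label become prototypical movements with durations. The hard part is not
k-means itself but deciding, objectively, **how many** prototypes the data
supports; the package's validation framework answers that with a
stability-plus-quality criterion.

## Features

For trajectory input the features are the six body-frame velocities:
forward, sideward and upward translation (m/s) and yaw, pitch and roll
rotation (deg/ms). Row $i$ is the displacement from sample $i$ to $i+1$
expressed in the animal's own frame at time $i$ — so the features do not
depend on where the animal is or which way it faces in the arena (a rigid
world-frame rotation of the whole trajectory leaves the feature matrix
unchanged; this invariance is property-tested at 1e-8).

Conventions, fixed once and used everywhere:

* Orientation is yaw/pitch/roll (Tait–Bryan, intrinsic Z–Y′–X″). Body axes
  x forward, y left, z up. Hence positive yaw velocity = left turn,
  positive roll = clockwise roll seen from behind, positive pitch = head
  down.
* Angular rates come from the rotation logarithm of the relative rotation
  $R_i^\top R_{i+1}$, not from differencing Euler angles; at 1 ms sampling
  and animal-scale rates the conversion error of the small-angle reading
  the log generalises is below 0.1%, but the log is exact at any rate.
* The last sample has no velocity row (forward difference); feature row
  $i$ carries time stamp $t_i$.

Raw trajectories are measurement-noisy; differencing amplifies that noise.
`smooth_trajectory()` therefore applies an order-2 low-pass Butterworth
filter twice, forward and backward (zero phase, effective gain
$|H(f)|^2$), with a relative border frequency of 0.1 of Nyquist — gentle
enough to leave the trajectory's slope (and so the velocities) essentially
intact while suppressing sample-to-sample noise. The filter coefficients
come from the signal package; the zero-phase pass is implemented with
odd-reflection edge padding because plain forward–backward filtering with
zero initial state produces large edge transients (a constant channel must
come back unchanged to 1e-9, and it does).

Because squared Euclidean distance adds feature differences, each feature
is z-normalised to mean 0, sd 1 (`znormalize()`). The parameters are kept:
centroids are mapped back to physical units (`renormalize_centroids()`)
for interpretation, and **reduced data sets reuse the full data's
normalisation** so that centroid sets from different leave-out conditions
live in one comparable space. Whether the original analysis re-normalised
each reduced set independently is not documented; sharing the parameters
is the choice that makes centroid distances across conditions meaningful,
which the validation framework requires.

`pca_diagnostic()` reports, separately for the translational and the
rotational triple, how variance spreads over principal components. It is a
diagnostic only: if no component dominates, all six features are kept (the
package never reduces dimensionality automatically).

## Constraining k: Ward pre-scan

Agglomerative clustering with Ward's criterion merges, at every step, the
two clusters whose fusion minimally increases total within-cluster
variance; the increase for clusters $(n_1, c_1)$ and $(n_2, c_2)$ is
$\frac{n_1 n_2}{n_1+n_2}\lVert c_1 - c_2\rVert^2$, and the increases
telescope exactly to the total variance. The agglomeration is delegated to
`stats::hclust(method = "ward.D2")`, whose heights $h$ give the joining
cost as $h^2/2$; agreement with a brute-force greedy implementation of the
definition is a test (1e-10, N ≤ 50), not an assumption.

`cost_curve()` indexes each merge by the number of clusters it starts
from: the entry at $m$ is the cost of going from $m$ to $m-1$ clusters.
`suggest_k_range()` anchors on the smallest $k$ whose cost exceeds 8× the
median of the `window = 5` next costs (at larger cluster counts) and
returns $[2, k+3]$. The factor deserves a note: cost curves of
*unstructured* data accelerate smoothly, and their local window-median
ratios reach about 4–5 at small $k$, so a small factor would "find" an
elbow in pure noise; merging across a genuinely separated cluster boundary
raises the cost by an order of magnitude or more (≈30× on the bundled
benchmark). 8 sits between the regimes. When no cost stands out the
function warns and falls back to $[2, 50]$ — mirroring noisy behavioural
data, where the pre-scan typically cannot pin a distinct number and only
bounds the k-means search.

The pre-scan is quadratic in N; apply it to subsequences (a few thousand
points), never to a full long recording — `ward_cluster()` refuses more
than 20 000 points.

## k-means

`lloyd()` is the classic alternation of nearest-centroid assignment
(squared Euclidean) and mean update, started from k distinct data rows
drawn under a seed, stopped when the largest centroid displacement falls
below `tol = 1e-6` (normalised units) or after `max_iter = 1000`
iterations. Details that matter for reproducibility:

* assignment ties go to the lowest centroid index;
* a cluster that runs empty is re-seeded at the point farthest from its
  nearest centroid (deterministic); returned clusterings never contain
  empty clusters;
* the objective trace is recorded and must be non-increasing (asserted in
  tests on every run);
* `method = "fast"` evaluates distances with one BLAS cross-product,
  `method = "naive"` loops per centroid; both are exact evaluations of the
  same quantity, and label agreement on 10 000 random points is an
  acceptance check.

A single Lloyd run only finds a local optimum. On the bundled benchmark a
single run reaches the global optimum in roughly a quarter of starts
(random rows often miss the smallest component), while the best of 12
restarts fails in only a few percent of cases — hence
`restarted_kmeans(n_restarts = 12)` is the unit of clustering everywhere,
including inside the validation scan. Smart seeding (k-means++ and
relatives) is deliberately not the default: uniform row sampling is the
documented protocol, and the restart mechanism is the robustness device.

## Validation: stability first, then quality

**Data variation.** For sequential behavioural data, random point
subsampling destroys exactly the temporal structure under study.
`leave_out_plan()` instead removes a *contiguous* block of 10%, 20% or 50%
of the sequence at 50 equidistant cut positions (every 2%), wrapping at
the sequence end so every mask keeps the same number of points and every
point is kept in most masks.

**Centroid-based instability.** Two clusterings are compared by their
centroid sets, not by partition-overlap indices: `match_distance()`
matches centroids one-to-one with the Hungarian algorithm (an O(k³)
Jonker–Volgenant implementation, tested against the exhaustive permutation
minimum) minimising the sum of squared Euclidean distances, normalised by
$k \cdot F$. Among repeated runs, the **mean set** is the member with the
smallest mean distance to the others; that minimal mean distance is the
collection's *instability* (`mean_set()`). The reported `mean_error`
follows the documented convention literally — the standard deviation of
the mean set's distances divided by the number of sets — although
sd/√n would be the conventional standard error; changing it would
silently change reported numbers, so the literal reading is kept and
flagged here. Note one more numerical caveat: the matched sum of
*squared* distances is not itself a metric (squared distances violate the
triangle inequality); its square root is, and the property tests check
exactly that.

**Quality.** Per cluster, $Q_j = d_j^2 / \sigma_j^2$: the squared distance
to the nearest other centroid over the mean squared distance of the
cluster's members to their centroid — a squared separation/compactness
ratio, evaluated per cluster so that individual prototypes can be judged;
the mean over clusters scores a whole clustering. Both numerator and
denominator are in squared-Euclidean units; this reading of the "squared
index" is isolated in `cluster_quality()` for easy revision. A
zero-variance cluster yields $Q_j = \infty$, excluded from the mean with a
warning. Quality is always evaluated **on the full data**, also for
centroids fitted on reduced sets.

**The scan and the decision.** `validation_scan()` measures, per k:
within-condition stability (10 restarted fits on the full data; one
restarted fit per leave-out mask), between-condition stability of the
per-condition mean sets, and the quality of every condition's mean set.
`select_k()` then treats stability as a prerequisite: k is admissible if
its between-condition instability is within 2× the scanned minimum *or*
below an absolute floor of 0.003 (the scale at which instabilities on
normalised data are negligible; without the floor, a minimum of numerically
zero would reject equally-stable competitors over 1e-5-scale noise). Among
admissible k, the highest mean quality wins; ties go to the smaller k. Both
the factor and the floor are parameters, because no exact threshold is
canonical — quality typically keeps rising with k while instability
eventually explodes, and the rule formalises "the best quality among the
stable options".

## Synthetic data: what it emulates, and what not

`default_artificial_spec()` is a five-component 2-D Gaussian mixture
(n = 500, unequal weights 0.30/0.25/0.20/0.15/0.10, component sd 0.7) with
means on a regular pentagon of circumradius 5 — nearest-neighbour
separation 8.4 sd, and, importantly, *no* cluster in a hub or rim
position. The pentagon is a deliberate choice: with a central cluster,
removing it (k = 4) doubles every remaining cluster's separation and the
quality index rewards the wrong k; with a rim cluster, sub-k solutions
keep one isolated high-quality cluster. On the pentagon the mean-set
quality has a clear maximum at five (≈30–35 vs ≈27 at k = 4 and ≈22 at
k = 6 across seeds) and the full scan selects k = 5 for every generator
seed tried.

`default_flight_spec()` emulates saccadic insect flight as a semi-Markov
alternation of nine states: four saccade states (yaw ±1.1 deg/ms with
*same-sign* roll of 0.3 deg/ms — a left turn comes with a clockwise roll —
pitch variants ±0.2 deg/ms, forward 0.4 m/s) and five intersaccade states
spanning forward 0.23–0.64 m/s coupled with downward 0.02–0.31 m/s and
sideward ±0.15 m/s. Dwell times are gamma distributed (shape 4) with
means 12 ms (saccade) and 40 ms (intersaccade), so saccades are short and
rarely exceed 20 ms while most intersaccades do. Velocity noise sd:
0.06 m/s / 0.08 deg/ms within saccades, 0.04 m/s / 0.03 deg/ms within
intersaccades — small enough that the nine states are separable, large
enough that assignments are not trivial. The trajectory is integrated from
the body-frame velocities with exactly the discretisation that
`body_frame_velocities()` inverts, so the feature round trip is exact to
1e-10 and recovery errors measure the pipeline, not the fixture.

What the simulator does **not** model: aerodynamics, smooth velocity
transitions between states (real saccades ramp up and down; simulated
states switch instantaneously), measurement noise on positions, or
correlated noise. Passing the recovery tests therefore shows the pipeline
is correct under clean semi-Markov conditions; on real recordings,
transition ramps produce short spurious segments and classification
uncertainty that the synthetic results do not exhibit. For the same
reason, per-group movement durations are compared at the group level
(rotational vs translational): a rare within-group misassignment between
two similar translational prototypes would otherwise split one long
intersaccade into several and bias duration statistics, which is a
labelling artefact, not a duration error.

## Problem sizes and runtimes

The shipped test and acceptance configurations use the benchmark at
n = 500 with the full protocol (k = 2..12, three leave-out fractions at 50
positions, 12 restarts — about 22 000 Lloyd runs and 60 000 Hungarian
matchings, ~1.5 min) and 60 s of simulated flight at 1 ms (60 000 steps,
k = 9, ~30 s). Both were chosen as the smallest sizes at which the
selection behaviour and the recovery rates are stable across seeds.

## Known limitations

* Stability thresholds (`factor`, `abs_floor`) and the elbow factor are
  heuristics with documented defaults, not derived quantities; for new
  data types inspect the instability and quality curves rather than
  trusting the defaults.
* `match_distance()` requires equal cardinality; comparing clusterings
  with different k is done via the validation report, never by padding.
* The hierarchical pre-scan inherits hclust's tie-breaking; with
  continuous features ties have measure zero, but exactly duplicated
  points may order merges differently across platforms.
* Segmentation reports every label run, however short; an optional
  minimum-duration filter exists in the CLI (`--min-duration`) but is off
  by default, because very short runs are informative as classification
  uncertainty.

## A minimal session

```{r example, eval = FALSE}
gm <- gaussian_mixture(default_artificial_spec())
fit <- prototypes(gm$features, k_range = 2:12, seed = 1)   # scans, selects k
summary(fit)
plot(fit)                       # star plots of the prototypes
seg <- segment(fit)             # prototypical movements with durations
```
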