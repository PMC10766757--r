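---
title: "The Cognitive Tangram Solver: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Cognitive Tangram Solver: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctsolver)
```

## The problem

The Tangram asks a player to tile a silhouette exactly with seven pieces
(*tans*): two small triangles, one medium triangle, two big triangles, a
square and a parallelogram.  Solving it is sequential problem solving: each
placement changes the remaining free space, the sequence of steps is not
fixed, and people routinely run into dead ends and backtrack.  `ctsolver`
implements a hybrid model of this behaviour — a classical-vision front end
that proposes *action-options* from the silhouette's edges, and an
activation-based memory model that chooses among them — together with a
synthetic-participant generator and four evaluation methods for comparing
model runs against behavioural traces.

The cognitive hypotheses encoded in the model are:

* **best fit (affordance)**: regions whose edges closely match a piece's
  outline invite that placement, especially early;
* **unrecognized composition**: compositions of several pieces that jointly
  fit a region are often missed, producing a characteristic wrong placement
  of a single large piece;
* **unfeasible-region backtracking**: noticing a region that can host no
  remaining piece triggers removal of the pieces that caused it, in the
  order the problem was noticed;
* **piece backtracking**: when no option can be retrieved at all, the placed
  action with the weakest support in the training data is removed;
* **phases**: solutions split into a best-fit opening, an exploration phase
  (errors, random search, backtracking), and a best-fit closing phase.

## Geometry

The small triangle has legs of length 1, so the seven tans have total area 8
and each bundled silhouette has area exactly 8.  Rotations are multiples of
45 degrees; under these, every vertex stays in the ring
$\{a + b\sqrt{2} : a, b \in \mathbb{Q}\}$, so placements introduce no
trigonometric drift and equality tests are safe at a $10^{-9}$ tolerance.
A placement is *legal* when the placed polygon lies inside the silhouette
and overlaps every placed piece by at most $10^{-6}$ square units (the edge
matcher tolerates small corner intersections; the geometric screen removes
them).  Containment and overlap are computed exactly by Sutherland–Hodgman
clipping: every tan is convex, and clipping an arbitrary simple polygon
against a convex one is exact.

Anchor points ("grid locations") identify placements by the lower-left
corner of the placed piece's bounding box.  The natural lattice for
45-degree Tangram geometry, $\{a/2 + (b/2)\sqrt 2\}$ per axis, is dense in
the reals, so the package bounds the diagonal coefficient to
$b \in \{-1, 0, 1\}$: one $\sqrt 2/2$ offset in either direction, which
covers every placement the bundled puzzles and their 45-degree-rotated
pieces need while keeping anchors distinct by at least ~0.09 units.  Anchors
are numbered row-major from 1.

The original House and Monk study figures exist only as drawings, not
coordinates, so the two bundled silhouettes are package-defined figures
with hand-verified 7-placement solutions.  The Monk preserves the
behaviourally important structure: the modal wrong opening is a big triangle
at rotation 270 placed one unit above its correct anchor; once one correct
big triangle is also down, the remaining free space is a diagonal strip too
narrow for the square — an unfeasible region detected exactly by the
brute-force placement oracle.  Each puzzle also designates this placement as
the modal "unrecognized composition" error used by the synthetic generator.

The parallelogram is the only chiral piece; mirroring is enabled by default
(the physical piece can be flipped), and the canonical chirality was chosen
so both bundled solutions use the unmirrored piece — disabling mirroring
removes the flipped templates and placements but leaves the puzzles
solvable.

## Vision

The uncovered region (silhouette minus placed pieces) is binarized at a
configurable resolution (default 12 px/unit) and its morphological boundary
(dilation minus erosion, 3×3 cross) forms the edge image.  Samples are taken
just off the pixel centre, with distinct sub-pixel offsets per axis, so no
sample ever lies exactly on a horizontal, vertical or 45-degree edge; a
hole's raster therefore partitions cleanly against its placed neighbours,
and an exactly tan-congruent, grid-aligned hole matches its template with
SSD 0.

One edge template exists per (kind, rotation) pair — 8 rotations, ×2 for the
mirrored parallelogram; symmetric duplicates such as the square at 0 and 90
degrees are kept, not deduplicated.  Matching minimizes the sum of squared
differences over all window positions; up to **five** candidates per
template survive a non-maximum suppression of radius half the template's
larger dimension, with ties broken in scan order.  The SSD is normalized to
a similarity $s = 1 - \mathrm{ssd}/\mathrm{ssd}_{\max} \in [0,1]$, with
$\mathrm{ssd}_{\max}$ the number of set template pixels plus the maximum set
pixels in any window — an upper bound, so $s$ is conservative but strictly
decreasing in the SSD.

Candidate pixel locations are snapped to the anchor grid.  Because anchor
spacing (down to $1.5-\sqrt 2 \approx 0.086$ units) can be smaller than the
rasterization jitter (~1 pixel), blind nearest-anchor snapping can land a
true match on a neighbouring anchor; the package therefore prefers the
nearest anchor at which the placement is geometrically legal (within a
1.5-pixel radius) and falls back to the plain nearest anchor.  Candidates
snapping to the same placement are merged keeping the lower SSD.

Filtering applies two screens: the geometric screen (membership in the
brute-force legal-placement set) and the frequency screen (the placement
must have non-zero phase-conditioned frequency in the training data).  The
vision-only variant disables the frequency screen; survivors then carry
$f = 0$.

## Cognition

Each surviving option is scored

$$\mathrm{strength} = k_d\, f_{\mathrm{phase}} + k_{cv}\, s$$

where $f$ is the option's relative frequency in the training data at the
current solution phase and $s$ its visual similarity.  Three variants are
bundled; the weights are package defaults (the source studies chose them
empirically during training and did not print them):

| variant | strength | default |
|---|---|---|
| `vision` | $k_d f + k_{cv} s$ | $k_d = 0.2,\ k_{cv} = 0.8$, frequency screen off |
| `frequency` | $k_d f + k_{cv} s$ | $k_d = 0.8,\ k_{cv} = 0.2$ |
| `balanced` | $f\,(1 - \lambda (1 - s))$ | $\lambda = 0.5$ |

The balanced form implements "frequency penalized by the size of the
matching error" multiplicatively; an additive reading is already covered by
the linear form, so the multiplicative penalty is what distinguishes the
variant.

The **six** strongest options (ties: higher $f$, then lower grid location,
then lower rotation) form the context buffer — capacity near the 7 ± 2 span
of visual working memory, configurable.  Retrieval computes
$A = B + S + \varepsilon$ per chunk: base-level $B$ equals the strength,
spreading activation $S$ adds $W/|\mathrm{context}|$ when the chunk is in
the buffer (self-association only; the sources name the mechanism but give
no association matrix), and $\varepsilon$ is logistic noise with scale
0.25 by default, seeded.  The most active chunk above the threshold
$\tau = 0$ is retrieved and enters the recently-retrieved (finst) record
(span 4), which blocks immediate re-retrieval — this is what eventually
starves a looping region-backtrack and hands control to piece backtracking.
The option chunks are reloaded from the current extraction each step; only
the finst record persists.

Decisions: a flagged unfeasible region short-circuits retrieval (modelled as
an unfeasible-region chunk that always wins) and removes the head of the
problem queue — the placements tagged, in notice order, when the flag first
fired.  An exhausted queue with a persisting flag, or a retrieval failure,
triggers piece backtracking: the placed action with the lowest
phase-conditioned frequency is removed, most recent on ties.  The
coordinator tags the most recent placement when the flag first fires (the
model cannot see which earlier piece caused the region, only when the
problem was noticed).

Solution phases bin step indices; the defaults are phase 1 = steps 1–4 (the
opening analysed in the training data), phase 2 = steps 5–12 (up to the
rounded mean step count of observed solutions), phase 3 beyond, all
configurable.

## Simulator

`run_trial()` loops extraction → scoring → decision → state update until the
state is solved or `max_steps` (default 50, comfortably above observed mean
+ 1 SD step counts) is reached.  Placements bind to a concrete free piece
instance (never re-using a placed one) and removals return it; both count as
steps, matching participant logs that record piece actions.  All randomness
flows through the trial seed, so equal seeds give bit-identical traces.
`predict_next()` replays a trace prefix, reconstructing the bookkeeping
exactly — each replayed placement enters the finst record as a retrieval
would, and unfeasible tagging is re-derived from the replayed states — then
reports the model's next choice without committing it.  With noise off this
reproduces the simulator's own trace step for step.

## Synthetic participants

`synth_participants()` emulates the observed phase structure: with
probability `p_perfect` a minimal 7-step solution (pieces in area-descending
best-fit order, random shuffles within equal areas); otherwise a best-fit
opening that with probability `p_composition_error` is the puzzle's modal
composition error, a geometric-length exploration of random legal placements
and removals, removal of everything non-canonical (the "aha" moment) and a
best-fit completion.  Defaults: `p_perfect` 0.43 (House) and 0.27 (Monk),
the observed training-cohort perfect-strategy ratios; `p_composition_error`
0.5 (House) / 0.65 (Monk) and exploration rate 0.3 are package choices that
put mean trace lengths near the observed 11–13 steps with right-skewed
spread.  Every generated trace replays legally by construction.

The generator emulates *choice structure*, not perception or timing: it
does not model hovering, within-step re-planning, mouse trajectories or
response times, and its exploration is uniform over legal placements rather
than affordance-weighted.  Tests passing against synthetic cohorts therefore
certify the machinery (replayability, frequency/heatmap construction, rate
recovery), not fidelity to any real population.

## Evaluation

* **Overall statistics**: mean and sample SD of per-trace step counts, and
  the perfect-strategy ratio (solved in exactly 7 steps).
* **Heatmap RMSE**: per step $s$,
  $\mathrm{RMSE}_s = \sqrt{\sum_{p=1}^{5} (h_{p,s}^{\mathrm{model}} -
  h_{p,s}^{\mathrm{data}})^2 / 5}$ over the five piece kinds, averaged over
  steps.  The radical and the division by 5 sit inside the root, as the
  metric's name requires; a one-hot disagreement gives
  $\sqrt{2/5} \approx 0.6325$.
* **States plausibility**: a model state at step $s$ (state = sorted list of
  (kind, grid location, rotation), instance-agnostic) matches if some data
  trace shows the same signature at a step within $s \pm \mathrm{offset}(s)$.
  The offset grows with the step — default
  $\mathrm{offset}(s) = 1 + \lfloor (s-3)/4 \rfloor$, configurable — and the
  evaluated range is steps 3 through $\lceil \mathrm{mean} + 1\,\mathrm{SD}
  \rceil$ of the data cohort.  Identical model states are not deduplicated:
  each model state in range counts once.
* **Prediction accuracy**: for every prefix of every data trace the model
  proposes an action; a hit is the proposed (action, kind, grid location,
  rotation) occurring within the next **2** steps (strict orders are often
  arbitrary — e.g. square before parallelogram in a roof — so one step of
  slack is behaviourally meaningful).  Accuracy is monotone in the window.

## Numerical choices and test scales

Area tolerance $10^{-6}$; coordinate tolerance $10^{-9}$; vision default
12 px/unit (raster/geometry round trips within one pixel; anchors recovered
exactly via legality-aware snapping, stable under doubling).  Degenerate
inputs: an empty uncovered region rasterizes to a blank edge image;
templates larger than the image return no candidates; a blank edge image
scores every window at the template's set-pixel count and is removed by the
geometric screen downstream; a backtrack with nothing placed is a dead end
that aborts the trial as unsolved.

The shipped tests exercise: both bundled puzzles end-to-end (noise-free
minimal solutions, seeded noisy runs), vision soundness against the
brute-force oracle on 100 randomized partial states per puzzle plus
completeness on all 14 exact holes, generator rate recovery at 200 traces
per puzzle (3-binomial-SD bands), and the evaluation metrics against
hand-computed values.  These sizes were chosen to give tight sampling error
while keeping the whole suite in the low minutes on one core.

## Known limitations

* The bundled silhouettes are package-defined approximations; printed
  model-vs-participant scores from the original study depend on its
  31-participant training traces and are not reproducible here.
* The grid numbering of the transcribed study frequency table cannot be
  recovered from its source figure; the shipped index map is a labelled
  synthetic stand-in (the transcription itself is verbatim, including the
  modal-row discrepancy noted in the file).
* The model must complete an action before it can backtrack — no
  "imagining" — so error recoveries run longer than human ones.
* No base-level learning or decay, no utility learning, no motor or latency
  modelling: the model predicts choices, not response times.
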