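---
title: "Quantifying directional T cell migration along perivascular tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying directional T cell migration along perivascular tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perivax)
```

## The problem

Naive T cells recirculate through the spleen, an organ with open blood
circulation: cells released from arterioles into the red pulp must find their
way into the white-pulp T zone without the high-endothelial venules that
organize entry into lymph nodes. Intravital two-photon imaging shows that
instead of wandering freely, T cells latch onto perivascular stromal paths
("PT-tracks") that connect the red pulp and marginal zone to the T zone, and
migrate along them in a strongly one-directional manner toward the T zone.
Perturbations dissect the mechanism: CCR7 deficiency removes the directional
bias and bars T-zone entry, pertussis toxin arrests cells in the red pulp,
integrin (LFA-1/VLA-4) blockade halves migration speed, and LPS-driven
inflammation detaches cells from the tracks and depletes track-associated
density.

`perivax` implements the quantification pipeline for this kind of experiment —
per-track motility metrics, a binary toward/away-T-zone classifier, a
superpixel optical-flow collective-motion statistic projected on vessel axes,
and fixed-ROI density measurements — together with an agent-based synthetic
generator of calibrated time-lapse stacks. Because no imaging data were
deposited with the original study, the generator is the package's test bed:
its presets encode the qualitative effect structure above, and the analysis
modules are validated against simulation ground truth and against
independent numerical oracles.

## The migration model

The simulated field (default 1000 × 1000 µm at 2 µm/px) contains a central
T-zone disc (radius 150 µm) and `n_tracks` polyline tracks radiating from the
disc perimeter into the red pulp, each wrapped in a vessel mask of half-width
15 µm. Four behaviours reproduce the observed phenotypes:

* **track_guided** — latched to a track, stepping along it toward the T zone
  with probability `bias_q` per frame (default 0.95) and away otherwise.
  Each per-frame step has total length exactly `speed × Δt`, partitioned
  between a lateral innovation (sd `sigma_lateral`, default 2 µm, reflected
  at the track half-width) and the along-track arc component. This
  partitioning is deliberate: it makes the realized per-step displacement
  equal the programmed speed, so speeds measured from rendered images can be
  compared directly with cohort parameters (the package asserts recovery
  within 2%). On reaching the T-zone end a control cell continues as a
  T-zone walker; the distal end reflects.
* **tzone_walker** — a persistent random walk confined to the disc; the
  heading turns by a Gaussian with sd `(1 − persistence)·π` per step.
* **redpulp_arrested** — rounded and immotile (jitter sd 0.3 µm/frame), with
  rare fast linear displacements (rate 0.2/min at 300 µm/min) mimicking cells
  caught in blood flow.
* **flow_flyer** — very fast intravascular objects (600 µm/min) crossing the
  field in straight lines, reflecting at the edges.

An additional **isotropic** behaviour (track-confined, uniformly random step
direction) provides the null condition for directionality statistics.

Speeds are drawn per frame from a normal truncated at zero (control mean
10 µm/min, sd 2). The defaults are order-of-magnitude choices consistent with
interstitial lymphocyte motility in two-photon imaging; the source study
reports its in vivo speeds only graphically, so these are plausible settings,
not published values. The frame interval defaults to 20 s, within the
15–30 s acquisition range typical for such experiments.

Presets transform a cohort at onset: `ccr7_ko` sets `bias_q = 0.5` and
reflects cells at the track's T-zone end; `ptx` reassigns every transferred
cell to `redpulp_arrested`; `integrin_block` multiplies motile speed means by
0.5 exactly; `lps` sets `bias_q = 0.5` and detaches each track-guided cell
permanently with probability `detach_prob = 0.5`, arresting it in place. The
detachment draw is the first use of each cell's random substream, so
non-detached cells follow the same trajectory they would under control.

Randomness is organized as one substream per cell, seeded from the cohort
seed and the cell id, so enlarging a cohort never perturbs existing
trajectories and every table and stack is reproducible from its seed.

The simulation is two-dimensional. Real acquisitions are 50–110 µm z-stacks,
but every statistic implemented here operates on 2-D coordinates or single
projected planes, so a single plane is simulated; the slab depth re-enters
only in the density conversion (below).

## Rendering

Cells are drawn as isotropic Gaussian blobs (sd 2 px, peak 0.6) on a uniform
background (0.05) with additive Gaussian read noise (sd 0.02), clipped to
[0, 1] — a deliberately simple image model: no point-spread anisotropy,
photobleaching, or scattering. Consequently, detection tests here probe the
geometry of the pipeline (thresholding, labelling, centroids, linking), not
robustness to realistic microscopy artifacts, and results on real data will
depend on segmentation quality in ways the synthetic suite cannot certify.

## Track metrics

For each track of duration ≥ 10 min (the inclusion convention for tracked
cells): mean velocity = path length / duration, straightness = net
displacement / path length ∈ [0, 1]. These are the standard "track speed
mean" and "track straightness" conventions; the displacement curve plots
mean displacement against √time over all tracks and start offsets
(overlapping windows, for variance reduction), with the motility coefficient
as the through-origin least-squares slope. Cohort summaries average per
animal first and report across-animal mean, SD and SEM — one point per
mouse, matching how such data are plotted.

## Binary directionality

A track is classified by comparing its start and end distances to the T-zone
centre: toward if it ends more than ε = 5 µm (about one cell radius) nearer,
away if more than ε farther, otherwise excluded as a dead band. Tracks with
more than half their points within 20 µm of a vessel-branch junction are
excluded — behaviour at branch points is complex and crowded — as are tracks
shorter than 10 min. The per-animal fraction toward uses only classified
tracks in the denominator.

Two design choices were genuinely open. The distance reference could be the
T-zone centre or its boundary; for tracks outside the disc the two orderings
agree, and both are exposed (`reference = "center"` is the default). The
branch exclusion radius is not quantified in the source description; 20 µm
(about two cell diameters) is this package's documented choice, not a
published value.

## Superpixel flow statistic

The collective-motion readout partitions each frame into approximately
10,000 equal square superpixels (a 1000 × 1000 px frame gives exactly
10,000 of side 10 px; in general the side whose count is closest to the
target is chosen by enumeration, ties resolved toward the ideal side
√(H·W/target)). Superpixel centroids are advected frame-to-frame by the mean
dense optical flow over their current square footprint (bilinear sampling,
forward Euler, footprint rigid); centroids reaching the frame edge freeze
and are flagged. Each trajectory is summarized by its mean velocity vector
(net displacement over total time) and mean position.

Dense flow is computed by pyramidal iterative Lucas–Kanade (3 levels, 15 px
box window, 3 iterations per level, per-frame contrast normalization, 2 × 2
block-average pyramid, per-iteration updates clamped to the window radius).
The method contract — not the specific algorithm — is what downstream code
relies on: for rigid translations up to 5 px of textured scenes the mean
error stays below 0.2 px per component, and uniform frames are flagged
low-confidence.

Each vessel branch is oriented by the eigenvectors of the second central
image-moment matrix of its mask; the major axis is flipped where necessary
to point toward the T-zone centre, and the minor axis is fixed to the +90°
rotation of the major axis so that all branches share one handedness (the
original convention is unspecified; any fixed convention gives the same
projection statistic, which uses the major axis only). Masks with eigenvalue
ratio below 1.2 have no meaningful axis and are rejected. A superpixel
belongs to the branch whose mask contains its mean position (nearest branch
centroid on overlap); it counts as moving toward the T zone when its mean
velocity projects strictly positively on the branch axis — an exactly zero
projection has no directionality and is not counted. Under isotropic motion
the expected fraction is 0.5.

## Density and association

ROIs are frozen at the reference time and reused verbatim later. A 2-D count
is converted to cells/mm³ with volume = area × slab depth; the default slab
of 60 µm is the mid-range of typical imaging depths and is recorded in every
output. Boundary points count as inside; density change reports
density(t1)/density(t0) and percent loss per ROI, flagging ROIs empty at t0
as undefined. The track-association fraction is on-track / (on-track +
red-pulp), excluding cells in neither compartment (e.g. inside the T zone).

## Numerical choices

* **Perimeter and circularity.** Circularity is 4πA/P². P is estimated from
  the Moore-traced 8-connected boundary chain with the Vossepoel–Smeulders
  corner correction (0.980 per axial step, 1.406 per diagonal, −0.091 per
  corner) plus π·pixel_size for the half-pixel offset between the
  pixel-centre chain and the true mask edge. On discs this converges to 1
  from below (0.94 at r = 10 px, 0.995 at r = 100 px); a plain unit/√2 chain
  is available as `method = "chain"`. Single-pixel objects fall back to
  their crack perimeter. Shape tests use radii ≥ 10 px where the estimator's
  bias is within the stated tolerances.
* **Thresholding.** Otsu's criterion on the frame histogram by default; any
  monotone global threshold (via `threshold_quantile`) is acceptable, since
  the source workflow's exact threshold method is unstated.
* **Linking.** Greedy nearest-neighbour in ascending distance with a gate of
  `max_speed × elapsed time` (default 40 µm/min, about twice the fastest
  expected per-frame displacement) and gap bridging up to 1 frame. Greedy
  rather than globally optimal: synthetic densities are low and identity
  swaps are checked in tests. Touching cells are not split; quantitative
  image-loop tests use configurations whose blobs stay separated.
* **Degenerate inputs.** Empty frames yield empty detection sets (not
  errors); empty masks, zero-volume ROIs, texture-free flow inputs, and
  geometries that cannot fit the field raise typed errors; short tracks are
  excluded with a reason code rather than dropped silently.

## Problem sizes

The bundled checks run, by choice, at: 20 rendered seeds of 150 cells for
the flow-statistic null (1000 × 1000 px × 30 frames); 5 simulated animals ×
60 cells for the strong-bias fraction; 200 cells per cohort through the full
image loop for the integrin-block contrast; 20 ROIs × 60 cells for
detachment thinning; and 10⁴-cell cohorts for distributional invariants
(symmetry null, bias monotonicity, speed conservation). These sizes give
Monte-Carlo errors comfortably inside each stated tolerance.

## Limitations

The generator emulates compartment structure, directional bias, arrest,
detachment and speed effects — not 3-D geometry, realistic optics, cell
shape dynamics (cells are isotropic blobs, so rendered-image circularity is
uninformative about real cell rounding), crowding at branch points, or
blood-flow hydrodynamics. Passing tests therefore certify the analysis
pipeline's correctness on data satisfying its assumptions, and the effect
sizes recovered from presets are by construction; they are not evidence
about biology. The full published motion-sensing-superpixels feature set
(mesh strain, saliency) is out of scope; only the partition → flow →
advection → projection pipeline described above is implemented.
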