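---
title: "Growth, retraction and wire optimality in comb-like sensory dendrites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth, retraction and wire optimality in comb-like sensory dendrites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combgrow)
```

## The system and the questions

Class I ventral posterior dendritic arborisation (c1vpda) neurons of the
*Drosophila* larva sense body-wall contractions during crawling. Their
apical dendrite is a comb: a main branch (MB) runs dorsoventrally,
perpendicular to the direction of peristaltic contraction; long
second-order lateral branches run along the anteroposterior axis; short
higher-order branches sprout from the laterals with broadly distributed
orientations. During embryonic development the arbour first extends
exuberantly, then enters a retraction phase (~18.5–21.5 h after egg
laying, AEL) that removes a large share of the branches, and finally
stabilises before hatching.

`combgrow` implements the quantitative machinery for three linked
questions. Does the growing arbour respect wire-optimality constraints?
Does the retraction phase improve the arbour's mechanosensory layout, and
is it selective or random? And can the whole developmental trajectory be
reproduced by a stochastic growth model with timed random retraction?

All stages run on synthetic data with exact ground truth, so every
estimator in the package has a parameter-recovery test.

## Tree model and conventions

A reconstruction is a rooted geometric tree (`dtree`): node coordinates
in µm, radii, and one parent pointer per node. Trees are treated as
planar — `z` is carried but ignored in spanning areas, orientation
angles and growth simulations — matching the essentially two-dimensional
geometry of body-wall sensory dendrites; cable lengths use the full 3D
metric. Times are hours AEL throughout.

`resample_tree()` redistributes nodes evenly along every unbranched
section at a target spacing. Even (per-section uniform) subdivision was
chosen over fixed-step-with-remainder because it leaves no sub-spacing
stub internodes and makes a second resampling pass reproduce the same
nodes exactly on straight-sectioned cable; on curved cable a repeated
pass re-discretises chords and may move nodes by a fraction of the
spacing.

A *terminal branch* is the cable between a termination point and the
nearest branch point towards the root (for a branchless path, the whole
tree). Terminal branches are the unit of retraction, tracking and the
in-silico retraction schemes.

## Main-branch detection and orientation angles

`find_main_branch()` aligns a tree by a fixed-point iteration: rotate the
metric-longest root path vertical; find the nodes nearest the top-left
and top-right corners of the bounding box; take the deepest common
ancestor of those two nodes as the candidate MB tip; re-rotate and
repeat until the tip stabilises. Ties in the corner search resolve to the
lowest node index. The iteration can in principle oscillate between two
equally plausible tips on ambiguous morphologies; a revisited candidate
is then resolved deterministically towards the longer metric root path.
This keeps the procedure total without affecting clean comb-shaped
inputs, which converge in one or two iterations.

Per-segment orientation angles are measured against the MB axis and
folded into [0°, 90°] (`atan2(|dx|, |dy|)`): 90° means a segment along
the anteroposterior axis, 0° along the MB. Folding reflects that the
measurement is an orientation, not a direction — a segment and its
reverse, or a mirror image across the MB, are physically equivalent.
Zero-length segments propagate as missing values.

*Branch length order* (blo, `blo_decompose()`) orders branches by
recursive longest-path peeling: the metric-longest root-to-tip path of a
lateral subtree is order 1, the longest paths branching off an order-k
path are order k+1. Length ties break towards the lowest terminal node
index. Within a lateral subtree, blo 1 is a "second-order" branch
(sprouting directly from the MB) and blo ≥ 2 "higher-order". This
ordering differs from both topological branch order and Strahler order
and matches the traditional primary/secondary/tertiary reading of comb
morphologies.

## The 49 branching statistics

`compute_morphometrics()` returns 49 named statistics per tree: counts
and topological orders, Van Pelt partition asymmetry, cable length,
diameters and taper ratios, membrane surface and volume, isoneuronal
distances of terminals, Euclidean/path distances and compactness,
per-branch tortuosity, branching angles, spanning-field statistics
(area, cable density, space filling, bounding box), MB ratio, terminal
statistics, lateral-branch perpendicularity and length statistics,
diameter/length extremes, and the total length after rescaling the
spanning field to 100 µm². Statistics that are undefined for a topology
(e.g. the asymmetry spread of a tree with fewer than two branch points)
are `NA`, never an error.

Two implementation notes. The spanning area defaults to a tight concave
boundary (below); the convex hull is available everywhere as
`method = "convex"` and is what the scaling pipeline uses. The
space-filling statistic is implemented as coverage efficiency: the
fraction of mesh cells (default 1 µm) inside the tight boundary that
contain cable.

## Planar geometry

No installed geometry library provides Delaunay triangulations or
alpha-shape boundaries, so the package carries its own: an incremental
Bowyer–Watson triangulation (`delaunay2d()`) stabilised against the
exactly-collinear node runs of resampled cable by an infinitesimal
deterministic perturbation, and a circumradius-filtration boundary
(`tight_boundary()`). With shrink factor 1 the filtration threshold is
the smallest circumradius for which every point stays covered and the
kept triangles form one connected region — the tightest valid boundary;
shrink 0 keeps everything (the convex hull). Spanning-area calls thin
very dense node clouds to 1500 points before triangulating; the boundary
is insensitive to interior thinning at that resolution. Point-in-polygon
tests use an even–odd crossing rule with a small boundary tolerance so
nodes lying exactly on a contour edge count as inside.

## Wire-optimality scaling

For planar dendrites that minimise wiring, total length L, spanning area
S and branch-point count N satisfy

L ≈ sqrt(S · N / π).

`generate_mst_tree()` grows greedy minimum-spanning morphologies: targets
connect one at a time at the point of the existing cable minimising
`wire + bf × root-path` cost (bf = 0.2 throughout). Attachment considers
segment interiors, and an interior attachment splits the segment — each
interstitial connection creates one branch point, the mechanism behind
the square-root law. Ties break towards the lowest target index.
`mst_scaling_ensemble()` samples targets uniformly on a square of
100 µm² (root at the centre), records every intermediate tree up to 500
targets, rescales each recorded length to a common 100 µm² spanning
area (convex hull), and pools the (N, L) records. Steps with fewer than
two branch points are dropped — their spanning fields are essentially
one-dimensional and the area normalisation is degenerate. An ordinary
least-squares fit of L against sqrt(N) over this ensemble yields
R² ≈ 0.98.

The fitted slope is larger than the idealised prefactor
10/sqrt(π) ≈ 5.64: with N counted as branch points, any spanning
construction over n targets carries cable of at least the order of the
minimal spanning tree (≈ 0.66–0.69 · sqrt(nS)) while only a fraction of
attachments create branch points, which bounds the achievable slope away
from the idealised value. The law's square-root *form* — the linearity
of L in sqrt(N) — is the tested property.

## The bending-curvature model

The larval cuticle fold is approximated by a cylinder whose axis runs
dorsoventrally. A branch of length L_b oriented at angle θ to that axis
follows, when bent onto the cylinder, an elliptical profile with
semi-diameters a = L_b/(2π) and b = a/sin θ, approximated by a circular
arc of radius R_c = (a + b)/2. For a thin tube the second principal
curvature is unchanged by bending, so the first principal curvature
c₁ = 1/R_c carries the signal. Rescaling by the maximal value at
θ = π/2 gives

f(θ) = 2 · sin θ / (1 + sin θ),

independent of branch length and cylinder size, strictly increasing,
f(0) = 0 and f(π/2) = 1. The closed form is verified in the tests
against a numeric oracle that constructs the plane–cylinder intersection
curve, measures its semi-diameters by numerical optimisation and applies
the circular-arc approximation, agreeing to 10⁻⁹ across random angles
and sizes.

Per-branch curvature aggregates per-segment values by a
segment-length-weighted mean (invariant under resampling); the
unweighted mean and the median are also reported, since either reading
of the per-branch aggregate is defensible.

## Retraction schemes

Given a pre-retraction tree and a removal count (the branch-point
difference between the peak-complexity frame and the post-retraction
minimum, `plan_removal_count()`), `apply_retraction_scheme()` removes
terminal branches shortest-first, lowest-mean-angle-first, highest-blo
first, or uniformly at random (an ensemble). The terminal-branch set is
re-dissected after every removal, so cable exposed by a removal becomes
a longer terminal branch with an updated sort key; `static_list = TRUE`
reproduces the alternative single-sort behaviour. The MB tip is never
eligible: retraction acts on lateral branches. Sort ties keep the stable
tip order.

`scheme_comparison_study()` plants the ground truth itself — uniformly
random whole-branch retraction of half the terminals across eight
independent synthetic combs — and measures each scheme's 1-Wasserstein
distance to the target's per-branch mean-angle distribution pooled over
the series. Pooling matters: with per-series distances the sampling
noise floor of an empirical distribution distance (≈ σ/√m for m
branches) is comparable to the sorted schemes' biases, and the study
would have no power; pooling a few hundred branches puts the floor well
below the biases, and the random scheme, being the generating mechanism,
wins.

## Single-branch tracking

Branch correspondence across frames is an input (a registration table of
termination points and track ids), not something the package infers —
synthetic series carry exact correspondences, mirroring the manual
registration of real time-lapse data. Matched terminal branches are
classified by their length change against an optical-resolution
threshold (default 0.3 µm, roughly the lateral confocal resolution):
new, retracted, elongated, shortened, or stable. `dynamics_summary()`
bins events into right-closed 1-hour bins (default edges 17.5–21.5 h
AEL) and reports class fractions and mean extension/reduction rates.

## The growth model

`simulate_development()` iterates 15-minute steps from 16 to 22.5 h AEL
inside a fixed arena (an initial MB plus the tight contour of a
reference spanning field):

1. **Growth** (until 19.5 h when retraction is enabled; to 22.5 h
   otherwise): the contour is probed with `n_probe` uniform random
   points (100,000 at full scale); each probe's shortest distance to the
   tree is capped at the active growth radius; one target is selected
   with probability proportional to d^γ, γ = k/(1−k) (k = 0.5 → linear
   preference for far targets; k = 0 uniform; k → 1 greedy-farthest);
   the target is connected at the tree point minimising
   `wire + bf × root-path` cost, laying at most one growth radius of
   cable in the target's direction, never outside the contour. This
   repeats Poisson(b_r) times per step (deterministic rounding is a
   config flag).
2. **Retraction** (after the growth iterations of each whole hour from
   16.5 to 21.5): a per-bin fraction of terminal tips is selected
   uniformly and shortened by the bin's retraction length (branches not
   longer than that are removed entirely), then a per-bin fraction of
   new branches is added through the growth machinery. Fractions convert
   to counts by round-half-up with a minimum of one when positive.

Key parameters, all in `growth_params()`: growth radii 2.5 µm
(pre-19.5 h) and 1.81 µm (post) — the mean lengths of newly formed
branches in tracked data before and after the switch; bf = 0.2 as in the
MST analysis; k = 0.5. The default branch-addition rate b_r = 12 per
iteration reflects that an addition realises as either a new
interstitial branch or a tip elongation; with roughly a third of
additions creating a branch point, simulated trees reach the peak
branch-point counts (~50–60) of embryonic reconstructions by the end of
the extension phase. Candidate attachment points are the tree nodes at
the `attach_spacing` resolution, default 0.5 µm: one fifth of the growth
radius, at which the discretisation of attachment costs is negligible,
while keeping node counts (and the probe-distance kernel) an order of
magnitude smaller than a 0.1 µm discretisation would.

`extract_growth_parameters()` parameterises the model from tracked data
with no fitting: b_r as the combined rate of newly formed and elongating
branches per 15 minutes up to 19.5 h; per-bin shorten fractions as the
combined retracting + shortening class fractions; retraction lengths as
the mean lengths of retracted branches per bin; growth radii as the mean
lengths of new branches before/after the switch.

Two ensemble-level properties are validated. First, pure growth
(retraction disabled) across ten synthetic arenas satisfies the
wire-scaling law: pooled frames with at least 10 branch points — below
that the single polarised MB dominates and the spanning field is
degenerate — give an L-vs-sqrt(N) fit with R² ≥ 0.95
(`growth_scaling_ensemble()`). Second, simulations with retraction,
parameterised end-to-end from planted comb time-lapses, shift the pooled
median branch orientation angle upwards between the peak-complexity
frame and the end of development (`retraction_angle_shift()`): random
removal of a fixed cable length preferentially eliminates short,
flat-angle branches. The shift under synthetic conditions is small (of
order one degree) but consistently positive; its magnitude depends on
the balance between the composition effect (short low-angle branches
dying) and the counteracting re-measurement of trimmed survivors.

## Contraction and calcium kinematics

The body-wall contraction of a segment is tracked through three adjacent
somata: the raw signal is the summed distance from the central soma to
its anterior and posterior neighbours, affinely normalised per trial to
[0, 1] with 1 at maximal contraction. Fluorescence fold change is
ΔR/R₀ with R = F_green/F_red and R₀ the mean ratio over the first five
frames; the ratio cancels common-mode intensity changes, and frames with
zero red signal propagate as missing. `align_and_average()` shifts every
trial so maximal contraction sits at t = 0 (ties to the earliest frame),
normalises each trial's fold change by its positive maximum, and
averages where at least five trials contribute (configurable), reporting
the lag of the mean fold-change peak. The synthetic peristalsis
generator plants a Gaussian contraction pulse (FWHM ~1 s, frame interval
0.2 s), a one-frame fluorescence lag and a target Pearson coupling of
0.85, built by mixing the lagged contraction with calibrated Gaussian
noise.

## What the synthetic data do and do not show

The generators emulate the *statistics* the estimators measure: comb
geometry with planted branch lengths, orders and angles; time-lapse
series with planted per-transition event fractions and 2–3 µm/hr rates;
soma trajectories with planted lag and coupling. Branches selected for
reduction lose cable at the drawn rate, and whether that realises as a
shortened or a fully retracted branch depends on the branch's own
length — the mechanism by which a random reduction penalises short
branches. Planted events are placed so that no event alters the measured
length of any other terminal branch (removals that would merge cable
into a surviving terminal branch, or attachments inside another terminal
branch's path, are not selected; higher-order branches are generated in
pairs sharing an attachment node for the same reason). This keeps the
ground-truth event table exact and is why the tracking tests can demand
a perfectly diagonal confusion matrix.

Real reconstructions are messier in ways the generators deliberately do
not model: tracing noise and z-projection artefacts, registration
errors, merge/split ambiguities when sibling branches retract,
sub-hour dynamics invisible at the 1-hour cadence, and diameter
variation. Passing the recovery tests therefore shows the estimators are
correct under their stated measurement model, not that they are robust
to all failure modes of real imaging data.

Problem sizes in the test suite are scaled to keep the full run
comfortably reproducible: 100 MST simulations (the deposited analyses
used 1,000), 50 growth-model runs at 5,000 probe points, 2,000 null
simulations for the bootstrap calibration at n = 100 per group, and
3 × 8 simulations for the angle-shift study. These sizes are stated in
the validation functions' signatures and can be raised.

## Numerical choices and degenerate inputs

- SWC dialect: whitespace-separated, `#` comments, parent −1 for the
  root; exactly one root enforced; coordinates written with 17
  significant digits so round trips are bit-exact.
- Resampling a section shorter than the spacing collapses it to its
  endpoints (documented, not an error); zero-length segments elsewhere
  propagate as missing angles.
- All sort and selection ties break deterministically (lowest node,
  target or terminal index) so seeded runs are bit-reproducible.
- The bootstrap null is pooled resampling with sizes preserved,
  two-sided, add-one-corrected, default 10,000 resamples; two constant
  identical samples return p = 1. Pooled bootstrap tests of medians run
  slightly conservative (empirical size ≈ 0.035–0.045 at nominal 0.05).
- `bootstrap_median_test()` computes null medians as order statistics of
  integer draws into the sorted pool (one radix sort per resample
  matrix), which keeps large calibration studies tractable.
- Fractions-to-counts conversions in the growth model round half up,
  with a minimum of one branch whenever the fraction is positive and
  terminals exist.

## Known limitations

- The concave boundary uses a circumradius filtration with a
  connectedness/coverage criterion; boundaries with pinch points are
  resolved by taking the largest closed loop, which can very slightly
  underestimate areas of strongly non-convex fields.
- The MB alignment assumes a discernible longest path; radially
  symmetric arbours (not the target morphology) would resolve through
  the deterministic tie rules rather than a meaningful MB.
- The growth model treats the arena contour as static; real spanning
  fields expand during the extension phase.
- Post-hatching isometric stretching is analysed through morphometrics
  only; it is not simulated.
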