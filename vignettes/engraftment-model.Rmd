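---
title: "Modeling cell engraftment on decellularized scaffolds and quantifying spatial clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cell engraftment on decellularized scaffolds and quantifying spatial clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recell)
```

## The scientific problem

Seeding decellularized lung scaffolds with cells (mesenchymal stromal cells,
alveolar epithelial lines) is a candidate route to regenerated tissue, but
engraftment is transient and its spatial dynamics are hard to interrogate
experimentally. `recell` implements a deliberately simple agent-based model
of the first weeks after seeding — attachment, chemotactic wandering,
substrate-modulated death and proliferation on a cubic scaffold lattice —
together with the image-analysis machinery needed to compare simulated and
experimental slice images on equal terms: nucleus detection by dual
thresholding, bounded Voronoi tessellation of the detected nuclei, and a
cell-count-corrected clustering statistic (CVHV). The package's purpose is
hypothesis discrimination: competing behavioral rule sets are simulated,
summarized with the same metrics applied to micrographs, and compared
statistically.

## The environment

The scaffold is a cube of $32^3$ unit patches. Patch coordinates are the
integers $-16,\dots,15$ per axis: the published description gives 32 patches
per axis yet an axis range of $-16$ to $16$, which cannot both hold for
integer coordinates; we keep the patch count (it fixes the population
density that all downstream numbers depend on) and accept the one-unit
asymmetry of the coordinate range. Each patch carries a substrate
concentration, initialized to the radial field

$$ c(x, y, z) \;=\; \frac{20\sqrt{x^2+y^2}}{21.2}, $$

which is zero on the central axis of every $x$–$y$ plane and maximal at the
in-plane corners; it has no $z$ dependence. The substrate is deliberately
generic (oxygen and matrix components are candidates); only its gradient
matters to the model. A patch holds at most one cell. The lattice border is
the scaffold edge — there is no wraparound, so corner patches have 7
neighbors, face patches 17, and interior patches the full 26 (Chebyshev
distance 1).

Engrafted cells feed back on the field: engraftment deposits `c_amount`
(default 1) on the cell's patch and death removes the same amount, floored
at zero because concentrations are physical quantities. The deposit is
applied once per engraftment event; a per-step accumulation variant is
available as `substrate_deposit_mode = "per_step"` for exploration.

## The behavioral rules

Each agent acts once per time step, in a freshly randomized agent order
(sequential updating, matching how agent platforms schedule concurrent
agents without write conflicts). A motile cell:

1. **moves**: it draws a fresh uniformly random 3D heading, quantized to the
   nearest of the 26 lattice directions; the "ahead-left" and "ahead-right"
   companions are obtained by rotating the heading $\pm 45^\circ$ about the
   axis perpendicular to it (within the plane of the heading and a fixed
   up-reference) and re-quantizing. Because the heading is free in 3D, the
   three "ahead" patches can lie above or below the cell. With
   $x_i \sim U[0,1]$ independent, the signal
   $S = x_1 c_\text{ahead} + x_2 c_\text{left} + x_3 c_\text{right}$
   determines the move: if $S > 1$ the cell moves to the unoccupied ahead
   patch with the largest concentration; otherwise to a uniformly random
   unoccupied neighbor. $S = 1$ (a measure-zero tie) follows the random
   branch. A cell whose candidate patches are all occupied or out of bounds
   stays put.
2. **attaches**: a draw $N \sim U[0,100]$ engrafts the cell when
   $N > N_\text{crit}$ (default 5, i.e. 95% per attempt).

An engrafted cell is immobile and carries a lifespan $T_\text{life}$ and a
proliferation delay $T_\text{prol}$ (time steps), with running counters
incremented every step:

3. **death**: when the age counter reaches $T_\text{life}$ the cell is
   removed and its substrate deposit decays.
4. **proliferation**: when the delay counter reaches $T_\text{prol}$ the
   cell places one copy on a uniformly chosen unoccupied neighbor patch
   that itself has at most 6 occupied neighbors (crowding limit). If no
   eligible patch exists the attempt is deferred — the counter holds and
   the cell retries each step, rather than resetting, so crowding does not
   penalize proliferation odds twice. After a successful division the
   counter restarts from zero.

### The two rule sets

Both shipped rule sets share everything except the four lifespan /
proliferation specifications:

| draw | `hypothesis1()` | `hypothesis2()` |
|---|---|---|
| initial $T_\text{life}$ | $U[0, 36]$ | $U[0, 45]$ |
| initial $T_\text{prol}$ | $U[33, 87]$ | $U[41, 103]$ |
| offspring $T_\text{life}$ | $U[0, 18]$ | $c_\text{patch}/1.9 + U[0, 45]$ |
| offspring $T_\text{prol}$ | $(33 - c_\text{patch}/1.9) + U[0, 54]$ | $U[41, 103]$ |

Rule set 1 encodes short-lived cells that proliferate sooner where substrate
is abundant (the mesenchymal-stromal-cell hypothesis); rule set 2 encodes
longer-lived cells that survive longer where substrate is abundant (the
epithelial-cell hypothesis).

### Draw conventions

Counters are integers incremented by one, so draws are integers, uniform on
the inclusive integer lattice of the stated interval. Death and
proliferation trigger on *counter $\ge$ threshold* (evaluated after the
increment) rather than strict equality: with equality, a drawn threshold of
0 would never fire for a counter that starts at 0 and first reaches 1,
accidentally creating immortal cells out of the smallest draws. Under the
$\ge$ rule, thresholds of 0 and 1 both fire at the first step, which is the
intended "some cells die before they can proliferate" behavior. The
environment-coupled formulas can go negative at high concentration; those
values are floored at 1 for the same reason. Uniform draws are returned
unfloored (their distribution is the stated one; a drawn 0 behaves exactly
like a 1).

### Seeding

At $t = 0$, 30 000 agents are placed on distinct uniformly random patches
and each attaches with probability 0.95. The default
`seeding_mode = "instant_cull"` eliminates the non-attachers immediately —
the literal reading of the published protocol ("the remaining cells being
eliminated"). The alternative reading, under which non-attachers stay
motile for one full step (moving and re-attempting attachment) before
elimination, is available as `"one_step_grace"`; it yields step-10
populations about 5% larger. Under the default, motile-cell rules 1–2 are
exercised only when `engraft_prob < 1` with grace seeding, and by the unit
tests.

## Physical calibration

Simulation units map onto physical scales through
`calibrate_time_scale()`: a 32-patch slice spanning roughly 1000 µm gives
~31 µm patches, and 80 steps spanning 28 days give a step rate of ~0.002
steps/min, so one patch-per-step of motion corresponds to ~0.06 µm/min —
the order of magnitude of observed cell crawling on scaffolds.

## Slice recording and the CVHV

Every 10 steps the engine records the 30 interior $z$-planes
($z = -15,\dots,14$; fixed across runs for reproducibility): the engrafted
count per slice, and the slice's CVHV. The CVHV of a point set in a
rectangle is

$$ \mathrm{CVHV} \;=\; n \cdot \mathrm{Var}(A_1, \dots, A_n), $$

where $A_i$ are the areas of the Voronoi tiles clipped to the rectangle.
The multiplication by $n$ corrects the mechanical shrinkage of tile-area
variance when more cells share a fixed field of view, making the statistic
a count-corrected measure of clustering heterogeneity: tight clumps
coexisting with empty territory give large CVHV, spatially regular or
homogeneously random arrangements give small CVHV.

Numerical conventions, where the published description leaves slack:

* *Variance convention.* "Variance of the histogram of tile areas" is read
  as the sample variance (denominator $n-1$) of the tile-area values
  themselves. A variance of binned frequencies would depend on bin widths
  that are nowhere specified.
* *Unbounded tiles.* Exterior Voronoi cells are clipped to the image
  rectangle (each point's territory is finite and the areas sum exactly to
  the rectangle area). The tessellation is computed by half-plane clipping:
  each tile starts as the rectangle and is cut by the perpendicular
  bisectors against other sites, visited nearest-first with an early stop
  once no remaining bisector can reach the tile. Unit tests cross-check the
  areas against an independent nearest-site grid oracle and against
  `deldir`'s bounded tessellation.
* *Degenerate slices.* A slice with fewer than two cells has no defined
  tile-area variance; slice-level records carry `NA` and the low-level
  `cvhv()` refuses such input. For population-level mean trajectories the
  convention `summarize_trajectory(cvhv_na = "zero")` counts such slices as
  zero clustering heterogeneity — near extinction a series would otherwise
  terminate in `NA` and late-time comparisons would be impossible.
* *Duplicate points* are merged with a warning before tessellating.

Model slices can be analyzed two ways: directly on patch coordinates
(`analyze_slice_points()`, areas in patch²) or rendered to an image with
`render_slice()` and pushed through the detection pipeline like a
micrograph; the two routes agree to within the centroid quantization error
(about 10% on CVHV at 8 px/patch).

## The image pipeline

`analyze_image()` composes the eight-step micrograph algorithm: grayscale
conversion (luminance weights), mask detection, dual-threshold nucleus
detection, optional programmatic centroid edits, counting, tessellation,
CVHV. Decisions worth recording:

* *Threshold polarity.* Foreground is intensity *below* threshold:
  hematoxylin renders nuclei dark on a light background. The in-mask
  re-detection at the stricter threshold 85 then picks out the darkest
  sub-objects inside dense clumps (whose body intensity sits between 85 and
  125).
* *Sizes.* Mask regions are dark components of ≥ 300 px; nuclei are dark
  components of ≤ 20 px. Objects between the two limits (debris) are
  deliberately invisible to both rules.
* *Connectivity.* Components use 8-connectivity by default, switchable to 4.
* *Manual editing* is reproducible and logged (`edit_centroids()`) rather
  than interactive: additions are appended, removals delete the nearest
  centroid within a tolerance and fail loudly when nothing is near.

## Synthetic fixtures

`generate_micrograph()` builds test images with exactly known ground truth:
dark nucleus discs (radius 2 px → 13 px, under the 20-px ceiling), large
clump discs (radius 12 px → ~440 px, over the 300-px floor) containing
darker sub-nuclei, and mid-sized debris. Default intensities (background
230, nuclei 60, clump body 110) straddle the two thresholds so both
detection branches are exercised. The generator emulates the geometry and
contrast structure of stained-slice images, not their appearance: there is
no stain texture, no uneven illumination, no out-of-focus blur, and at most
additive Gaussian intensity noise. Passing detection tests on these
fixtures therefore demonstrates correctness of the component logic
(thresholds, size filters, mask routing, centroid accuracy), not
performance on real histology.

`generate_point_pattern()` provides uniform and clustered point sets
(uniform cluster centers, Gaussian members, out-of-window members redrawn
rather than clamped — clamping piles duplicates onto the boundary) for
exercising the CVHV contrast between clumped and dispersed arrangements.

## Statistics

Trajectories are normalized per replicate to their first recorded time
point (percent scale, first value 100) before comparison, matching how such
series are presented. `compare_hypotheses()` fits a fixed-effects two-way
ANOVA (factors: rule set and time) on the per-replicate slice means with
type-II sums of squares (`car::Anova`) and reports the group main effect as
the headline; no interaction term is reported because the comparison is
summarized by a single p-value. `sensitivity_analysis()` implements the
±5% protocol: each parameter in turn is scaled by $1 \pm 0.05$ at the start
of the simulation — interval parameters scale both endpoints (and the
deterministic part of an environment-coupled formula), the only reading
that preserves the interval's shape — and the CVHV at the probe step
(40 for the short-lived rule set, 50 for the long-lived one, where the
populations are collapsing and parameter changes have had time to act) is
compared to the unperturbed control by one-way ANOVA at $\alpha = 0.05$. No
multiple-testing adjustment is applied across the sensitivity table,
matching the protocol being reproduced.

## Problem sizes and reproducibility

All randomness flows through R's RNG: `simulate_engraftment(seed = )` makes
a run bit-reproducible, and `simulate_replicates()` derives per-replicate
seeds from one master seed. The test suite runs the full study conditions —
30 000 seeded cells on the $32^3$ lattice, 80 steps — with 30 replicates
per rule set for the trajectory comparisons; the sensitivity protocol is
repeated 5 times per rule set with 15 replicates per condition, a size at
which the lifespan/delay effects are decisively powered while keeping the
whole suite within a few minutes; survival-law calibration uses 30
replicates of 5 000-cell cohorts (survival is per-cell independent, so the
cohort size only sets Monte-Carlo resolution).

## Known limitations

* The model stops at attachment, movement, death and proliferation:
  no differentiation, no detachment of engrafted cells, no mechanical or
  fluid coupling, and a single linear substrate gradient standing in for a
  chemically heterogeneous scaffold.
* The lattice geometry is a fixed cube; image-derived scaffold geometries
  are out of scope.
* Experimental CVHV magnitudes depend on pixel dimensions of the acquiring
  microscope; only normalized trajectories and qualitative shapes are
  comparable across setups, which is how the package presents them.
* The "ahead-left/right" geometry of lattice movement is one faithful
  quantization of a cone-of-vision rule that has no unique lattice
  counterpart; it only influences runs with motile cells (grace seeding).
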