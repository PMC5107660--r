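# recell

Agent-based simulation of cell engraftment on decellularized lung
scaffolds, and Voronoi-based quantification of cell clustering in
micrograph-like images.

Recellularizing a decellularized scaffold — seeding it with stem or
epithelial cells in the hope that tissue regrows — is still largely
empirical, with few predictive tools. `recell` is for researchers who want
to test *rules of cell behavior* against slice-image data: it simulates
competing behavioral hypotheses on a 3D scaffold lattice, measures the
simulated slices with the same image metrics used on experimental
micrographs, and discriminates the hypotheses statistically.

## The model

The scaffold is a cube of 32³ unit patches carrying a radial substrate
field

&nbsp;&nbsp;&nbsp;&nbsp; *c*(x, y, z) = 20·√(x² + y²) / 21.2,

lowest at the center of each plane, highest at the border. 30 000 agents
are seeded at random; each attaches with probability 0.95 (a uniform draw
*N* ∈ [0, 100] above *N*<sub>crit</sub> = 5). Engrafted cells are immobile,
deposit one unit of substrate, and carry a drawn lifespan *T*<sub>life</sub>
and proliferation delay *T*<sub>prol</sub>; counters tick once per step,
death removes the cell (and its deposit), and proliferation places one copy
on an uncrowded neighboring patch. Two shipped rule sets differ only in the
lifespan/delay draws:

* `hypothesis1()` — short-lived cells (*T*<sub>life</sub> ~ U[0, 36]) whose
  offspring proliferate sooner at high substrate:
  *T*<sub>prol</sub> = (33 − *c*/1.9) + U[0, 54];
* `hypothesis2()` — longer-lived cells (*T*<sub>life</sub> ~ U[0, 45]) whose
  offspring survive longer at high substrate:
  *T*<sub>life</sub> = *c*/1.9 + U[0, 45].

Recorded 2D slices are summarized by cell count and by the **CVHV**
(corrected Voronoi histogram variance): tessellate the slice by the nuclei,
clip the tiles to the image rectangle, and report
*n* · Var(tile areas) — a cell-count-corrected measure of clustering
heterogeneity. The same statistic is computed from images via an 8-step
pipeline (grayscale → dual-threshold nucleus detection with 300-px masks
and 20-px nuclei → logged programmatic edits → Voronoi → CVHV).

## Worked example

```r
library(recell)

calibrate_time_scale(32, 1000, 80, 28)
#>   patch_size_um step_rate_per_min velocity_um_per_min
#> 1          31.2           0.00198              0.0620

tr1 <- simulate_replicates(hypothesis1(), replicates = 5, seed = 1)
tr2 <- simulate_replicates(hypothesis2(), replicates = 5, seed = 2)
s <- summarize_trajectory(rbind(tr1, tr2), cvhv_na = "zero")
s[s$time_step %in% c(10, 40, 80), ]
#>    hypothesis time_step mean_n_cells se_n_cells mean_cvhv   se_cvhv
#>  hypothesis1        10     624.3533    1.28513     172.4     1.571
#>  hypothesis1        40       1.6533    0.10660   66238.4 11010.905
#>  hypothesis1        80       0.0000    0.00000       0.0     0.000
#>  hypothesis2        10     675.7467    1.11288     137.2     1.068
#>  hypothesis2        40      95.6867    0.67775    3139.4    69.363
#>  hypothesis2        80       0.9467    0.07902   29755.4  8272.623
```

Each row is the mean over 30 recorded z-slices and 5 replicate runs. Both
populations collapse (most cells are dead well before step 80), but they
collapse differently: the short-lived rule set is nearly extinct by step
40, while the long-lived one keeps a persistent, strongly clustered tail —
its CVHV at step 80 is still ~200× the step-10 value. The count
trajectories separate the two rule sets decisively:

```r
cmp <- compare_hypotheses(rbind(tr1, tr2))
cmp
#> <hypothesis_comparison> response: n_cells (normalized to first time point)
#>   group effect: F = 40.747, p = 1.55e-08
```

The image pipeline runs on anything 8-bit grayscale; here, a synthetic
micrograph with known ground truth (40 isolated nuclei plus one clump
containing 3):

```r
fx <- generate_micrograph(micrograph_spec(n_nuclei = 40, n_clumps = 1,
                                          clump_nuclei = 3, seed = 7))
analyze_image(fx$image)
#>   n_cells n_masks area_variance     cvhv
#> 1      43       1       391495. 16834273.
```

All 43 placed nuclei are recovered (the clump is handled by the stricter
in-mask threshold), and the CVHV is their count-corrected tile-area
variance in px⁴. `autoplot()` methods display trajectories, tessellations
and sensitivity reports; `exec/recell` exposes `simulate`, `analyze-image`,
`make-fixtures` and `sensitivity` subcommands for shell use.

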