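---
title: "Quantifying treatment response in angiograms by globally optimal intensity clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying treatment response in angiograms by globally optimal intensity clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Digital subtraction angiography (DSA) is the reference modality for judging
whether an intracranial aneurysm has been excluded from the circulation
after clipping or coiling, but routine reading is visual and qualitative.
`dsaclust` makes the comparison quantitative: each 8-bit grayscale frame is
segmented into four intensity clusters — background, low, medium and high —
and treatment response is read out as the redistribution of pixels among
those clusters between the pre- and post-treatment frames. A successfully
occluded aneurysm stops filling with contrast, so its pixels migrate from
the high-intensity cluster into the background cluster.

Segmentation is one-dimensional k-means on intensity: given a frame's
normalized intensities $x_p \in [0,1]$, find centers
$c_1 \le c_2 \le c_3 \le c_4$ minimizing the within-cluster sum of squares

$$W(c) \;=\; \sum_p \min_{j} \,(x_p - c_j)^2 .$$

Two design commitments follow from the method this package implements:

* **Global optimization, not a heuristic.** $W$ has many local minima;
  Lloyd iterations from an arbitrary start can converge to any of them. The
  package minimizes $W$ with a dividing-rectangles (DIRECT) global search
  over the center cube $[0,1]^4$, exploiting the permutation symmetry of
  $W$: only rectangles intersecting the sorted simplex
  $\{c : c_1 \le \dots \le c_4\}$ are retained (an intersection test by a
  greedy witness, never a clipping). An exact dynamic-programming solver for
  1-D k-means ships alongside as an independent oracle, and the test suite
  requires the optimizer to match it to a relative $10^{-6}$ on hundreds of
  random histograms.
* **Per-image centers.** Centers are estimated independently for every
  frame. Cluster semantics are therefore *relative to each frame's own
  intensity distribution*; this keeps the method free of manual thresholds
  but means a cluster index is not an absolute calibrated intensity. This
  caveat matters when interpreting between-frame count differences and is
  repeated in the README.

### Exact histogram reformulation

An 8-bit frame takes at most 256 distinct values, so
$W(c) = \sum_b w_b \min_j (v_b - c_j)^2$ over the intensity histogram
$(v_b, w_b)$ — identical to the per-pixel objective, evaluated at a few
hundred terms instead of tens of thousands of pixels. This is an exact
reformulation, not an approximation, and is what makes a desk-scale global
optimizer honest.

### The optimizer in detail

The search follows the classical DIRECT scheme: the unit cube is trisected
recursively; at each iteration the *potentially optimal* rectangles — the
lower-right convex hull of (diameter, objective) points, with slack
`epsilon` — are selected and trisected along their maximal sides, sampling
center ± side/3. Ties are broken everywhere by rectangle creation order, so
the optimizer is fully deterministic and uses no random stream.
Symmetric-infeasible children are pruned at creation.

Termination: an evaluation budget (`max_evals`, default 10 000) or all
rectangle diameters below `diameter_tol` (default $10^{-6}$). The incumbent
is then *refined*: the best evaluated point plus a small, diversity-filtered
elite of low-objective rectangle centers are each polished with Lloyd
iterations followed by a one-dimensional boundary polish (optimal 1-D
clusters are contiguous, so the partition is described by three split
points; each split is moved one histogram bin at a time while the objective
improves). The boundary polish is what closes the last gap between a Lloyd
fixed point and the true optimum when a single bin sits on the wrong side
of a cluster boundary; with it, the optimizer reproduces the
dynamic-programming optimum to machine precision on every random histogram
in the test suite. Polishing a *set* of elite starts rather than the single
incumbent is a deliberate design choice: on rough histograms the incumbent
basin occasionally neighbors a slightly better one, and the extra Lloyd
runs cost microseconds.

Degenerate inputs (fewer distinct values than clusters) return the values
themselves padded with the largest, a zero objective, and a warning — the
downstream counting invariants still hold.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `gaussian_sigma` | 1.0 | px | tames sensor noise before rank filtering; 0 disables |
| `median_radius` | 1 | px | removes impulse artifacts (window side $2r+1$) |
| `clip_percentiles` | (0.5, 99.5) | % | robust normalization anchors; outliers clipped |
| `polarity` | `vessels_bright` | — | conventional DSA display renders vessels dark; raw exports vary, so polarity is explicit rather than guessed |
| `downsample_factor` | 1 | — | block-mean pooling for figure preparation only; the quantitative path never downsamples |
| `epsilon` | $10^{-4}$ | — | standard potential-optimality slack from the DIRECT literature |
| `max_evals` | 10 000 | evals | evaluation budget; ample for a 4-D cube over a 256-bin histogram |
| `diameter_tol` | $10^{-6}$ | — | termination diameter |
| `lloyd_refine` | `TRUE` | — | refinement stage described above |
| `alpha`, `alpha_norm` | 0.05 | — | significance level and Shapiro–Wilk gate for test selection |

Filtering order is fixed as Gaussian → median, recorded in the normalized
image's provenance attribute; rounding back to integers is plain half-up.
Neither choice is consequential at the default strengths, but both are
stated so results are auditable.

## Statistics

Within each arm, per-cluster pre/post pairs are compared with a
distribution-gated paired test: Shapiro–Wilk on the differences at
`alpha_norm`, then paired Student's t (normal) or Wilcoxon signed-rank
(otherwise). Between arms, post-treatment counts (and per-patient percent
changes) are compared with pooled-variance Student's t or Mann–Whitney U
under the same gate. The Wilcoxon and Mann–Whitney implementations follow
explicit small-sample contracts: zero differences dropped, tied ranks
averaged, and *exact* two-sided p-values by full enumeration (sign
assignments up to $n = 25$; group labelings up to $n_1+n_2 = 20$ without
ties), with tie- and continuity-corrected normal approximations beyond. The
test suite checks the exact and approximate branches against each other at
the crossover sizes and calibrates the full gated pipeline's type-I error
under a simulated null.

Cohort percent change is the **mean of per-patient percent changes**, not
the percent change of group means — the two differ, and the per-patient
form matches how such percentages are conventionally reported alongside
group means. No multiple-testing correction is applied by default (reports
carry raw per-cluster p-values); a Holm adjustment is available behind a
flag.

Inter-rater agreement uses Cohen's κ with marginal-product expected
agreement. The same statistic doubles as an automated quality measure:
agreement between pipeline labels and phantom ground truth.

## The synthetic phantom

No patient images ship with the package; every pipeline stage is exercised
on synthetic matched pairs with known ground truth. A phantom frame is a
noisy background at a planted background mode, a vessel tree (random-walk
polylines dilated to width) at the high mode, a one-pixel medium-intensity
halo hugging the vessels, low-mode parenchymal speckle, and a compact
elliptical aneurysm at the high mode. The post frame shares the geometry
exactly; the aneurysm (outside the vessel lumen) reverts to background
(complete occlusion) or keeps a concentric residual core of a chosen area
fraction. Defaults: 96 × 96 px, modes (30, 90, 160, 230) of 255, noise SD 8,
three branches of width 2–4 px, 10% speckle, aneurysm radii 9 px
(≈ 250 px² area). Cohorts jitter these per patient from seeded streams
split by patient index, so generation is reproducible and
order-independent.

What the phantom deliberately does *not* model: contrast transport and
temporal dynamics, projection geometry, clip metal artifacts, and — most
importantly — real angiograms have no guarantee of four well-separated
intensity modes. Passing phantom tests therefore demonstrates that the
*algorithmic chain* is correct (segmentation recovers planted structure,
readouts point the right way, statistics are calibrated), not that four
clusters are the right description of any particular clinical image.

## Numerical choices and degenerate inputs

* Assignment ties (a pixel exactly midway between adjacent centers) go to
  the lower cluster — conservative for the headline background-increase
  readout.
* A constant frame cannot be normalized (clip levels coincide) and is
  rejected as a degenerate intensity range; in cohort runs such frames are
  recorded under `failures` and the run continues.
* Percent change with a zero pre-treatment count is reported as undefined,
  never infinite.
* Frame aggregation (arithmetic mean of per-cluster counts) requires equal
  pixel totals across a patient's frames, which the manifest loader
  enforces per projection; a standardized acquisition protocol with a fixed
  crop window makes this the natural contract.
* All outputs are timestamp-free and carry an MD5 hash of the
  configuration, so repeated runs are byte-identical and mixed-provenance
  outputs are detectable.

## Problem sizes in the test suite

The suite verifies optimizer exactness on 200 random histograms (≤ 256
bins), pruning soundness on 1 000 random rectangles, mode recovery on 100
phantom seeds at noise SD 10, directional readout on 50 complete-occlusion
pairs, type-I calibration on 2 000 simulated null cohorts of 30 pairs, and
a power study of 200 two-arm cohorts (30 patients per arm, 64 × 64 frames,
50% residual occlusion planted in one arm). These sizes were chosen to make
the Monte-Carlo acceptance bands tight enough to be meaningful while
keeping the default test run at desk scale.

## Known limitations

* Clustering is over grayscale intensity only; no spatial term enters the
  objective. "Spatial balance" of clusters is not defined by the method and
  is not invented here.
* Four clusters are fixed in the pipeline (the library's optimizer and
  oracle support generic k for testing).
* Static 2-D frames only; no temporal or 3-D quantification.
* Per-image centers mean cluster counts are comparable between matched
  frames only to the extent acquisition was standardized — the same caveat
  that applies to the underlying clinical protocol.
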