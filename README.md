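# dsaclust

Quantitative cluster analysis of digital subtraction angiography (DSA)
images for objective assessment of aneurysm treatment response.

## What it does and for whom

After an intracranial aneurysm is treated — by microsurgical clipping or by
endovascular embolization — follow-up DSA shows whether the aneurysm still
fills with contrast. That reading is usually visual and qualitative.
`dsaclust` is for imaging researchers who want the comparison to be
numeric and reproducible: it segments each 8-bit grayscale frame into four
intensity clusters (1 = background, 2 = low, 3 = medium, 4 = high) and
quantifies treatment response as the redistribution of pixels among
clusters between matched pre- and post-treatment frames. An occluded
aneurysm stops filling, so its pixels move from the high-intensity cluster
into the background cluster — a rise in cluster 1 and a fall in cluster 4
is the signature of successful exclusion.

## The method

Segmentation is globally optimal 1-D k-means on intensity. For a frame's
normalized intensities, the package minimizes the within-cluster sum of
squares

    W(c) = Σ_b  w_b · min_j (v_b − c_j)²,   c_1 ≤ c_2 ≤ c_3 ≤ c_4,

over the frame's intensity histogram (v_b, w_b) — exactly equivalent to the
per-pixel objective for 8-bit data. The minimizer is a symmetric
dividing-rectangles (DIRECT) global search: the center cube [0,1]⁴ is
trisected recursively, "potentially optimal" rectangles (the lower-right
convex hull in diameter–objective space) are refined first, and rectangles
that cannot contain a sorted center vector are pruned. A deterministic
refinement stage (Lloyd iterations plus a boundary polish over histogram
bins) finishes the job; an exact dynamic-programming 1-D k-means oracle is
included and the test suite requires the optimizer to match it to a
relative 1e-6. Centers are estimated per image — no manual thresholds, no
values shared across frames — which also means cluster semantics are
relative to each frame's own intensity distribution (see the vignette for
the interpretive caveat).

Pixels are assigned to the nearest center; per-cluster counts are averaged
over a patient's frames; pre→post percent changes are computed per patient;
and a cohort report runs distribution-gated paired tests within each
treatment arm (Shapiro–Wilk gate, then paired t or Wilcoxon signed-rank)
and between-arm tests on post-treatment counts (pooled t or Mann–Whitney U),
plus Cohen's κ for rater or truth agreement.

Because no patient imaging ships with the package, a synthetic vascular
phantom generator produces matched pre/post pairs (vessel tree, halo,
speckle, aneurysm, four planted intensity modes) with ground-truth label
maps, so every stage is testable end to end.

## Worked example

```r
library(dsaclust)

spec <- phantom_spec(seed = 42)          # synthetic pre/post pair, known truth
pair <- generate_pair(spec)

cfg  <- run_config()                     # defaults: Gaussian+median, DIRECT k=4
pre  <- segment_frame(pair$pre,  cfg)
post <- segment_frame(pair$post, cfg)

round(pre$centers, 3)
#> 0.046 0.283 0.611 0.913
as.integer(pre$counts);  as.integer(post$counts)
#> 7526  406  424  860
#> 7683  390  439  704
round(percent_change(pre$counts, post$counts), 1)
#> cluster1 cluster2 cluster3 cluster4
#>      2.1     -3.9      3.5    -18.1
```

The four centers sit near the phantom's planted modes (30, 90, 160, 230 on
the 8-bit scale ≈ 0.12, 0.35, 0.63, 0.90 normalized, shifted here by
denoising and percentile normalization). After complete occlusion the
background cluster gains 2.1% of its pixels while the high-intensity
cluster loses 18.1% — the expected signature, since the removed aneurysm
(~250 px²) stops filling with contrast.

For a cohort, write a YAML manifest mapping patients to groups and matched
frame files (`load_manifest()` documents the layout, `generate_cohort()`
writes a complete synthetic one) and run:

```r
report <- run_cohort("manifest.yaml", run_config(), out_dir = "out")
```

which writes `counts.csv`, `changes.csv` and `cohort_report.json` — group
means ± SD pre/post, within-group and between-group p-values per cluster,
and per-patient percent changes, all stamped with a configuration hash and
free of timestamps so repeated runs are byte-identical.

A thin command-line interface wraps the same functions:

```sh
Rscript inst/cli/dsaclust.R phantom --out demo --n-per-group 3 --seed 1
Rscript inst/cli/dsaclust.R cohort --manifest demo/manifest.yaml --out demo/out
Rscript inst/cli/dsaclust.R segment --frame demo/frames/E01_pre_AP_1.png
Rscript inst/cli/dsaclust.R verify --frame demo/frames/E01_pre_AP_1.png
```

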