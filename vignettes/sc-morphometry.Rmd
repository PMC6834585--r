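---
title: "Quantifying synaptonemal-complex architecture from 3D point models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synaptonemal-complex architecture from 3D point models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scquant)
```

The synaptonemal complex (SC) joins homologous chromosomes during
meiotic pachytene: two lateral elements (LEs) about 100 nm apart,
bridged by transverse filaments (TFs, dimers of SYCP1) that interdigitate
in the central element (CE). Electron tomography plus manual
segmentation yields, per tomogram, an annotated 3D point model: a
polyline per TF and point sets for the three elements. This vignette
explains what `scquant` computes on such models, the assumptions
behind each step, and what the bundled synthetic generator does and
does not emulate.

## The measurement model

**Calibration.** Coordinates arrive in pixels. Conversion to nm
multiplies by the pixel size (tomogram default 0.287 nm); z is
additionally stretched by the z-scale factor, the ratio of the nominal
section thickness (default 250 nm) to the reconstructed z-extent,
compensating the thinning that resin sections suffer. Scaling is applied
once, after reading (`apply_scaling`); models carry a units flag so a
second application is a state error.

**Element membership.** A segmented element is a point cloud; a point is
"embedded" in it when its distance to the cloud is at most a membership
radius $\delta$ (`quant_config(delta_nm = 4)`). The radius absorbs
segmentation sparsity with one tunable parameter. The synthetic
generator can instead emit `slab` regions — oriented boxes with exact
boundary surfaces — which make zero-noise results exactly checkable; its
point-cloud mode samples a grid over the box eroded by `cloud_delta_nm`
so that the cloud's $\delta$-offset surface reproduces the slab surface
(use the same $\delta$ at analysis time).

**Segment lengths.** Each TF is assigned to the LE nearer its closer
endpoint; the far endpoint is its CE end. A trace whose CE end also lies
inside the same LE is flagged `unresolved` (a suspect segmentation,
likely a trace that never leaves the rail) and excluded from
side-specific statistics, with exclusion counts reported. Walking the
polyline from the LE end (respectively CE end), the first vertex pair
straddling the membership boundary brackets the crossing, which is
located by bisection — to 0.01 nm on point clouds (well below the
0.287 nm pixel; clouds have no sub-spacing accuracy anyway) and to
1e-8 nm on slabs, whose surfaces are exact, so that noise-free synthetic
models are recovered to numerical precision. LE-indent, CE-indent,
midsection and total length are Euclidean distances between endpoints
and intersection points; a TF missing an intersection contributes `NA`
to the affected summaries only.

**Widths.** The CR width sample at an LE intersection point is its
nearest-neighbor (NN) distance to the opposing LE's intersection points;
LE-CE uses same-side CE intersections, and CE width cross-side CE
intersections ("accordingly" left this open; the cross-side NN reading
keeps all three widths structurally parallel). Because a tilted filament
crosses the rails at laterally offset points, these NN estimates can
only overshoot the true rail spacing — an estimator property the test
suite asserts (`CR width >= planted gap`). Means are reported with the
sample (n−1) standard deviation throughout, as per-tomogram samples are
small.

**Pairing classes.** Per CE endpoint, `nn_opposite` is the minimal
distance to an opposing-side CE endpoint and `nn_parallel` to a
same-side one (self excluded). No published rule defines the classes, so
the package uses a threshold: *opposite* if `nn_opposite <= 15` nm, else
*parallel* if `nn_parallel <= 15` nm, else *single*, with
opposite-over-parallel precedence. 15 nm sits below both reported NN
means (17 and 20 nm), so only markedly close neighbors count as pairs;
the threshold is exposed in `quant_config`.

**Densities and asymmetry.** Site points (CE insertion points by
default) are projected onto their orthogonal-regression plane; an
axis-aligned rectangle over the projected extrema estimates the SC
length (larger side) and area, giving TFs/µm (total TF count over
length) and TFs/µm² (site count over area). Asymmetry is
$100\,|n_L - n_R| / \max(n_L, n_R)$ — the larger side as denominator
reproduces 21% for a 100-vs-79 split. The per-µm figure counts both
sides; published per-µm and per-µm² values are consistent with that
reading (79/µm over a ~75.5 nm depth extent gives ~1046/µm²).

**Rank-sum comparisons.** `rank_sum_test` wraps the two-sided Wilcoxon
rank-sum test: exact when $n_1 + n_2 \le 16$ and tie-free, else the
normal approximation with midranks and continuity correction. The test
suite checks the exact branch against a full enumeration over all
$\binom{n_1+n_2}{n_1}$ rank assignments.

**Pooling.** Cohort statistics are computed over the concatenated
per-TF and per-point samples — all tomograms treated as one data set —
never as means of per-tomogram means. Densities and asymmetry, which are
intrinsically per-tomogram, are summarized across tomograms.

## The layer test

If TFs were organized in two layers, their endpoints on each side of the
CE should fall on two parallel planes at a fixed spacing. The package
fits a single plane (normal = eigenvector of the smallest eigenvalue of
the centered second-moment matrix, i.e. orthogonal regression) and a
two-plane model via k-planes alternation: assign each point to the
nearer plane by orthogonal distance, refit, repeat. Initializations
cover the sign of the single-plane residual, median and range-midpoint
splits along each principal axis (the midpoint split lands directly in a
planted-bilayer basin even when the layers are unequal in size), and
random balanced partitions. Clusters below 3 points are discarded.

Two numerical choices matter here:

- **Solution selection.** The k-planes objective is nearly flat across
  its local optima: a split along the layer axis and a split along the
  width-axis scatter can differ by a few percent in SSE, which is below
  the $\sim\sqrt{2/n}$ sampling noise of the SSE itself at $n \approx
  100$. Among converged solutions within 30% of the best SSE the fit
  therefore reports the most separated one (largest gap-to-scatter
  ratio), not blindly the lowest-SSE one. On unimodal data all
  near-optimal splits have gap/scatter $\lesssim 3.4$, so this cannot
  conjure a layer signal.
- **Verdict criteria** (`layer_config`): *bilayer* requires (1) plane
  normals within 20°, (2) a gap of at least 4× the pooled within-cluster
  rms **and** at least 5 nm, and (3) longitudinal overlap of the two
  clusters of at least 0.5. The 4× multiplier is deliberate: an optimal
  two-way split of *any* unimodal Gaussian scatter already produces
  gap/rms $\approx 2.65$ (uniform scatter: 3.46), so a 2× rule would
  declare every noisy monolayer bilayered; 4 separates that artifact
  ceiling from genuine layering (a planted 30 nm gap at 3 nm jitter
  gives a ratio near 10). The 5 nm floor guards noise-free data, where
  any split of exactly coplanar points has gap 0 yet also rms 0. The
  overlap criterion excludes the longitudinal-split artifact: when an SC
  tilts or curves through the section, the two "layers" the fit finds
  are front and back halves of a single sheet along its course, and
  their longitudinal ranges barely overlap. All three thresholds are
  exposed in `layer_config`.

Sides are evaluated independently (the default fits the CE endpoints of
each side; `endpoint = "both"` is a sensitivity option) and combined
into a cohort verdict only when they agree. The lateral-view depth
projection (`ce_projection`) uses a geometrically defined frame — width
axis from the LE centroids, long axis from the principal direction of
the CE intersections, depth as their cross product — rather than a
fitted frame, which in degenerate (flat) models would swing its "depth"
axis onto the width axis.

## The synthetic generator

`generator_config()` defaults encode the measured murine geometry:
CR width 114 nm, CE width 29 nm, LE thickness 40 nm, TF total
88 ± 14 nm, LE-indent 21 ± 9 nm, CE-indent 14 ± 7 nm, 79 TFs/µm (both
sides pooled), and a TF depth extent of 75.5 nm — the value implied by
dividing the per-µm density by the per-µm² density. Note that the
printed width table is not an exact geometry: $(114-29)/2 = 42.5$ nm,
not the separately measured 45 nm LE-CE distance; the generator derives
the rail-to-CE gap from CR and CE widths.

Filaments are straight segments (all published lengths are
endpoint-to-endpoint Euclidean distances, so trace curvature would add
untestable freedom). Obliquity reconciles the midsection with the gap:
a drawn midsection $m \ge g$ spans the gap at tilt
$\theta = \arccos(g/m)$, with the azimuth uniform. Draws are truncated
normals (1 nm floor); a midsection drawn below the gap is clamped to it
(a perpendicular TF), the clamp recorded per TF — at defaults roughly a
third of draws clamp, raising the realized total length a few nm above
88, which is why recovery tests compare estimators against *realized*
ground truth, not against configured constants. Arrangement classes are
planted by construction: opposite pairs share a CE locus in the
length-depth plane within 5 nm (the partner's own indent draw is
accepted when the 3D endpoint separation stays under 14 nm, with an
unconditioned fallback so infeasible geometries do not bias the draws),
parallel pairs likewise on one side, and singles keep a 25 nm exclusion
radius enforced by rejection sampling (violations are counted and
warned about). Bilayer mode places CE endpoints on two z-planes at
±gap/2; a sinusoidal course offset emulates an SC bending through the
section. Gaussian jitter (default sd 2 nm) is added to every polyline
vertex last; ground truth records everything pre-jitter, with the
realized width and density aggregates computed by the same NN and
projected-rectangle constructions the estimators use, evaluated on the
true intersection points.

When positions are unjittered (`position_jitter_frac = 0`) anchor sites
sit on a regular grid spanning the full length and the depth levels are
assigned symmetrically about the SC midpoint; the sample length-depth
covariance then vanishes and the projected rectangle recovers length
and depth spans exactly, making the zero-noise identity checks exact
rather than approximate. Counts are deterministic
(`round(density x length)` with the asymmetry split); randomness lives
in placement and per-TF draws. Per-tomogram seeds are master seed + index.

What the generator does *not* emulate: curved filament traces, real
segmentation artifacts (gaps, mistraced rails), intensity information
(TF diameter is an image measurement, out of scope), nonplanar rail
separation (the configured CR-width spread is recorded but the rails are
kept planar so slab regions stay exact), chromatin, and nuclear-envelope
attachment. Passing tests therefore demonstrate correctness of the
geometry and statistics pipeline under a faithful geometric idealization
— not robustness to every property of real tomograms.

## Problem sizes and runtime choices

The test suite and acceptance script use: a 2 µm zero-noise model
(158 TFs) for exactness; six 1.055 µm tomograms (≈500 TFs, seed 1) for
recovery, matching the published six-tomogram design; 20 replicates of
2.532 µm models (≈100 TFs per side) for the layer discrimination rates;
n = 2000 singles for sampler calibration (3 standard errors, in a
narrow-CR geometry where clamping is negligible); and 500-point clouds
for the brute-force NN oracles. These sizes give stable statistics in
seconds per case.

## Known limitations

- The pairing threshold, CE-width operationalization, asymmetry
  denominator and layer-verdict thresholds are this package's own
  definitions of under-specified quantities; all are exposed in the
  configuration records.
- At the published NN statistics (17 ± 9 vs 20 ± 10 nm), a rank-sum
  comparison at n = 200 per group has roughly 70–80% power at
  $\alpha = 0.01$; single replicates at that size will not reliably
  reach very small p-values (the direction itself is stable, and the
  acceptance script reports the measured power at both 0.01 and 0.05).
- Layer discrimination degrades below ~50 endpoints per side; verdicts
  on very short SC segments should be treated as exploratory.
- Binary IMOD `.mod` files are not parsed; convert with
  `model2point -object` first.
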