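---
title: "Methods: layerwise affect decoding with noise-ceiling normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layerwise affect decoding with noise-ceiling normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(affdecode)
```

## The problem

Groups of human respondents rate images for evoked affect (arousal, valence,
beauty) on a bounded scale, and we ask how much of the group-average rating a
*feature space* — typically one layer of a deep vision network — can predict
with a linear read-out. Because respondents disagree, raw predictive accuracy
is bounded not by 1 but by the reliability of the group average itself, so the
package always reports accuracy alongside two inter-rater variability
ceilings and as a noise-corrected fraction of explainable variance.

The pipeline, stage by stage: flatten each layer's activations to one feature
vector per image; reduce wide layers with a sparse random projection sized by
the Johnson–Lindenstrauss bound; fit a leave-one-out cross-validated ridge
regression from features to group-average ratings; score each layer by the
Pearson correlation `r(y, yhat)` between pooled out-of-fold predictions and
observed ratings, and by the explainable variance explained,

$$ r^2_{EVE} \;=\; \frac{r(y,\hat y)^2}{r_{split}^2}. $$

A robustness suite covers bootstrap model ranking, paired comparisons with
Holm correction and Hedge's g, Mann–Whitney tests, decoding of individual
respondents, and cross-decoding between image sets.

## Reliability ceilings

Two quantities summarize rater agreement:

* **Mean-minus-one correlation** (`mm1()`): each respondent's Pearson
  correlation, over exactly the images they rated, with the group mean
  computed without them. We read it as a "ceiling of shared taste" — how well
  a single human predicts the group.
* **Split-half reliability** (`split_half()`): the respondent pool is split
  into two equal halves (an odd pool drops one respondent at random per
  split), per-image means are correlated across images, and each split's
  correlation is corrected with the Spearman–Brown prophecy formula
  `2r/(1+r)`. The mean over 10,000 splits (the default) is the noise ceiling.

Degenerate correlations (zero-variance respondents, images unrated in one
half) are flagged and excluded per split with counts, never silently coerced.
All correlations here and below are Pearson. Confidence intervals are
percentile bootstrap intervals; bias-corrected variants are out of scope.

Note a structural property of the EVE denominator: the Spearman–Brown
corrected split-half estimates the *reliability* of the group mean, which
already is a squared-correlation-scale quantity
(`var(signal)/var(observed)`). Dividing `r^2` by `r_split^2` therefore
over-corrects slightly, and EVE estimates can legitimately exceed 1 for
decoders near the ceiling. We follow that convention, report values unclipped,
and carry the sign of `r` so that squaring cannot hide an anticorrelated
predictor.

## The synthetic rater pool

`simulate_ratings()` draws

$$ rating_{ij} = t_j + u_{ij} + e_{ij}, \quad
   t_j \sim N(0, s),\; u_{ij} \sim N(0, v_i),\; e_{ij} \sim N(0, v_e), $$

where `t` is the image-level affect latent shared by everyone, `u` is a
rater-by-image stable idiosyncrasy (fixed per pair — "personal taste"), and
`e` is trial noise. Each rater views a fixed-size uniform subset of images
(`coverage`), mirroring sparse viewing designs in which every respondent
rates a few hundred of the images. Ratings are affinely mapped onto the 0–7
scale and optionally rounded to integers; the affine map preserves every
correlation-based quantity exactly, rounding degrades them slightly, so
parameter-recovery work uses `discretize = FALSE` while the default mirrors
the integer rating task.

For `m` raters per image the Spearman–Brown corrected split-half reliability
has the closed form `s / (s + (v_i + v_e)/m)`, which the generator stores as
`expected_rsplit` and the tests recover empirically to within 0.02 at 900
images and 10,000 splits.

Defaults — `n_images = 900`, `m = 40` raters per image, `s = 1`,
`v_i = 2`, `v_e = 2` — give a reliability of `1/(1 + 4/40) ≈ 0.909` and a
mean mean-minus-one correlation near 0.43, a regime comparable to published
beauty-rating pools. Published sources do not state per-image rater counts,
so `m = 40` is a package default, exposed in the configuration. Vector-valued
`var_idio` makes rater "taste-typicality" heterogeneous, which the
individual-respondent analyses exploit.

## The synthetic feature hierarchy

`simulate_feature_bank()` builds layers whose decodable signal grows with
relative depth `d = (index − 1)/(n_layers − 1)`. Layer `l` contains `k`
signal columns

$$ x_{\cdot j} = \alpha(d_l)\, g\, w_j + \sigma \varepsilon, $$

padded with unit-noise columns to the layer width. The gain profile
`alpha(d)` is monotone with `alpha(0) = 0`; the default `d^2` emulates the
accelerating, near-monotone rise of decodability over depth seen in trained
vision hierarchies. The read-out weights are normalized to `||w||^2 = k` so
the deepest layer's column signal-to-noise ratio is deterministic.

The carrier `g` mixes the standardized latent with an independent nuisance,
`g = a\, t_{std} + \sqrt{1-a^2}\, q`. Two closed-form facts set the mixture
weight: `cor(g, Y)^2 = a^2 r_{SB}` against the group mean `Y`, and the best
linear read-out of the `k` noisy signal columns recovers `g` with
`cor^2 = k/(k + \sigma^2)`. Setting

$$ a^2 = f \cdot r_{SB} \cdot \frac{k + \sigma^2}{k} $$

makes the *optimal* read-out of the deepest layer attain exactly
`r^2 = f\, r_{split}^2`, i.e. a designed EVE of `f`. Because the scoring
metric divides by `r_split^2`, designing `f` on the EVE scale (rather than as
a raw fraction of latent variance) is what makes parameter recovery a clean
identity; the two scales differ by the factor `1/r_split ≈ 1.1` at the
default variance components. The residual gap between designed and recovered
EVE is then pure decoder estimation loss — ridge shrinkage, leave-one-out
noise, and the dilution caused by the noise-padding columns — measured at
roughly 0.01–0.04 EVE at the default widths, within the ±0.05 recovery band
the tests enforce.

Default widths are a scaled-down hierarchy (32–1024 columns over six
layers): wide enough that the padding dilution is realistic, small enough
that a full recovery study (60 bank decodes) runs in minutes. Real networks
are orders of magnitude wider; nothing in the pipeline depends on the
absolute scale because projection and standardization normalize it away.

`simulate_two_datasets()` adds category structure for cross-decoding: every
distinct category name owns a private block of `k` feature dimensions and a
private weight vector, shared across datasets exactly when the category name
is shared. One caveat discovered while designing it: a ridge decoder trained
on one category noise-fits a spurious alignment of order `sqrt(k/D)` onto any
*other* category's signal block, so the no-transfer condition is only
represented cleanly when the layer width dominates the block size — hence the
1024-column default for the single cross-decoding layer.

What the generator does **not** emulate: real image content and category
frequencies, rater drift or prompt effects, heavy-tailed rating
distributions, and the absolute accuracy values of any published pool.
Passing recovery tests shows the *pipeline* is correct and calibrated under
its stated model; it does not certify behavior on real data whose violations
of that model (non-Gaussian taste, non-linear feature-affect relations) are
untested here.

## Sparse random projection

The minimum embedding dimension preserving pairwise distances of `n` points
within distortion `epsilon` is

$$ p \;\ge\; \frac{4 \ln n}{\epsilon^2/2 - \epsilon^3/3}, $$

which `jl_min_dim()` evaluates with floor rounding by default — for 900
images at `epsilon = 0.1` the bound is ≈ 5830.6, so the working dimension is
5830 (ceiling rounding is exposed for conventions that round up). Layers no
wider than the threshold pass through untouched.

The projection matrix is the standard sparse construction: i.i.d. entries
`±sqrt(sqrt(D)/p)` with probability `1/(2 sqrt(D))` each, zero otherwise
(density `1/sqrt(D)`). This scaling makes each column contribute
`||u||^2/p` to `E||uR||^2`, so squared norms — and hence pairwise distances —
are preserved in expectation; the tests verify the density law, the norm law
over 1000 matrix draws, and the `(1±epsilon)` distance sandwich at
`D = 50{,}000, p = 5830`. The matrix is oriented `D x p` (features in, target
dimension out), which is the only orientation dimensionally consistent with
`P = F R`. One matrix is drawn per layer, seeded from
`(global seed, model id, layer id)`, so layers are independent but every run
is reproducible; whether a single matrix should be reused across layers of
equal width is a sensitivity question we deliberately left one seed away.

## Ridge decoding with closed-form leave-one-out

The target and the (projected) feature columns are standardized **once on
the full data** — mean 0, population SD 1 — before cross-validation. This
follows the benchmark convention and implies a mild train/test leak through
the standardization parameters; a `standardization = "per-fold"` mode
recomputes them inside every fold (at `n` times the cost) for anyone who
wants the leak-free variant, and the two agree closely whenever the decoding
is not near chance. The population-SD convention is recorded because it is a
genuine free choice; it affects nothing beyond scale.

For fixed `lambda` the leave-one-out predictions have a closed form through
the ridge hat matrix,
`yhat_i = (fit_i − h_ii y_i)/(1 − h_ii)`, computed via the primal Gram matrix
when `p ≤ n` and via the kernel identity `H = K(K + \lambda I)^{-1}`,
`K = PP'`, when `p > n`, so the cost never exceeds `O(n^3 + n^2 p)`. The
identity is exact: tests require agreement with an explicit per-fold refit to
1e−8 relative tolerance on 200 random problems. The default penalty is
`lambda = 1e4`, global across layers; `grid_search_lambda()` (logarithmic
grid `1e-1`–`1e6`, smallest cross-validated error wins) is provided as a
calibration utility but is not part of the default pipeline, and we make no
attempt to re-derive the default from scratch. A subtlety worth stating: for
a pure-noise target the expected cross-validated error is monotone in
`lambda`, but single realizations can prefer interior penalties through
chance alignment (and whole-data standardization contributes a small genuine
leak), so the tests assert the shrinkage preference on error curves averaged
over draws.

Zero-variance feature columns are dropped with a logged count. Exact
best-layer ties are broken toward the shallowest layer and flagged. Layer
selection reuses the cross-validated `r` itself — there is no second
held-out selection set — so best-layer scores carry mild selection optimism;
this is inherent to the "most predictive layer" convention and is recorded
in the outputs rather than corrected. The depth-on-accuracy regression uses
unbinned per-layer scores per model; the 10 equal-width depth bins are for
display only.

## Inference

* **Respondent-pool bootstrap** (`bootstrap_scores()`): respondents are
  resampled with replacement, group means recomputed, and each model's
  best-layer regression *refit* to every replicate (the default); rank
  tabulations count how often each model places first, second, and so on.
  Pairwise differences get percentile CIs and a two-sided sign-fraction p
  (`2·min(frac ≤ 0, frac ≥ 0)`, capped at 1), Holm-corrected over the family
  of pairs. A cheaper `"rescore"` mode keeps the out-of-fold predictions
  fixed and only re-correlates them with resampled targets.
* **Calibration of those p values**, measured on simulated true-null pairs:
  the refit bootstrap is conservative (no excess false rejections; null p
  values lean high), while the rescore shortcut is *anticonservative* — the
  bootstrap never resamples the ridge fit's chance adaptation to the realized
  target, so its spread understates the sampling spread of the score
  difference by roughly a factor of two. Rescore mode is therefore a smoke
  -test tool, not an inference tool. More generally, a respondent-pool
  bootstrap quantifies rater-sampling uncertainty only; image-level chance
  alignment is a fixed effect within any one experiment and is invisible to
  it.
* **Paired comparisons** (`paired_ttest_holm()`): paired t tests per cell
  with Holm step-down across the declared family and the paired Hedge's g,
  `mean(d)/sd(d) · (1 − 3/(4·df − 1))` — the small-sample-corrected,
  difference-SD variant, a choice we record because published reports rarely
  state theirs. Zero-variance differences are flagged: all-zero gives
  `g = 0, p = 1`; a constant nonzero shift gives an undefined (`NA`) g,
  never an infinite one.
* **Mann–Whitney** (`mann_whitney()`): exact p for small tie-free samples,
  tie-corrected normal approximation otherwise, via the standard library
  routine; tests pin it to brute-force enumeration.
* **Individual-respondent decoding** (`decode_individual()`): the chosen
  layer is refit to each respondent's own ratings over exactly the images
  they viewed, with a configurable 20-image floor; negative accuracies are
  reported as-is. The correlation between per-respondent accuracy and
  mean-minus-one correlation quantifies the taste-typicality relationship:
  divergent raters are harder to decode.
* **Cross-decoding** (`cross_decode()`, `cross_decode_matrix()`): a single
  ridge fit on the training subset, standardization parameters estimated on
  the training rows and applied unchanged to the test rows (leaking test
  statistics would invalidate the transfer claim), Pearson accuracy on the
  held-out rows; diagonal cells report the within-subset leave-one-out
  accuracy instead.

## Numerical and reproducibility choices

All solves use Cholesky factorizations of symmetric positive-definite
systems; `lambda = 0` is refused whenever it would make the system singular.
Every source of randomness descends from one integer seed through
`derive_seed()`, a documented label-folding scheme, so any stage can be
reproduced in isolation; derived seeds stay below `2^31`. Feature-bank files
store arrays as full-precision text with per-file checksums, and readers
reject rather than coerce malformed input.

## Problem sizes used by the test suite

The packaged tests run the recovery studies at the generator's default
conditions — 900 images, 40 raters per image, six layers up to width 1024 —
with 20 replicates per designed decodable fraction, 10,000 reliability
splits, and three replicates per cross-decoding configuration (900–1200
images per dataset). These sizes are the package's chosen design points:
large enough that Monte-Carlo error is well inside the stated tolerances,
small enough that the whole suite completes in a few minutes.

## Known limitations

Selection optimism in best-layer scores is unquantified (no nested
selection); EVE above 1 is reported, not truncated; the respondent bootstrap
cannot see image-sampling variability; the generator's Gaussian, linear,
block-structured world is a deliberately simple testbed, not a model of real
affect; and feature extraction from actual networks is outside the package —
it begins at ratings tables and feature banks.
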