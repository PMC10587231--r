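---
title: "Label-free recalibration of classifier scores under acquisition shift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free recalibration of classifier scores under acquisition shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(upalign)
```

## The problem

A binary image classifier deployed in a screening programme emits a
continuous malignancy score in $[0,1]$, thresholded at a pre-calibrated
operating point — here the *balanced* point, where sensitivity equals
specificity. After deployment, the data acquisition pipeline changes: a
scanner is replaced, a site uses a different vendor, the vendor ships an
image-processing update. Such *acquisition shift* typically leaves the
model's ability to separate classes intact (ROC-AUC generalises) while
displacing the score distribution, so the frozen threshold no longer sits at
the intended operating point. The consequence is a silent drift of the
sensitivity/specificity balance — under- or over-diagnosis — that no AUC
monitor would notice.

This package implements unsupervised prediction alignment: the score
distribution observed on the shifted domain is mapped back onto a reference
score distribution by piecewise-linear cumulative-distribution matching (the
score-space analogue of histogram matching in image processing). No labels
from the shifted domain are needed — only a modest batch of unlabelled
predictions.

## The transform

Let $F_A$ be the empirical CDF of the *alignment set* (unlabelled scores
from the shifted domain) and $F_R$ that of the *reference set*. For every
distinct alignment score $a$, `fit_alignment()` places a knot at
$(a,\; F_R^{-1}(F_A(a)))$ and interpolates linearly between knots. Applying
the map to a new score from the shifted domain returns the reference-domain
score occupying the same quantile.

Conventions the package fixes (the method itself leaves them open):

* **ECDF / quantile convention.** $F_A(a) = \#\{x \le a\}/n$, and
  $F_R^{-1}$ interpolates linearly between order statistics with order
  statistic $i$ of $n$ at level $i/n$; levels below $1/n$ clamp to the
  minimum. Under this pairing, aligning a set to itself is *exactly* the
  identity at every knot, which makes the null-shift behaviour easy to
  reason about and to test.
* **Ties.** Knots are built on distinct values, so tied inputs always map to
  equal outputs; the tied mass moves to the matched quantile of the upper
  tie boundary.
* **Extrapolation.** Outside the alignment range the map continues linearly
  with the outermost segment's slope and the result is clipped to $[0,1]$.
  New test scores may legitimately exceed the alignment range; clipping
  preserves the score-domain contract at the cost of possible ties at the
  boundary. Inputs outside $[0,1]$ are an error, never clamped.
* **Minimum fit size.** A transform is refused below `min_fit_size`
  (default 2 scores; the streaming engine uses 50) rather than fitted badly.

Because the map is monotone non-decreasing, it never reorders predictions:
ROC-AUC is identical before and after alignment (exactly so for tie-free
scores; with ties the change is bounded by the tied pair mass). Alignment
therefore *cannot* repair a genuine loss of separability — it repairs the
operating point, assuming AUC transfers. It also preserves the shape of the
score distribution, so relative calibration (and hence the expected
calibration error against the reference) is maintained, unlike approaches
that move the threshold instead of the scores.

```{r transform-demo}
reference <- plogis(rnorm(5000, 0.5))
shifted   <- plogis(rnorm(2000, 0.5) - 1.5)  # same classes, displaced scores
tr <- fit_alignment(reference, shifted)
tr
detect_shift(reference, shifted)$statistic                      # KS before
detect_shift(reference, apply_alignment(tr, shifted))$statistic # KS after
```

## Operating points and metrics

The decision rule is *positive iff score $\ge$ threshold* (the method note
is silent on $\ge$ vs $>$; one rule is fixed for determinism and documented
here and in the CLI). `select_threshold_balanced()` scans all candidate
thresholds — midpoints between adjacent distinct scores plus the endpoints —
for the exact minimiser of $|\mathrm{SEN}-\mathrm{SPC}|$, breaking ties
towards the smallest threshold; `select_threshold_at_specificity()` returns
the smallest candidate attaining a target specificity. ROC-AUC is the
Mann–Whitney concordance with ties counted $1/2$ (rank formula). Youden's
index is $J = \mathrm{SEN}+\mathrm{SPC}-1$. The expected calibration error
uses 10 equal-width bins by default — the convention of the calibration
literature; reported ECE values are binning-dependent and should not be
compared across bin counts. All metrics are image-wise; cases are the
*sampling* unit, never the evaluation unit.

## What the synthetic generator emulates

No real screening scores ship with the package; a seeded generator supplies
data with exactly the statistical structure the method assumes:

* **Binormal-on-logit scores.** Per image, a latent
  $z \sim N(\mu_{\text{class}}, \sigma)$ squashed through the logistic
  function. Chosen because the separability has the closed form
  $\mathrm{AUC} = \Phi\!\big((\mu_+-\mu_-)/(\sigma\sqrt2)\big)$, giving the
  tests an independent oracle. Defaults $\mu_-=0,\ \mu_+=2,\ \sigma=1$, i.e.
  $\mathrm{AUC}=\Phi(\sqrt2)\approx 0.921$ — the regime of a strong but
  imperfect screening model.
* **Case structure.** Case labels are Bernoulli(prevalence); every image of
  a case inherits the label (all four views of a malignant study count as
  positive images); latent noise is independent per image. The mammography
  preset uses prevalence 0.02, 4 images/case, 250 cases/week; the
  histopathology preset prevalence 0.5, 1 image/case.
* **Acquisition shift as a monotone score warp.** Strictly increasing warps
  change the score distribution while provably preserving AUC — the regime
  the method is designed for, by construction. The shipped
  `scanner_shift` preset is a latent logit shift of $-1.5$: at the balanced
  operating point of the unshifted domain it drives
  $|\mathrm{SEN}-\mathrm{SPC}|$ to $\approx 0.69$ (closed form), i.e. a
  Youden's index collapse from $\approx 0.68$ to $\approx 0.30$ — a severe,
  realistic scanner-replacement break. A software update that sharpens
  images is represented by the odds-power warp
  $x \mapsto x^{1+s}/(x^{1+s}+(1-x)^{1+s})$ (identity at $s=0$, fixed points
  0 and 1, scores pushed to the extremes); the shipped strength $s=1.5$
  breaks the balanced point by $\approx 0.29$. The warp strength has no
  data-anchored value — the original update acts on images, not scores — so
  it is a free parameter fixed once at a clearly threshold-breaking level.

What the generator does *not* emulate: population or prevalence shift
(assumed roughly constant across domains — the method's own assumption, and
enforced), label noise, reader effects, correlated views within a study
beyond the shared label, or separability loss (non-monotone shifts exist
behind `warp_power`-style families only for negative testing). Passing tests
therefore demonstrate correctness of the machinery under the method's
assumptions, not robustness to their violation.

## Deployment protocols

**New site (one-off).** `scenario1_bootstrap()` freezes the balanced
threshold on a labelled reference, then repeatedly (default 500, scaled down
in examples) draws an evaluation set (default 2500 cases) and a disjoint
alignment set (default 1000 cases) from the target domain, fits the
transform label-free, and reports SEN/SPC/AUC/Youden and SEN−SPC before and
after alignment with percentile summaries. "Repeated with replacement" is
read as: each repetition draws independently, without replacement *within* a
repetition (disjointness is required), cases reusable across repetitions —
the only reading consistent with drawing 3500 cases per repetition from a
~4000-case pool.

**Continuous streams.** `upa_engine()` freezes the reference scores and the
operating point once; `engine_step()` consumes one week of records, fits a
per-device transform from that device's running window (the previous
`window_length = 2` weeks — never the week being evaluated), and reports
per-device and pooled metrics before/after. Devices are fully isolated: each
scanner's transform sees only that scanner's buffer, so a software update on
one scanner never perturbs another's calibration. Until a device's buffer
reaches `min_fit_size` (50 images) its scores pass through unchanged — the
cold-start rule; the method note does not define weeks 0–1 behaviour, and
deferring is safer than fitting on a handful of points. After a sudden
shift the window is fully post-shift within `window_length` weeks, which
bounds the recovery time. Pooled metrics are computed on the concatenation
of the per-device aligned scores; no pooled transform is fitted.

```{r streaming-demo}
sch <- make_schedule("software_update", horizon = 12, update_week = 6)
rep <- run_scenario(sch, n_reps = 5, seed = 2)
subset(as.data.frame(rep), device_id == "overall" & week >= 5 & week <= 9,
       select = c(week, aligned, mean_gap))
```

The uncorrected trajectory jumps at the update week and stays displaced;
the aligned one returns to $\approx 0$ within the window length.

## Monte-Carlo design of the evaluation

Quantities like "mean SEN−SPC after alignment" are expectations over the
sampling protocol. The package's evaluation code fixes two design choices:

* **Replicated experiments.** A single reference draw carries an
  operating-point estimation offset (with ~240 positive reference images at
  2% prevalence its standard deviation is $\approx 0.026$ in SEN−SPC
  terms — comparable to the effects being measured). Summary experiments in
  the acceptance suite therefore average several independent replicates of
  the complete protocol, reference draw included, rather than conditioning
  on one lucky or unlucky reference. `run_scenario()` builds this in: every
  repetition draws a fresh reference.
* **Common random numbers in `size_sensitivity()`.** Within one repetition,
  all alignment-set sizes share the same evaluation draw and use nested
  alignment subsets ($250 \subset 500 \subset 1000$ cases); reference-size
  sweeps nest subsets of one permutation. Each grid point marginally follows
  the plain protocol; the coupling only stabilises *comparisons* across grid
  points, so that the expected tightening of the dispersion with more
  alignment data is not drowned in uncoupled percentile-estimator noise.

Problem sizes used by the shipped tests and the acceptance script — chosen
as desk-scale versions of the deployment protocols: reference 3000 cases,
target 4000 cases, 100 repetitions at evaluation 1000 / alignment 500 cases
for the new-site protocol; 50 repetitions of 20-week streams at 250
cases/week for the scenarios; 50,000 images for generator validation.

## Numerical and degenerate-input behaviour

* Fitting requires at least two *distinct* alignment scores; constant score
  vectors are refused.
* `quantile`-style interpolation and `approx` are linear throughout; no
  smoothing, no parametric fits.
* Record I/O writes scores at 17 significant digits (the transform is
  rank-sensitive, so round-tripping must not perturb order) and JSON
  transforms round-trip bit-identically.
* Weeks must arrive strictly ordered; a week whose records overlap the
  fitting window (by case/image id) is an error, enforcing the
  evaluation/window disjointness contract.
* Degenerate operating-point searches (all scores equal, unreachable target
  specificity) return the threshold 1 with an explicit degenerate flag and
  warning rather than failing silently.

## Known limitations

* Alignment corrects *threshold* shift only. If AUC itself drops across
  domains, the method will align distributions without restoring
  performance; pair it with AUC monitoring.
* A prevalence change between reference and target biases the matching (the
  mixture CDF moves for reasons the warp model cannot express). The
  assumption of stable prevalence is realistic for established screening
  programmes but must be checked; the package deliberately ships no
  prevalence-shift correction.
* The KS-based `detect_shift()` flags distribution change, not performance
  change; small cosmetic shifts can trip it while leaving the operating
  point intact. Its default threshold (0.1) is a monitoring convention, not
  a decision rule.
* With very small alignment windows (cold start, rare devices) scores pass
  through unaligned by design; users should treat per-device metrics from
  those weeks accordingly.
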