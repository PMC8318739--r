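---
title: "Threshold segmentation with a fireworks-algorithm optimizer: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold segmentation with a fireworks-algorithm optimizer: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(firethresh)
```

## The segmentation model

`firethresh` performs binary threshold segmentation of single-channel
grayscale images, the setting typical of organ/lesion delineation in
abdominal MRI. A gray image with `H` levels is summarized by its
histogram: counts $m_i$ per level $i \in [0, H-1]$, total $m$, and
probabilities $T_i = m_i / m$ with $\sum_i T_i = 1$.

A threshold $x \in [0, H-2]$ splits the levels into $R_0 = \{0,\dots,x\}$
and $R_1 = \{x+1,\dots,H-1\}$ (a pixel equal to $x$ belongs to $R_0$).
From the histogram we form

* class probabilities $V_0 = \sum_{i \le x} T_i$, $V_1 = 1 - V_0$;
* class means $\theta_0 = \sum_{i \le x} i\,T_i / V_0$,
  $\theta_1 = \sum_{i > x} i\,T_i / V_1$, and the global mean
  $\theta_Z = V_0\theta_0 + V_1\theta_1$;
* class variances $\sigma_k^2 = \sum_{i \in R_k} (i - \theta_k)^2 T_i / V_k$;
* the between-class variance
  $\sigma_J^2 = V_0(\theta_0-\theta_Z)^2 + V_1(\theta_1-\theta_Z)^2$ and
  within-class variance $\sigma_N^2 = V_0\sigma_0^2 + V_1\sigma_1^2$.

The identity $\sigma_J^2(x) + \sigma_N^2(x) = \sigma^2_{\text{global}}$
holds for every $x$; the test suite verifies it to $10^{-9}$ on random
histograms. The Otsu-type criterion maximized here is the variance ratio

$$\hat x = \arg\max_x \frac{\sigma_J^2(x)}{\sigma_N^2(x) + \varepsilon},
\qquad \varepsilon = 10^{-12}.$$

The regularizer $\varepsilon$ keeps the ratio finite on perfectly
separable (two-spike) histograms, where $\sigma_N^2 = 0$; because the
denominator is a constant minus the numerator, it does not move the
argmax, so the ratio criterion selects exactly the classic
between-class-variance Otsu threshold. When a class is empty
($V_0 = 0$ or $V_1 = 0$) its mean and variance are defined as 0; the
printed formula $\sum (i - \theta_k)^2 T_i / V_k$ is then a 0/0 and this
convention is the unique choice that keeps the conservation identity
exact.

As a comparator the package implements the Kapur–Sahoo–Wong (KSW)
maximum-entropy criterion: maximize $H_0(x) + H_1(x)$ with
$H_k = -\sum_{i \in R_k} (T_i/V_k)\,\ln(T_i/V_k)$, natural log,
zero-probability levels contributing 0, and an empty class scored
$-\infty$ so it can never win. On a uniform 256-level histogram the KSW
objective is $\ln\big((x+1)(255-x)\big)$, maximized at $x = 127$ — one
of the suite's closed-form oracles.

## Finding the threshold

Two search routes are provided and tested against each other:

* `exhaustive_best_threshold()` scans all $H-1$ candidates (the
  brute-force oracle, also the implementation of the plain `otsu` and
  `ksw` methods); ties break to the smallest $x$ for determinism.
* `fa_optimize()` runs a fireworks-algorithm (FA) search, exposed for
  thresholding via `fa_threshold()` / `segment_image(method = "fao")`.

The FA treats candidate thresholds as continuous positions in
$[\mathrm{lo}, \mathrm{hi})$ and follows the canonical loop, in
maximization form. Per generation, for fireworks with fitnesses $f_i$:

* **spark counts** $s_i = m_s \cdot (f_i - f_{\min} + \varepsilon) /
  \sum_j (f_j - f_{\min} + \varepsilon)$, rounded and clamped to
  $[\max(1, \mathrm{round}(a\,m_s)),\ \mathrm{round}(b\,m_s)]$ — better
  fireworks explode more;
* **amplitudes** $A_i = \hat A \cdot (f_{\max} - f_i + \varepsilon) /
  \sum_j (f_{\max} - f_j + \varepsilon)$ — better fireworks explode more
  locally;
* **explosion sparks** at $\mathrm{position} + U(-A_i, A_i)$;
* **Gaussian sparks**: a randomly chosen firework's position times
  $g \sim \mathcal N(1, 1)$ (the origin is a fixed point);
* **boundary mapping** $\mathrm{lo} + |x| \bmod (\mathrm{hi} -
  \mathrm{lo})$ for any spark leaving the interval;
* **selection**: the best candidate survives deterministically; the
  remaining $n-1$ are drawn without replacement with probability
  proportional to summed distance to all other candidates, which keeps
  the population spread out. If all candidates coincide the selection
  falls back to a uniform draw.

The best fitness ever evaluated (`best_val`) is tracked with strict
elitism, so the per-generation history is non-decreasing; fitness ties
resolve to the smallest position, matching the exhaustive tie-break.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `n` | 5 | fireworks per generation |
| `sparks` | 50 | total explosion-spark budget per generation |
| `amplitude` | 40 | amplitude cap $\hat A$, in gray levels |
| `a`, `b` | 0.04, 0.8 | spark-count clamp fractions |
| `gaussian_sparks` | 5 | mutation sparks per generation |
| `iterations` | 50 | generations |
| `min_amplitude` | 1 | floor on the per-firework amplitude (gray levels) |
| `seed` | — | RNG seed; fixes the whole run |

The first six are the canonical FA values; 50 generations are ample for
a one-dimensional search over at most 255 candidates. `min_amplitude`
is a numerical choice specific to the discrete objective: thresholding
fitnesses are evaluated at `round(position)` (clamped to $[0, H-2]$),
so an amplitude below one gray level cannot reach any new candidate —
and the allocation formula assigns the *best* firework, which receives
the largest spark batch, an amplitude of essentially $\varepsilon$.
Flooring the amplitude at the objective's resolution lets those sparks
probe the neighbouring levels instead of re-sampling a single point.
The floor is a constant, not a schedule; set `min_amplitude = 0` for a
genuinely continuous objective. Evaluations are cached per integer
threshold, so the FA's objective cost is at most one histogram pass per
distinct level probed.

`fa_optimize()` propagates `-Inf` as an "infeasible position" sentinel
(the KSW fitness of a threshold outside the histogram's support). If an
entire generation is infeasible, spark counts and amplitudes fall back
to uniform full-range exploration until feasible ground is found; `NaN`
from an objective is an error naming the offending position.

## Quality metrics

**DF (difference function)** is the fraction of pixels whose labels
disagree between two segmentations of the same scene. The anti-noise
protocol segments the clean reference image and a noise-corrupted copy
with the same method and reports their disagreement: 0 means the
method's output is unmoved by the noise, 1 means every pixel flipped.
Note the operands are two *masks*; comparing gray values against binary
labels would saturate the measure at ~1 and carry no information, so
the mask-vs-mask reading is the one implemented. DF is symmetric and
zero iff the masks are equal.

**GC (regional contrast)** is $|d_1 - d_2| / (d_1 + d_2)$, where $d_1$
is the mean gray value over the segmented foreground and $d_2$ the mean
over the adjacency ring — background pixels within Chebyshev distance
`ring_radius` (default 5 px) of any foreground pixel. "Adjacent area"
is not otherwise standardized; a ring tied to the boundary measures
local edge contrast rather than global foreground/background contrast,
and the radius is exposed for sensitivity checks. The absolute value
keeps GC in $[0, 1]$ when the foreground is the darker region. GC is
undefined (an error) for an empty foreground, an empty ring, or two
all-black regions; the benchmark records such cells as missing rather
than aborting.

## The phantom generator

Clinical images behind published thresholding comparisons are rarely
deposited, so the package ships a synthetic stand-in:
`phantom_spec()` / `generate_phantom()` draw an axis-aligned liver-like
ellipse (mean gray 110) containing a circular lesion (mean 200) on a
dark background (mean 30), 256×256 by default, geometry scaling with the
frame. Ground truth (organ ∪ lesion by default, lesion-only mode for
three-class experiments) is derived from the clean geometry *before*
noise, so truth masks are invariant to the noise model. Gaussian noise
is added per pixel, rounded and clipped to $[0, H-1]$ — clipping, not
wrapping, because real gray values saturate; salt-and-pepper noise
flips a Bernoulli fraction of pixels to 0 or $H-1$ with equal chance.

The phantom reproduces exactly the property that histogram thresholding
relies on — a multimodal gray-level mixture with known class geometry —
and deliberately nothing else: no MRI physics (sequence weighting, bias
fields, partial-volume effects), no anatomical shape realism, no
spatially correlated noise or texture. Passing the suite therefore
demonstrates correctness of the criteria, the optimizer and the metrics
under controlled mixtures; it does not certify segmentation quality on
clinical scans, where class overlap and intensity inhomogeneity violate
the bimodal model.

Default noise levels in the benchmark grid are sd
$\in \{0, 5, 10, 20, 40\}$ on the 8-bit scale; against the smallest
class-mean gap of 80 gray levels these range from trivial to
substantially overlapping mixtures. The ground-truth-recovery check
uses sd 15, keeping the gap above three noise standard deviations —
the regime where a correct threshold should misclassify only the far
Gaussian tails (mean DF against truth well below 0.02).

## Validation design

The suite is property-based, at these problem sizes: 500 seeded random
histograms for the algebraic identities (probability normalization to
$10^{-12}$, mean decomposition and variance conservation to $10^{-9}$)
and for ratio-vs-classic argmax equivalence; 200 histograms for
FA-vs-exhaustive agreement on the Otsu criterion and 50 on KSW; 20
seeded phantoms for ground-truth recovery; 20 seeds per cell for the
DF-vs-noise monotonicity of each method. Two histogram families are
used: bimodal Gaussian mixtures (the structure thresholding targets,
and what the phantoms produce) and a jagged family with independent
Poisson counts per level as a stress case with no smoothness at all.

Determinism is part of the contract: one seeded generator is threaded
through each run (the caller's RNG state is saved and restored), and
identical seeds reproduce phantoms, thresholds and benchmark tables
bit-identically; wall-clock runtime is reported in benchmark output for
orientation but never tested or compared, being hardware-dependent.

## Known limitations

* Binary thresholds only; multi-level ($k > 2$) and local/adaptive
  thresholding are out of scope.
* The FA searches one dimension; no claim is made about its behaviour
  on multi-dimensional objectives.
* GC depends on the ring radius; very thin structures can leave an
  empty ring at large radii.
* On a noiseless phantom the optimal threshold sits at the lowest
  occupied level of the gap (smallest-`x` tie-break), so thresholds
  below the background mean yield a degenerate all-foreground mask —
  the GC-peak comparison is only meaningful toward higher offsets
  there.
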