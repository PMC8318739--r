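# firethresh

Binary threshold segmentation of grayscale medical images, with the
threshold chosen by a fireworks-algorithm (FA) metaheuristic.

Histogram thresholding is the workhorse for separating an organ or
lesion from background in modalities like abdominal MRI: pick a cut
point `x` on the gray axis, label every pixel `<= x` background and
every pixel `> x` foreground. `firethresh` is for researchers who want
the classic criteria, a swarm optimizer over them, and a controlled
synthetic benchmark in one reproducible toolbox:

* the **Otsu variance-ratio criterion**
  `argmax_x σ_J²(x) / (σ_N²(x) + ε)` — between-class over within-class
  variance of the gray-level histogram (equivalent to the classic
  between-class-variance argmax, verified as a package invariant);
* the **KSW (Kapur–Sahoo–Wong) maximum-entropy criterion**
  `argmax_x H_0(x) + H_1(x)` as a comparator;
* an **exhaustive search oracle** over all `H − 1` candidates, and a
  **fireworks-algorithm optimizer** (`fao`) — fireworks emit uniform
  explosion sparks with fitness-dependent counts and amplitudes plus
  multiplicative Gaussian mutation sparks, with elitist
  distance-based selection — validated against the oracle;
* segmentation quality metrics: **DF**, the fraction of pixels whose
  labels change when the input is corrupted by noise (0 = perfectly
  noise-robust), and **GC** `= |d1 − d2| / (d1 + d2)`, the normalized
  contrast between the segmented region and its adjacent ring;
* a **synthetic liver-phantom generator** (background / parenchyma /
  lesion, Gaussian or salt-and-pepper noise, ground-truth masks) and a
  seeded **benchmark harness** comparing `otsu`, `ksw` and `fao`
  across noise levels, with PNG/TIFF input and CSV/JSON output.

See `vignettes/firethresh-methods.Rmd` for the full model description
and design rationale.

## Worked example

Segment a noisy synthetic liver phantom and score the result:

```r
library(firethresh)

spec <- phantom_spec(noise = "gaussian", noise_level = 15, seed = 7)
ph   <- generate_phantom(spec)                       # image + ground truth
res  <- segment_image(ph$image, method = "fao",
                      config = fa_config(seed = 7))

res$threshold                                        # 72
res$fitness                                          # 4.565869
exhaustive_best_threshold(compute_histogram(ph$image))$threshold  # 72
difference_function(res$mask, ph$truth)              # 0.003326416
regional_contrast(ph$image, res$mask)                # 0.5800808
```

The FA lands on threshold 72 — identical to the exhaustive Otsu oracle
— sitting in the gap between the background mode (mean 30) and the
parenchyma mode (mean 110) of the noisy histogram. Against the known
ground truth only 0.33 % of pixels are mislabeled (the far tails of
the sd-15 noise), and the segmented organ is well delineated: its mean
gray level differs from its surrounding ring by 58 % of their sum.

The same operations are available from the shell:

```sh
Rscript exec/firethresh phantom  --image ph.png --mask truth.png --seed 7
Rscript exec/firethresh segment  --input ph.png --method fao --seed 7 --output mask.png
Rscript exec/firethresh benchmark --methods otsu,ksw,fao --noise 0,5,10,20,40 --seeds 1:5 --csv bench.csv
```

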