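# discgabor

Unsupervised localization and segmentation of intervertebral discs
(IVDs) in mid-sagittal T2-weighted spine MRI, built on a complex 2-D
Gabor filter bank.  No training data, no user interaction: the filter
bank's orientation- and scale-selective responses drive every stage.

**Who it is for.** Researchers in spinal image analysis who need a
reproducible, dependency-light baseline for disc localization and
segmentation on single sagittal slices, and a synthetic-phantom test bed
with exact ground truth for validating such methods.

## The method

A bank of complex Gabor kernels

```
ψ(x, y; θ, ω) = 1/(2π σx σy) · exp{ −½[(x′/σx)² + (y′/σy)²] + i ω x′ },
x′ = x cosθ + y sinθ,  y′ = −x sinθ + y cosθ
```

with S = 16 directions θ_μ = μπ/S, K = 5 scales ω_v = ω_max/f^v
(ω_max = π/2, f = 2^¼), σx = 3k/ω_v, σy = 6k/ω_v (k = √(2 ln 2)), on a
31×31 window, filters the slice.  Pipeline (each stage a documented,
exported function):

1. **Spine curves** — the clipped difference of near-vertical minus
   near-horizontal direction-subset response means isolates the two
   spinal edges; a banded cumulative column sum locates the spine
   center, and each edge ridge is traced row by row
   (`compute_spine_gfi`, `find_centers`, `trace_curves`).
2. **Disc localization** — a disc-direction feature image is condensed
   by a 44×17 elliptical median filter; row/column profiles inside the
   spinal curves plus anatomical priors (adjacent-disc spacing 25–60 px
   ≈ 20–50 mm, common vertical alignment, tilt within ±30°) give coarse
   centers, boxes and tilts; centroid correction refines the centers
   (`localize_discs`).
3. **Disc segmentation** — per disc, a feature-bounded candidate region
   and an Otsu-initialized adaptive local threshold (bisection on an
   area window, ≤ 30 iterations) produce a coarse mask; morphological
   post-processing (hole fill, erode/dilate, 5-of-8 majority, largest
   component) finishes it (`segment_discs`).
4. **Evaluation** — localization accuracy (percent of centers inside
   the true disc), Dice = 2|M∩A|/(|M|+|A|), sensitivity |M∩A|/|M|,
   specificity (|I|−|M∪A|)/(|I|−|M|), and Euclidean center-distance
   statistics (`evaluate_phantom`, `dice`, `center_distances`).

A synthetic spine phantom (`phantom_generate`) with exact ground truth
— bright discs with annulus/nucleus/cleft structure, darker vertebrae,
optional noise, bias field and spinal curvature — makes the whole
pipeline testable offline.  See the methods vignette
(`vignettes/discgabor-methods.Rmd`) for the model, conventions, design
decisions and limitations.

## Worked example

```r
library(discgabor)

truth <- phantom_generate(phantom_spec(seed = 1))   # 512x256, 8 discs
res   <- run_pipeline(truth$image, truth = truth)
print(res$report)
#> Detections: 8 of 8 true discs; Acc = 100.00%
#> Center distance (px): mean 0.45, sd 0.45, median 0.32, max 1.52
#> Mean DSI 0.9998, Sen 0.9996, Spe 1.0000
```

All 8 discs are detected; every center lies inside its true disc
(accuracy 100%), centers are off by under half a pixel on average, and
the segmentation masks overlap the ground truth almost perfectly
(Dice 0.9998).  On the fixed-seed 20-phantom suite the pipeline reaches
accuracy 100% with mean center error 1.03 px and mean Dice 0.908
noise-free, and mean Dice 0.965 at Gaussian noise of 5% of the dynamic
range (`run_suite(n = 20, seed = 1)`).

`write_outputs(res, "out/")` writes `centers.csv`, a 16-bit label mask
`labels.pgm`, an `overlay.ppm` and `report.json`.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "discgabor", package = "discgabor"))')
Rscript $CLI phantom --seed 1 --out demo          # phantom + ground truth
Rscript $CLI run demo/phantom.pgm --out demo/out  # localize + segment
Rscript $CLI evaluate demo/out/labels.pgm demo/truth_labels.pgm
Rscript $CLI suite --n 20 --seed 1                # aggregate metrics
```

Inputs: PGM (8/16-bit), CSV/TSV, single-slice uncompressed NIfTI
(`.nii`, pixel spacing read from the header); PNG/TIFF work when a
`python` with Pillow is on the PATH.  Every method parameter can be
overridden through a flat `key = value` config file (`--config`).

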