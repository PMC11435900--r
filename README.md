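# l3seg

Rule-based, CPU-only segmentation of skeletal muscles in a single axial CT
slice at the third lumbar vertebra (L3), with the evaluation metrics and
synthetic phantoms needed to test it end to end without patient data.

## Why

The skeletal-muscle cross-sectional area at L3 is a standard imaging
biomarker for nutritional status in patients with cancer or sarcopenia.
Delineating it by hand is slow; deep-learning segmenters need large
annotated corpora and are hard to inspect. `l3seg` implements a lightweight
alternative built entirely from interpretable image-processing primitives —
Hounsfield-unit (HU) thresholding, Chebyshev distance-map isocontour
selection, convex-hull band extraction, adaptive Gaussian-peak double
thresholding, a vertebra-anchored bounding box and adaptive corner carving —
and segments the two muscle groups separately:

* the **abdominal wall band** (rectus + obliques + transversus, one class),
* the **paraspinal muscles** (psoas + quadratus lumborum + erector spinae,
  one class),

then combines them into the complete muscle mask. It targets low-dose
acquisitions and uses one parameterisation for plain and contrast-enhanced
series.

Predictions are scored against a reference mask `B` with the standard
overlap and boundary metrics

```
DSC(A,B)       = 2|A∩B| / (|A|+|B|) × 100%
precision(A,B) = |A∩B| / |A| × 100%
recall(A,B)    = |A∩B| / |B| × 100%
HD95(A,B)      = 95th percentile of the pooled directed minimal boundary
                 distances {min_b ||a−b||}_{a∈∂A} ∪ {min_a ||b−a||}_{b∈∂B}   [mm]
ASD(A,B)       = (Σ_{a∈∂A} min_b ||a−b|| + Σ_{b∈∂B} min_a ||b−a||) / (|∂A|+|∂B|)   [mm]
```

with multi-annotator consensus by per-pixel majority voting (a class wins a
pixel when at least two of three observers agree on it).

## Worked example

Every stage is testable against a synthetic L3 phantom with known
per-pixel ground truth:

```r
library(l3seg)

ph  <- generate_phantom(phantom_spec(seed = 1))   # 512x512, 1.27 mm spacing
seg <- segment_l3(ph$slice)
seg
#> <l3_segmentation> abdominal 3192 px, paraspinal 3928 px, combined 7120 px
#>              step  px_in px_out elapsed_ms
#>  global_threshold 262144  10553          3
#>      extract_body  10553  55363        260
#>       remove_skin  10553   8856         95
#>          branches   8856   7120        424

evaluate_case(seg, phantom_muscle_mask(ph$labels))
#> <metric_set> DSC 98.6%  precision 100.0%  recall 97.3%  HD95 0.00 mm  ASD 0.13 mm
```

The step log shows pixels in/out and wall time per stage (timing is
informational only). The metric set says the recovered muscle map overlaps
98.6% of the ground truth, every predicted pixel is muscle
(precision 100%), and the boundaries agree to 0.13 mm on average. The
adaptive threshold underlying the paraspinal branch can be inspected
directly:

```r
fit_peak_gaussian(ph$slice$pixels[ph$labels$pixels %in% c(3L, 4L)])
#> <histogram_fit> mu = 44.99 HU, sigma = 9.98 HU, band [30.02, 59.95] (k = 1.5, coverage 86.6%)
```

Real slices enter through `read_ct()` (single-frame DICOM, NIfTI-1, or the
package's two-channel HU PNG); masks through `read_mask()`/`write_mask()`
(PNG 0/255 or NIfTI uint8). A thin CLI wraps the same functions:

```sh
inst/cli/l3seg phantom -o demo --seed 1
inst/cli/l3seg segment demo/phantom.nii.gz -o demo/seg --dump-steps
inst/cli/l3seg evaluate demo/seg/combined.png demo/muscle_gold.png
inst/cli/l3seg vote o1.png o2.png o3.png -o consensus.png
```

See the vignette (`vignettes/l3-muscle-segmentation.Rmd`) for the full
method description, parameter table and design rationale.

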