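# lesionmorph

Morphological and texture feature extraction for grey-scale ultrasound
images of breast lesions with manually contoured boundaries, and two-group
statistical comparison of the resulting feature tables.

Atypical lesions are hard to classify by eye: their shape, margin and
internal echo descriptors overlap between benign and malignant disease.
`lesionmorph` quantifies those descriptors. From an 8-bit image plus a
lesion contour it computes eleven features per lesion:

| feature | definition |
|---|---|
| circularity | `C²/S` — squared boundary perimeter over area pixel count |
| height-to-width ratio | row extent / column extent of the circumscribed rectangle |
| margin spicules | low/high frequency mass ratio of the radial boundary spectrum, `Σ_{ω≤π/4} R(ω) / Σ_{π/4<ω≤π} R(ω)` |
| margin coarseness | cyclic mean absolute difference of successive radii `(1/N) Σ|d_i − d_{i+1}|` (px) |
| margin indistinctness | Σ of Sobel gradient magnitude `√(d_x²+d_y²)` over the boundary band (reported ÷10⁶) |
| margin lobulation | count of extrema of the radial profile after a cyclic median filter (window 21) and a degree-20 polynomial fit |
| energy | `Σ P(i,j)²` of the grey-level/gradient co-occurrence matrix (GLGCM) |
| entropy | `−Σ q_i ln q_i` of the GLGCM grey marginal |
| grey mean | `Σ g_i q_i`, normalised grey values in [0, 1] |
| calcifications | count of bright connected components inside the lesion after thresholding at `μ + α(max−μ)` and morphological closing |
| ALS | angle between the lesion long axis (direct least-squares ellipse fit) and the skin line, folded into [0°, 90°] |

Groups are compared feature by feature with two independent samples t-tests
(pooled by default, Welch optional), reported as mean ± SD per group with
two-sided p values at the 0.05 level.

Because clinical images cannot be redistributed, the package includes a
seeded phantom generator (`phantom_spec()`, `make_phantom()`,
`make_cohort()`) that plants ground-truth boundary harmonics (lobulation),
orientation, calcification counts and margin blur in speckled hypoechoic
lesions, so the entire pipeline is testable end to end.

## Worked example

Simulate a 30 + 30 cohort, extract all features from the written
images/contours, and compare the groups:

```r
library(lesionmorph)
dir <- tempfile("cohort")
ch  <- make_cohort(30, 30, seed = 42, dir = dir)
out <- run_batch(file.path(dir, "manifest.csv"))
compare_groups(out$features, out$features$group)
```

```
Two-group feature comparison (pooled t-test, alpha = 0.05)

           feature          benign      malignant        p sig
       circularity  15.649 ± 0.877 16.407 ± 0.862 1.31e-03   *
               hwr   0.611 ± 0.096  0.721 ± 0.090 2.55e-05   *
          spicules 43.614 ± 10.099 34.565 ± 6.253 1.02e-04   *
     coarseness_px   0.469 ± 0.055  0.495 ± 0.044 5.04e-02
 indistinctness_e6   0.117 ± 0.017  0.105 ± 0.011 2.20e-03   *
        lobulation   4.000 ± 0.000  5.733 ± 2.016 1.59e-05   *
            energy   0.146 ± 0.020  0.065 ± 0.016 8.97e-25   *
           entropy   1.714 ± 0.088  2.144 ± 0.041 4.95e-32   *
         grey_mean   0.395 ± 0.006  0.376 ± 0.008 1.24e-15   *
    calcifications   3.833 ± 1.663  2.667 ± 1.583 7.25e-03   *
           als_deg  10.392 ± 8.899  4.951 ± 3.648 2.99e-03   *
```

The default simulation profile plants more lobulation harmonics, fewer
calcifications and smaller long-axis angles in the malignant arm, and the
comparison recovers exactly those directions: higher `lobulation`, lower
`calcifications`, lower `als_deg` in the malignant column. (More interior
heterogeneity bands are also planted there, which is why `entropy` rises and
`energy` falls in this synthetic cohort.) A cohort-composition table ships
as a packaged fixture:

```r
summarize_pathology(read_pathology_counts())
```

```
Cohort composition (n = 206 )

benign (n = 174)
  Adenosis                              67   38.5%
  Benign phyllodes tumour                6    3.4%
  Fibroadenoma                          68   39.1%
  ...
malignant (n = 32)
  Intraductal carcinoma in situ         12   37.5%
  Intraductal papillary carcinoma        2    6.2%
  Invasive ductal carcinoma             18   56.2%
```

Percentages are within-group, rounded half-to-even to one decimal.

## Documentation

The methods vignette (`vignettes/lesion-morphometry.Rmd`) documents the
feature definitions and their numerical conventions (perimeter weighting,
the lobulation seam/prominence rules, GLGCM quantisation), the phantom
generator's scope and what passing tests do and do not establish about
clinical data, and the validation design with its problem sizes.
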