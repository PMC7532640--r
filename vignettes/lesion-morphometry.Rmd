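---
title: "Morphometry of contoured ultrasound lesions: models, conventions, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of contoured ultrasound lesions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionmorph)
```

## The problem

Breast lesions assessed on grey-scale ultrasound are routinely described by
shape (round vs. lobulated), orientation (parallel to the skin or not),
margin quality (smooth, coarse, spiculated, indistinct), internal echo
texture, and calcifications. `lesionmorph` quantifies these descriptors: from
an 8-bit grey image and a manually contoured lesion boundary it computes
eleven features per lesion and compares them between two groups
(conventionally benign vs. malignant) with independent-samples t-tests.

The unit of analysis is the `lesion_roi`: the image, the rasterized lesion
mask, the traced boundary (clockwise in image coordinates), the centroid, the
area pixel count `S` and the boundary pixel count `C`. Row 1 is the top of
the image; the first axis is depth (beam direction), the second lateral. The
skin line is assumed parallel to the top image edge, as with a linear probe.

## The eleven features

**Circularity** is `C^2 / S` with `C` the boundary perimeter and `S` the area
pixel count. The perimeter is the Euclidean length of the traced boundary
chain — diagonal steps count `sqrt(2)` — so a rasterized disc approaches the
continuous limit `4*pi ~ 12.57` from above (a step count of 1 per pixel would
undercount diagonal runs by 30% and make the measure depend on how boundary
segments align with the pixel lattice). Higher values mean a less circular,
more complex outline.

**Height-to-width ratio** is the row extent over the column extent of the
axis-aligned rectangle circumscribing the boundary, extents counted
inclusively (`max - min + 1`), consistent with the pixel-count semantics of
`S` and `C`. Values below 1 describe lesions wider than tall (typically
parallel-growing).

**Margin spicules** converts the boundary to a radial sequence
`(r_i, theta_i)` about the centroid and takes the magnitude spectrum of
`r`: with DFT bin `k` at `w_k = 2*pi*k/N` radians per boundary sample, the
feature is the spectral mass at `w_k <= pi/4` (DC included) over the mass at
`pi/4 < w_k <= pi`. Smooth boundaries concentrate mass at low frequency and
give large values; fine radiating structure raises the high-frequency mass
and lowers the ratio. A perfectly smooth boundary has zero high-frequency
mass: when the denominator falls below `1e-9` times the numerator the
overflow sentinel `Inf` is returned (written as `"inf"` in CSVs) rather than
an error, because smooth lesions are legitimate inputs. Note that with DC
included the feature scales with lesion size; it is kept literal because the
group comparison, not the absolute value, is the contract.

**Margin coarseness** is the cyclic mean absolute difference of successive
radii, `(1/N) * sum |d_i - d_{i+1}|` with `d_{N+1} = d_1`, in pixels: a
local roughness measure, zero for a constant-radius margin.

**Margin indistinctness** sums the 3x3 Sobel gradient magnitude over the
boundary band — all pixels within `band_width` (default 5 px) of a boundary
pixel, covering tissue just inside and outside the lesion. Sharp margins give
large values; blur lowers them monotonically. The feature table stores the
sum divided by 1e6. The band width is a package choice: the neighbourhood
must be wide enough to straddle the intensity transition after moderate blur
yet narrow enough to stay local; 5 px does both at typical lesion scales.
Border pixels use replicate padding, so constant images have exactly zero
gradient.

**Margin lobulation** counts undulations of the smoothed radial profile:
(1) cyclic median filter of window 21 samples (the boundary is closed, so
the filter wraps); (2) least-squares polynomial of degree 20 in normalised
position `t = i/N`, fitted on the sequence cyclically padded by the median
half-window (10 samples) and evaluated at the in-range positions; (3) count
of local maxima plus minima of the fitted values over the closed grid.

Two numerical choices here deserve explanation, because the naive pipeline
miscounts systematically:

* *Padding the fit window.* A polynomial fitted on `[0, 1)` has its largest
  error at the interval ends. Evaluated cyclically, that endpoint error
  splits the extremum nearest the seam into a max–min–max triple and adds a
  spurious extrema pair to every count. Fitting on the cyclically padded
  sequence moves the endpoint error outside the evaluated range.
* *Prominence.* A degree-20 polynomial has spare capacity beyond the planted
  oscillation and wiggles at amplitudes of order `0.005 * r0`; a
  zero-tolerance extrema count picks every wiggle up. Extrema are therefore
  counted with a hysteresis threshold of `min_prominence * median(r)`
  (default 0.02): an order of magnitude below any anatomically meaningful
  lobe (a lobe of relative amplitude `a` swings `2a * r0`, so even `a = 0.05`
  clears the threshold five-fold) and far above the fit wiggle. With these
  two rules, planted harmonics `r = r0 (1 + 0.1 cos(k*theta))`, `k = 2..8`,
  are recovered as exactly `2k` extrema in 20/20 noisy replicates at
  boundary-trace sampling density (`N ~ 2*pi*r0`); the degree-20 polynomial
  itself is the capacity limit near `k = 8`, where worst-case phases can
  still merge neighbouring extrema.

**Internal calcifications** are bright connected components inside the
lesion: pixels outside the mask are zeroed, the interior is binarised at
`T = mu + alpha (max - mu)` (interior mean and maximum; default `alpha = 0.5`,
the midpoint), the binary image is cleaned by morphological closing (dilation
then erosion) with a Euclidean disc of radius `struct_radius` (default 1),
components smaller than `min_blob_px` (default 4) are dropped, and the
8-connected component count is returned. Because `T` is defined relative to
the interior statistics the count is invariant to uniform brightness shifts.
Closing is kept in the stated dilate-then-erode order; opening (the
conventional speck remover) is available via `calc.morph_order = "open"`.
A constant interior returns 0 by construction.

**GLGCM texture features.** The grey level gradient co-occurrence matrix
`H(i, j)` counts interior pixels with quantised grey level `i` and quantised
Sobel gradient magnitude `j`; `P = H / sum(H)`. Grey levels map linearly from
the fixed range [0, 255] to `1..L_s`; the gradient is normalised per lesion
to its own interior maximum before mapping to `1..L_g` (machine gain settings
vary across scanners, so absolute gradient scales are not comparable). The
defaults `L_s = L_g = 16` make the entropy bound `ln 16 ~ 2.77` consistent
with entropy values near 2.2–2.4 observed for 8-bit ultrasound textures at
this quantisation. Three scalar features follow:

* *Energy* `sum P(i,j)^2`, in (0, 1], equal to 1 exactly for a homogeneous
  interior;
* *Entropy* `-sum_i q_i ln q_i` of the grey marginal `q_i = sum_j P(i,j)`,
  natural log, in `[0, ln L_s]`. The marginal (not joint) form is the
  contract; the joint entropy would need an explicit double sum over cells.
* *Grey mean* `sum_i g_i q_i` with `g_i = (i-1)/(L_s-1)` in [0, 1]; the raw
  level-index scale is available via `texture.gm_scale = "levels"`.

**Angle between long axis and skin (ALS).** The boundary is fitted with the
numerically stabilised direct least-squares ellipse (algebraic conic fit
under the ellipse constraint `4AC - B^2 = 1`), and the major-axis angle is
folded into [0, 90] degrees by the four-branch reflection `theta`,
`pi - theta`, `theta - pi`, `2*pi - theta`. The fold makes the measure
independent of axis direction and tracing orientation. For near-circular
lesions (`a/b < 1.05`) orientation is ill-defined; the value is reported but
carries a `low_confidence` attribute, which extraction records in the
`flags` column.

## Geometry conventions

Rasterization fills a contour polygon by pixel-centre inclusion: a pixel is
foreground when its centre lies strictly inside the polygon or exactly on an
edge. For hand-drawn integer contours this is the inclusive-boundary rule (an
axis-aligned square with corners 31 px apart fills 961 pixels); for dense
real-valued polygons almost no centre lies exactly on an edge, so the filled
area is an unbiased estimate of the polygon area (a 360-gon of radius 30
fills within 2% of `pi * 30^2`).

The boundary is traced with Moore neighbour tracing (Jacob's stopping
criterion) and oriented clockwise on screen; the traced chain equals exactly
the set of foreground pixels 4-adjacent to background. Masks whose chain
revisits a pixel (single-pixel-wide spurs or necks) are rejected as
degenerate rather than traced ambiguously. All geometric features are
translation invariant by construction.

## The phantom generator

Clinical images cannot ship with the package, so every feature is validated
on synthetic phantoms with planted ground truth. A phantom boundary is
`r(theta) = e(theta) * (1 + sum_k a_k cos(k*theta + phi_k))`, with
`e(theta)` the radial profile of an ellipse of geometric-mean radius `r0`,
axis ratio `a/b`, and planted orientation. The interior is darker than the
background (hypoechoic convention), optionally divided into concentric
intensity bands (the heterogeneity control for the texture features); the
margin can be Gaussian-blurred; bright discs of intensity 250 are planted as
calcifications by rejection sampling with pairwise separation at least
`4 * calc_radius`, which makes the planted count identifiable by
construction; and multiplicative Gaussian speckle `x(1 + eps)`,
`eps ~ N(0, sigma)`, is applied last. The interior is painted through the
same rasterization the analysis pipeline applies, so the contoured region
and the painted region agree pixel for pixel.

The speckle model is first-order only: it reproduces the intensity mean and
variance structure the features consume, not Rayleigh statistics,
log-compression, attenuation, or posterior acoustic effects. Passing tests
therefore demonstrate correct feature arithmetic and recoverability of
planted structure, not performance on clinical images.

`make_cohort()` draws per-lesion parameters from group-specific
distributions. The default effect profile plants the qualitative group
structure used throughout validation: the malignant arm draws higher-order,
larger-amplitude boundary harmonics (orders 5–6 vs. 2–3), fewer
calcifications (Poisson means 2.5 vs. 3.8), smaller long-axis angles
(half-normal SD 6 vs. 18 degrees), and more interior bands (4 vs. 2); both
arms share canvas 128 px, interior/exterior means 70/140, speckle 0.08, and
margin blur uniform on [0.5, 1.5] px. The `"null"` profile draws both arms
from the benign distribution and is the calibration instrument.

## Statistics

Group summaries are sample means and SDs (n−1 denominator); the two-group
comparison is the two independent samples t-test, pooled-variance Student by
default with Welch behind a flag, two-sided, significance at 0.05, and no
multiple-testing correction across the eleven features. Non-finite feature
values (the spicule sentinel) are excluded pairwise with logged counts; a
group left with fewer than two usable values flags the row instead of
computing it. Zero-variance degeneracies are resolved explicitly: equal
means give `t = 0, p = 1`; unequal means give `p = 0` with a `degenerate`
flag. Cohort-composition tables report within-group percentages rounded
half-to-even to one decimal.

## Validation design and problem sizes

The test suite validates each feature three ways: closed-form cases
(constant images, squares, discs, exact harmonics), independent brute-force
oracles (direct-summation DFT, per-pixel Sobel and GLGCM tallies, explicit
morphology plus flood fill, textbook t formulas), and planted-parameter
recovery (rotation within 2 degrees at twelve angles; lobulation `2k` for
`k = 2..8` in at least 90% of 20 noisy seeds; exact calcification counts in
20 seeds). Statistical behaviour is checked at desk scale, chosen as the
package's own validation conditions: type-I error on 200 zero-effect
cohorts of 10 lesions per arm on 96-px canvases (2,200 feature-tests,
nominal 5% within ±1.5 points), and power on 100 replicate cohorts of 100
lesions per arm, where the lobulation row — computed on the boundary-geometry
path, since lobulation uses only the contour — must be significant with the
malignant mean higher in at least 95 of 100 replicates. Planted-harmonic
sequences use `N = 720` samples, the density a traced pixel boundary of an
`r0 = 100` lesion actually yields (`~2*pi*r`).

## Known limitations

* Lobulation inherits the capacity limit of the degree-20 polynomial: beyond
  about 8 lobes (16 extrema against at most 19 turning points) counts
  saturate, and at `k = 8` adverse phases can merge extrema.
* The spicule ratio includes the DC term and so scales with lesion size;
  comparisons across cohorts with very different size distributions should
  interpret it with care.
* Boundaries are treated as star-shaped about the centroid for the radial
  features, as the clockwise pixel ordering implies; deeply folded lesions
  produce multi-valued radial profiles that are analysed in trace order, not
  re-parameterised.
* One comparison per feature, uncorrected: with eleven features, about one
  in two null cohorts shows a spurious significance somewhere.
* The generator does not model acoustic physics; see above for what passing
  tests do and do not establish.
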