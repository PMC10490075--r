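---
title: "Seed morphometrics with seedmorph: models, conventions, and limits"
author: "seedmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed morphometrics with seedmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedmorph)
```

## The measurement problem

Seed length, width, projected area (PA), and aspect ratio are routine
phenotyping traits in legume breeding: they discriminate genotypes,
predict seed weight, and feed yield models. Measuring them with calipers
is slow and error-prone at trial scale, so a common alternative is to
photograph seeds on a dark background and segment the bright silhouettes
from the image. `seedmorph` implements that classical fixed-threshold
pipeline end to end, together with the statistics used to validate one
measurement method against another, and a synthetic scene generator that
makes the whole chain testable without any photographs.

## The pipeline

For **measurement** the chain is:

1. convert the RGB image to grayscale (ITU-R BT.601 luminance,
   `0.299 R + 0.587 G + 0.114 B`, rounded half-up);
2. binarise with a fixed global threshold — foreground where intensity is
   *strictly greater than* the cutoff;
3. extract one contour per 8-connected foreground region;
4. keep the `n_seeds` largest contours by enclosed pixel count — small
   bright specks lose this competition, which is the pipeline's entire
   noise-rejection mechanism;
5. fit a rotated bounding rectangle per seed: the longer side is the
   length, the shorter the width, and their quotient the aspect ratio
   (always ≥ 1 by construction);
6. count each seed's pixels that survive a second, stricter threshold:
   the projected area;
7. divide lengths by the pixels-per-mm calibration and areas by its
   square.

For **counting**, the image is dilated before thresholding (a 3×3
neighbourhood maximum, one pass, by default) and the seed count is simply
the number of contours at or above the noise floor.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| size threshold | 140/255 | intensity | segments whole seed silhouettes for length/width |
| area/count threshold | 170/255 | intensity | stricter cutoff so faint background noise never registers in PA or counts |
| dilation kernel, passes | 3×3, 1 | px | solidifies silhouettes before counting; off by default for measurement |
| `n_seeds` | 1 | — | how many largest contours to measure per image |
| `min_contour_area_px` | 25 | px | belt-and-braces floor beneath any plausible seed (a 4 mm seed at 10 px/mm is ~1,250 px) |
| `px_per_mm` | from calibration | px/mm | two points a known distance apart, e.g. ruler marks 10 mm apart |

The two-threshold split mirrors established practice for this kind of
imagery: a permissive cutoff recovers the full silhouette for size
measurement, while area estimation and counting use a higher cutoff
because a single stray bright patch would otherwise register as a seed.
The threshold comparison is strictly greater (value = cutoff stays
background); dilation parameters are exposed because the convention in
the field's literature leaves them unstated.

## The bounding-rectangle convention

Two genuinely open choices had to be made.

**Rotated, not axis-aligned.** Seeds lie at arbitrary orientation; an
axis-aligned box inflates both sides for tilted seeds, so the default
rectangle rotates with the seed. The axis-aligned box remains available
(`rect_method = "axis"`).

**Principal axes, not strict minimum area.** The obvious rotated
rectangle is the minimum-area one (rotating calipers over the convex
hull). On rasterised shapes, however, its *orientation* is unstable:
spans of pixel centres fall short of the continuous silhouette by up to
1 px for axis-aligned directions but up to √2 px at 45°, so candidate
orientations are near-tied and ±0.5 px of lattice noise decides the
winner. For a low-eccentricity ellipse the winning rectangle can sit
tens of degrees off the true axes, mis-stating length and width by
several percent and the aspect ratio by over 10% — we measured up to 8%
side errors at 25 px/mm on 4–9 mm ellipses. The default therefore
orients the rectangle along the principal axes of the boundary point set
(eigenvectors of its second moments). For convex seed-like silhouettes
the principal axes coincide with the symmetry axes, and the estimator is
self-stabilising: orientation noise grows only as the shape approaches a
disk, exactly where orientation stops mattering. The strict minimum-area
fit is kept as `rect_method = "minarea"` for comparison.

Sides are reported as spans of boundary-pixel centres (the convention of
the mainstream contour libraries): they can read up to one pixel short
of the continuous shape, never long. At typical working resolutions
(≥ 10 px/mm) this bias is below 1%.

## Calibration

`make_calibration(p1, p2, known_mm)` converts two image coordinates a
known physical distance apart into a pixels-per-mm scale;
`px_to_mm()` and `px2_to_mm2()` are exact divisions, so mm → px → mm
round-trips are identities to floating precision. One ruler photograph
serves a whole session provided the camera geometry is unchanged.
Calibration files are flat `key = value` text so they diff and version
cleanly. Interactive point-picking is deliberately out of scope: the
two-point API plus the `calibrate` CLI keep the package headless and
testable.

## Method-comparison statistics

Validation against a reference method (calipers, or another program)
uses paired vectors of observed (`o`) and standard (`s`) values:

- RMSE = √( Σ(oᵢ−sᵢ)²/n )
- MAE = Σ|oᵢ−sᵢ|/n
- RSE = √( Σ(oᵢ−sᵢ)²/df ), with df defaulting to n−2, the residual
  degrees of freedom of a two-parameter linear fit (clamped at 1). The
  identity RSE = RMSE·√(n/df) always holds, and RSE is implemented
  *with* the square root — the definition that makes it commensurate
  with RMSE.
- percent forms divide each metric by the mean of the standard values ×
  100, since absolute errors are meaningless without the trait's scale;
- the "fit of plot" is ordinary least squares of observed on standard
  (closed-form normal equations; r² is the squared Pearson correlation),
  with 95% confidence and prediction bands available via `fit_bands()`.

These are exercised against hand-solved instances and `lm()`/
`predict.lm()` as independent oracles.

## What the synthetic generator emulates — and what it does not

`make_trial_grid()` renders batches of elliptical "seeds" with axes drawn
uniformly from 4–9 mm (the size span of typical soybean lots), at 25
px/mm, five per scene, randomly oriented, on a near-black (intensity 10)
background with foreground intensity 220 — bracketing both default
thresholds, like pale seeds on black cloth. Rasterisation is hard-edged
(a pixel belongs to a shape iff its centre does), so pixel-count oracles
are exact up to boundary discretisation. Speckle noise defaults to 5 px
blobs placed clear of the seeds — below the 25 px floor even after one
dilation pass, so default noise is harmless *by construction*; a hostile
mode (larger radius) deliberately breaks the floor to exercise failure
paths.

The generator does **not** emulate: texture or colour gradients within
seeds, shadows, specular highlights, lens blur or distortion, uneven
illumination, or seed-to-seed contact. A green test suite therefore
establishes that the geometry, thresholds, selection logic, calibration,
and statistics are correct — not that the fixed thresholds 140/170 are
appropriate for any particular camera setup; those remain an empirical
choice the user can override.

## Numerical and degenerate-input choices

- Coordinates are 1-based `(row, col)` pixel centres, the native R
  matrix convention (the spec of the original tool counts from 0; only
  the internal representation differs, no exported quantity depends on
  it).
- A single-pixel contour reports sides (1, 1); rectangle sides are
  clamped at 1 px.
- Ties in maximum-area selection break by scan order (first region
  encountered row-major), making selection deterministic and
  permutation-stable.
- Zero seeds is a valid counting result; a measurement run on an image
  with no contour above the floor is an error (`no seed found`).
- An overlapping seed pair merges into one contour and is counted as
  one: this limitation of the contour-count approach is pinned by tests,
  not hidden — no watershed declumping is attempted.
- CSV floats are written with exactly 4 decimals and LF line endings, so
  identical runs are byte-identical across platforms.

## Image I/O

The package reads and writes PNG (8-bit grayscale and RGB), binary
PGM/PPM, and uncompressed baseline TIFF with its own codecs (the PNG
zlib stream is handled by base R's `memCompress()`/`memDecompress()`),
keeping the dependency footprint at zero imaging libraries. JPEG is
rejected with a clear message — a DCT decoder is out of scope, and
measurement imagery should be lossless anyway.

## Known limitations

- Touching or overlapping seeds are merged (by design, see above).
- Fixed global thresholds assume controlled illumination and a dark
  background; no adaptive thresholding is provided.
- Length/width carry a ≤ 1 px downward bias from the centre-span
  convention; at very low resolution (< 5 px/mm) this becomes material.
- The empirical accuracy figures of any specific camera rig cannot be
  reproduced from synthetic scenes; the package validates the algorithm,
  not the photography.
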