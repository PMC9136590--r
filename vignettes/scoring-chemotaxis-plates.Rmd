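---
title: "Scoring quadrant chemotaxis plates from images"
author: "chemotax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring quadrant chemotaxis plates from images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemotax)
```

## The measurement model

A quadrant chemotaxis plate is a round assay arena: animals start at the
center, a test compound sits in one diagonal pair of quadrants and a
solvent control in the other, both laced with a paralytic so animals stay
where they first arrive. The behavioral readout is the chemotaxis index

$$ CI = \frac{A_\mathrm{test} - A_\mathrm{control}}
            {A_\mathrm{test} + A_\mathrm{control}} \in [-1, 1], $$

where this package measures $A$ as segmented **nematode pixel area** per
quadrant rather than an animal count. The area proxy is a deliberate
modelling choice: worms paralyzed at a compound spot pile into clumps
that defeat per-animal counting, while total covered area degrades
gracefully — a clump of five worms covers roughly five worms' worth of
pixels. The price is that the CI weights animals by body size; at the
developmental stage assayed (synchronized L4s) size variation is small
relative to the quadrant contrasts of interest. Animals still inside a
central exclusion disk never expressed a preference and are excluded
from the denominator; an all-zero denominator makes the CI undefined and
it is reported as `NA`, never silently as 0, because 0 would fake a
neutral response.

## Pipeline stages and their assumptions

1. **Plate detection** (`detect_plate`). The illuminated agar disk is
   assumed brighter than the surround. An Otsu threshold on the full
   frame, the largest connected bright component, hole filling, and an
   algebraic least-squares circle fit to its boundary give the center
   and radius with sub-pixel accuracy. A confidence gate (RMS radial
   residual ≤ 2% of the radius) turns non-circular fits into an error
   that points to the manual override (`plate_geometry()` passed
   directly, or `--center/--radius` on the command line) rather than a
   silently wrong geometry.
2. **Region map** (`build_region_map`). Two perpendicular lines through
   the center split the trimmed plate disk into quadrants numbered 1–4
   counter-clockwise from upper-right; the numbering and the default
   axis alignment with the image axes are package conventions (plates
   are photographed square in a holder), with `axis_rotation_deg` as the
   escape hatch. Boundary pixels are assigned by strict half-open
   angular intervals $[0°, 90°), [90°, 180°), \dots$ so every pixel has
   exactly one region and nothing is double-counted.
3. **Illumination flattening** (`preprocess`). Plate photographs carry a
   radial vignette that defeats a single global threshold. The
   background is estimated by grayscale morphological closing with a
   disc wider than a worm body — thin dark structures (worms, debris,
   spot-edge rings) vanish from the estimate *even when clumped*, which
   a plain median filter does not guarantee — followed by a median
   smoothing pass; the surround is pre-filled with the in-plate median
   so the dark background does not bleed across the wall. The flattened
   image is re-centered at 0.5 and clipped to $[0, 1]$.
4. **Segmentation** (`segment_foreground`). One global Otsu threshold
   computed from the plate-interior histogram only (the bimodality
   assumption holds inside the plate; outside pixels would corrupt it).
   Polarity is normalized first, so worms darker or brighter than agar
   are both supported and inverting image + polarity flag is an exact
   symmetry. A single-valued histogram yields an empty mask with a
   warning — a blank plate is a valid observation, not a crash.
5. **Object filtering** (`filter_objects`). Components are labelled with
   8-connectivity so thin diagonal worm bodies stay whole. Filters:
   area below `min_area_px` (default 0.2 × the expected single-worm
   area — debris), area above `max_area_px` (default 50 × — plate-scale
   artifacts, while even large worm clumps survive), and a spot-ring
   heuristic: components with perimeter²/area ≥ 60 **and** a
   hole-filled-to-raw area ratio ≥ 1.5 are hollow thin rings, the
   signature of the reflective edge of an unabsorbed compound droplet
   (a solid disc scores ~12.6 and ~1, a worm ~30–40 and ~1, a ring
   >100 and >2, so the joint cut separates cleanly; worm clumps that
   enclose no hole are kept). `ring_filter = FALSE` restores unfiltered
   behavior for parity runs. Every removed pixel is counted, so kept +
   filtered pixels reproduce the thresholded foreground as an exact
   integer identity — the suite asserts this invariant on every image.
6. **Scoring** (`measure_quadrant_areas`, `compute_ci`). Pixel sums per
   region; a component straddling a quadrant boundary contributes to
   both sides pixel-wise, consistent with the area-as-proxy principle.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `margin_frac` | 0.05 | fraction of radius | trims the plate wall and meniscus reflections |
| `center_exclusion_frac` | 0.15 | fraction of radius | origin zone excluded from the CI denominator; 0 counts every plate pixel |
| `axis_rotation_deg` | 0 | degrees | quadrant-axis rotation |
| `expected_worm_area_px` | 120 | px | scale anchor for all object filters |
| `min_area_px` / `max_area_px` | 0.2× / 50× expected | px | component size window |
| `ring_score_min` / `hollow_ratio_min` | 60 / 1.5 | — | spot-ring heuristic |
| `flatten_radius` | radius/40, ≥5 | px | median smoothing half-width |
| `threshold` | `"otsu"` | — | or a fixed value in (0, 1) |
| `test_pair` | {1, 3} | — | which diagonal pair received the compound |

The area thresholds are scale-relative on purpose: at twice the imaging
resolution, worm areas quadruple and the filters follow
`expected_worm_area_px` without retuning. Zone sizes are package
defaults, not measurements of any particular rig; both are plain
configuration.

## What the synthetic generator emulates — and what it does not

`generate_synthetic_plate()` renders: a bright plate disk on a dark
surround; a radial-quadratic vignette (`vignette_strength`, default 0.3
— the simplest model of edge illumination falloff); worms as
random-walk thick curves of ~`worm_area_px` (default 120 px at a
200 px plate radius) so that elongated shapes, not discs, exercise the
shape filters; blobs left inside the center zone; 3 px debris specks;
an optional hollow spot-edge ring; Gaussian pixel noise (`noise_sd`,
default 0.02); and either foreground polarity. The default plate holds
50 animals (17/4/17/4 per quadrant plus 8 in the center), matching a
50-animal dispense responding to an attractant with a true CI ≈ 0.6.
Placement is rejection-sampled so every blob lies wholly inside its
assigned region and blobs never overlap; ground-truth areas are
therefore *exact rendered pixel counts*, and a single seeded RNG stream
makes every image bit-reproducible.

Real plates differ in ways the generator does not model: agar texture
and condensation, partially transparent worms with soft edges, motion
blur, off-axis (elliptical) plates, and overlapping worms. Passing
tests therefore demonstrate that the pipeline's logic is correct and
self-consistent under controlled optics — not that any particular
laboratory rig will reach the same accuracy. On real images the
validation route is the one the statistics module implements: score a
strain panel both manually and automatically and examine the agreement
regression, its strain-effect ANOVA, and the heritability of the
resulting CIs.

## Method-agreement statistics

`fit_agreement()` regresses automated on manual CI by OLS and reports
slope, intercept and $R^2 = 1 - SSE/SST$ (equal to the squared Pearson
correlation; a zero-variance automated column is reported as
$R^2 = 0$). `strain_effect_anova()` compares
`automated ~ manual + strain` against `automated ~ manual` by
extra-sum-of-squares F-test; per-strain coefficients are reported
normalized to a reference strain (lexicographically first unless given
— in practice the N2 reference) with 95% confidence intervals, the
reference itself exactly 0 by construction.
`broad_sense_heritability()` fits the one-way random-effects model
`phenotype ~ 1 + (1|strain)` and reports
$H^2 = \sigma^2_\mathrm{strain} / (\sigma^2_\mathrm{strain} +
\sigma^2_\mathrm{res})$. The default backend is the balanced
method-of-moments estimator ($\hat\sigma^2_\mathrm{strain} =
(MS_B - MS_W)/n_0$, negative estimates truncated at 0 so $H^2 \in
[0, 1]$); `method = "reml"` fits the same model with `lme4::lmer`. On
balanced designs the two coincide in expectation, and the suite
cross-checks them against each other. The truncation makes the
method-of-moments $H^2$ slightly conservative near 0 and the ratio
nonlinearity biases it mildly downward (≈0.46–0.47 recovered at a true
0.5 with 11 strains × 9 replicates) — within the sampling noise of
panels this size.

## Numerical choices and degenerate inputs

* Ties on quadrant boundaries: half-open angular intervals, determinism
  over symmetry.
* The CI is computed in exact integer arithmetic up to the final
  division; injecting the generator's true mask and geometry reproduces
  the true CI to floating-point equality.
* Results files print CIs with 17 significant digits, so a round-trip
  through `read_results()` restores the doubles exactly and two runs of
  the same configuration are byte-identical.
* Degenerate inputs error early and specifically: no-contrast images at
  detection, single-strain heritability, zero-variance manual CIs,
  aliased strain terms. A blank plate (empty mask) is the one degraded
  case handled with a warning instead, because it is a legitimate assay
  outcome.
* Failures in batch scoring are isolated per image: an unreadable file
  becomes an `NA` row and a nonzero exit code while the rest of the
  batch completes.

## Verification problem sizes

The shipped verification uses 100 seeded plates for the exact-CI
oracle, 50 full-pipeline plates for CI recovery (|CI − truth| ≤ 0.05 on
≥90%), 50 plates spanning ±25 px translations, 150–230 px radii and
0–0.6 vignettes for detection accuracy (≤2 px center, ≤2% radius), 1000
replicates for the ANOVA type-I error (5% ± 2%) and 200 seeds for H²
recovery at a simulated 0.5 — sizes at which the binomial/Monte-Carlo
error of each check is comfortably below its acceptance band. Unit
tests run the same logic on 256 px plates.

## Known limitations

* One plate per image, roughly centered, circular (no tilted-camera
  ellipse model).
* No worm counting, clump splitting, pose estimation or tracking — out
  of scope by design.
* The spot-ring filter assumes the artifact survives thresholding as a
  *hollow* thin component; a ring broken into small arcs is instead
  caught by the minimum-area filter, but a ring fused with a worm clump
  would be kept. Adjusting plate illumination so spots do not reflect
  remains the upstream fix.
* Otsu assumes some foreground; on a plate with a single worm the
  threshold still separates it after flattening. A truly empty noisy
  plate has no object/background separation at all — the automatic
  threshold would split the noise in half — so segmentation detects
  the condition (foreground would flood >30% of the plate), warns, and
  returns an empty mask; the plate scores CI `NA`, the correct reading
  of an empty plate. A fixed numeric threshold bypasses the guard.
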