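---
title: "Methods: TIF quantification, co-localization inference, and limiting-dilution frequency estimation"
author: "telofoci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIF quantification, co-localization inference, and limiting-dilution frequency estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telofoci)
```

# Scope

`telofoci` covers the image-analysis chain for scoring telomere
dysfunction-induced foci (TIFs) — nucleus segmentation, per-channel Otsu
thresholding, Manders co-localization with a block-scramble permutation
null, per-cell focus/TIF counting and group statistics — and the
limiting-dilution analysis that converts transplantation dose-response
tables into functional stem-cell frequencies. A synthetic-data generator
provides images and assay tables with exact ground truth; it is a
first-class, tested component, not a fixture.

# The imaging model and its conventions

## Segmentation and thresholding

All focus analysis is restricted to nuclear regions identified from the
nuclear-stain channel (TOTO3/DAPI in practice). `segment_nuclei()`
Otsu-binarizes the blue channel over the whole frame, fills holes, labels
components and drops those below `min_nucleus_area`. Conventions, fixed
once and used everywhere:

* **Otsu's threshold** maximizes between-class variance over a 256-bin
  histogram spanning the observed min–max of the intensities inside the
  region of interest. Ties take the lowest maximizing threshold.
  Foreground is *strictly greater than* the threshold; either inequality
  convention is defensible, but bit-exact tests require fixing one.
  A constant region has no threshold and raises a degenerate-input error
  (the segmentation wrapper converts it to "no nuclei" with a warning).
* **Connectivity is 8** (diagonal neighbors connect), for nuclei and foci
  alike. Two nuclei whose rendered masks touch merge into one component;
  no watershed splitting is attempted.
* **Hole filling** applies to nuclei only, never to focus masks, whose
  areas would otherwise be distorted.
* Focus channels are thresholded per image within the **union of nuclear
  masks**, not over the whole slide, since everything outside nuclei is
  excluded from analysis anyway.

`otsu_threshold()` returns both the binary map and the retained
intensities (original value where foreground, 0 elsewhere); downstream
code treats "above threshold" and "> 0 retained intensity" as synonyms.

## Manders coefficients

`manders_coefficients()` computes, over the pixels of a mask,

$$M_1 = \frac{\sum_i G_{i,\mathrm{coloc}}}{\sum_i G_i},\qquad
  M_2 = \frac{\sum_i R_{i,\mathrm{coloc}}}{\sum_i R_i},$$

with $G_{i,\mathrm{coloc}} = G_i$ if $R_i > 0$ and zero otherwise
(symmetrically for $R$), where $G_i, R_i$ are the *thresholded*
intensities. Because the two channels generally occupy different numbers
of pixels, $M_1 \ne M_2$ in general. A channel with no above-threshold
signal in the mask makes its coefficient undefined; the package reports
`NA`, never 0 — "no signal" and "no overlap" are different findings.

## The block-scramble permutation null

Scrambling individual pixels destroys the local spatial correlation that
blurred, punctate foci impose on neighboring pixels, and therefore
overstates the significance of any observed overlap. `coloc_test()`
instead tiles the frame into square blocks of side `block_size_px`
(chosen to approximate a focus footprint; the worked defaults use 7 px
for foci of radius 2.5–3 px with a 1 px blur), at a fresh uniformly
random offset each iteration so no fixed block frame leaves its imprint.
Same-shape blocks are permuted uniformly at random, independently in the
two channels, carrying their retained intensities; the coefficients are
then recomputed restricted to the mask. The empirical p-value uses the
add-one estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(n_{\mathrm{perm}}+1)$,
which can never return 0, and ties count toward the tail — both choices
conservative.

Two scrambling scopes exist:

* `scope = "image"` permutes blocks across the whole frame. This is the
  simplest reading of restricting *analysis* (not scrambling) to nuclei.
* `scope = "mask"` permutes only blocks lying entirely inside the nuclear
  mask, so foreground stays confined to nuclei under the null.

When foci are confined to nuclei but scrambling can relocate them over
the whole frame, the null spreads signal over a larger area than the data
ever occupy; the observed coefficients then beat the null for a purely
geometric reason (concentration), inflating rejection far beyond nominal.
Calibration studies in this package therefore use `scope = "mask"`;
`"image"` remains the default for exploratory use because it matches the
minimal description of the procedure, and the choice is always recorded
in the result object.

For cohorts of images, `cohort_welch()` compares observed coefficients
with the per-image null means. The phrase "Welch's paired *t*-test" that
circulates for this comparison is internally contradictory — Welch's
correction applies to unpaired unequal-variance tests — so the function
reports both the paired t on per-image differences and the unpaired Welch
statistic, labeled as such, and presents neither as canonical.

## TIF identification and group statistics

A TIF is a green (telomere-marker) focus component co-stained by the red
(damage-marker) channel: `count_tifs()` counts green components of at
least `min_focus_px` pixels whose overlap with red foreground is at least
`min_overlap_px` (default 1 px — the minimal faithful reading of
"co-stained"; the threshold is exposed). The size filter applies to TIF
candidates exactly as it does in `count_foci()`: a single above-threshold
noise pixel is not a focus, and counting it as a TIF would otherwise let
the TIF count exceed the focus count. Whether co-staining should instead
be defined by centroid distance is not resolvable from the available
description; component overlap is implemented, centroid matching is not.

Per-cell counts are summarized as mean ± SD with n = cells, and compared
with a two-tailed pooled-variance Student's t-test for two groups
(Welch's available by flag) or one-way ANOVA followed by Tukey's HSD for
more. Zero-variance two-group degeneracies return a documented result
(statistic 0/p 1 on equality, infinite statistic otherwise) rather than
an error.

# The synthetic-data generator

`simulate_field()` emulates interphase cells spread on a slide and imaged
in three channels:

* **Nuclei** are filled disks of radius `nucleus_radius_px` (default
  40 px, roughly a 4 µm-radius nucleus at ~0.1 µm/px; the optics are not
  claimed to match any particular instrument and every dimension is
  configurable). Centers are rejection-sampled with pairwise distance
  > 2r, so nuclei never overlap; failure after bounded attempts raises a
  placement error naming the offending parameters.
* **Foci** are disks of radius `focus_radius_px` (default 3 px) at
  amplitude `focus_amplitude` over `background_level`, convolved with an
  isotropic Gaussian PSF (`psf_sigma_px`, kernel truncated at 3σ),
  additive over background. Additive Gaussian noise (`noise_sd`) is
  applied and intensities clip at zero. Poisson shot noise, spectral
  bleed-through, photobleaching and 3-D structure are deliberately out of
  scope: one noise knob suffices to stress the pipeline.
* **Ground truth**: `round(colocal_fraction × foci_per_nucleus_green)`
  green foci per nucleus share centers *exactly* with red foci — identical
  centers, not mere overlap, so truth labels are unambiguous. The
  per-nucleus true TIF count is that pair count by construction.
* **Spacing**: non-paired foci keep `min_focus_sep_px` apart (default:
  two rendered footprints plus 2 px), so distinct foci never merge and
  planted counts are exactly recoverable.
* **Containment vs uniformity** (`focus_margin_px`): by default focus
  centers keep one rendered footprint inside the nuclear boundary, which
  guarantees every focus pixel lies in its nucleus — the right regime for
  count-recovery studies. That margin concentrates foci toward the
  nucleus center, which is *not* the right regime for calibration of the
  permutation test: a null world of "independently placed foci" must
  place them uniformly over the region within which the null scrambles.
  Setting `focus_margin_px = 0` draws centers uniformly over the whole
  disk (a little blur energy spills past the boundary). Calibration
  studies use margin 0 with near-zero separation; recovery studies use
  the defaults.

`simulate_lda_table()` draws limiting-dilution outcomes: at dose $d$ each
of `n_per_dose` recipients responds with probability $1 - e^{-f d}$,
binomially. Both generators are bit-reproducible under their seed, and
restore the caller's RNG state.

What passing tests on this generator do **not** show: robustness to
irregular nucleus shapes, uneven illumination, autofluorescence texture,
overlapping nuclei, or chromatic misregistration. The generator validates
the *statistics and bookkeeping* of the pipeline, not its performance on
difficult real slides.

# The limiting-dilution model

With $f$ the frequency of active cells, a recipient of $d$ cells carries
no active cell with probability $e^{-fd}$ (single-hit Poisson), so

$$\operatorname{cloglog} P(\text{response}) =
  \log(-\log(1 - P)) = \log f + \log d.$$

`lda_fit()` fits this as a binomial GLM with complementary log-log link
and `log(dose)` offset (the generalized-linear formulation standard for
extreme limiting-dilution analysis); the intercept estimates $\log f$.
Numerical choices:

* **CI**: Wald interval on $\log f$ by default (determinate, always
  available); profile likelihood by `ci_method = "profile"`, falling back
  to Wald if profiling fails. GLM convergence tolerance is tightened to
  `1e-12` so single-dose fits agree with the closed form
  $\hat f = -\ln(\text{negative fraction})/d$ to ~1e-15 relative.
* **Zero-negative doses** are informative and stay in the likelihood — no
  0.5-type corrections; they are flagged in the result and drawn as
  downward-pointing triangles on the fitted line in `plot()` (a display
  convention only, since $\ln 0$ is undefined).
* **Boundary cases**: all recipients responding bounds $f$ only from
  below; none responding bounds it only from above (closed form
  $-\ln\alpha / \sum n_i d_i$). Both return one-sided results with an
  explicit `status`, never a point estimate.
* **CRU**: "competitive repopulation units" are reported as total cells
  transplanted × $\hat f$ — an interpretation, labeled as such, since no
  standard formula accompanies the term.

`lda_compare()` tests equality of two frequencies by likelihood ratio
(group term on the intercept vs a shared intercept); the deviance
difference is clamped at 0 before the $\chi^2$ tail so identical groups
return p = 1 rather than NA. The fold enrichment is the ratio of the two
estimates; when one group is unidentified the fold degrades to a labeled
one-sided bound.

# Problem sizes used in the test suite

The suite exercises every property at sizes a laptop handles in about a
minute: oracle equivalence on 1000 random grids up to 16×16; conservation
over 10^4 scrambles; calibration on 200 null fields of 96×96 px with 3
nuclei and 199 scrambles each; power across co-localized fractions
{0, 0.5, 1} at 50 fields each; TIF recovery on 100 fields of 160×160 px;
CI coverage and fold-enrichment recovery on 500 simulated assays at
$f = 1/100$, doses {20, 50}, 24 recipients per dose (matching the scale
of real limiting-dilution transplant designs). These sizes are the
package's chosen study conditions; all are parameters, not constants.

# Known limitations

* Disk nuclei and Gaussian-blurred disk foci are idealizations; the
  pipeline has no shape priors, but its *validation* inherits them.
* `scope = "image"` scrambling is anti-conservative whenever signal is
  confined to a sub-region of the frame; use `scope = "mask"` for
  inference and treat the default as exploratory.
* The component-overlap TIF definition can merge two touching green foci
  into one; the enforced separation in synthetic data sidesteps this, and
  real overlapping foci would be undercounted.
* The asymptotic Wald CI undercovers for very sparse responder counts;
  profile intervals help, exact small-sample methods are out of scope.
* The Tukey step assumes homoscedastic groups, as does the pooled t; the
  Welch flag covers unequal variances for two groups only.
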