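---
title: "Intra- and inter-phantom variability of mammography QC metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intra- and inter-phantom variability of mammography QC metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomqc)
```

## The problem

Mammography quality control relies on test plates ("phantoms") whose embedded
details — low-contrast discs, high-contrast microcalcification-like dots, a
resolution grating and step wedges — are measured repeatedly to monitor
image quality. Two variance sources affect every such metric:

* **intra-phantom variability**: the scatter of repeated measurements of one
  plate (quantum and electronic noise, manual repositioning between
  exposures, residual ROI placement effects), and
* **inter-phantom variability**: systematic differences between nominally
  identical plates (manufacturing tolerances on detail contrast, placement
  and particle coating).

If plates of one model differed only negligibly, any plate could stand in
for any other when comparing imaging systems. `phantomqc` provides the full
machinery to study this question synthetically: a renderer with a known
two-level variance structure, an automated extractor for the standard 64
image-quality metrics of a TORMAS-type semicircular plate, and the
variance-component analysis that splits each metric's dispersion into
within- and between-phantom parts.

## The measurement model

A measurement of metric $m$ on phantom $p$, repeat $r$, is modelled as

$$ y_{p,r,m} = \mu_m + b_{p,m} + e_{p,r,m}, \qquad
   b_{p,m} \sim N(0, \sigma^2_{\mathrm{inter},m}), \quad
   e_{p,r,m} \sim N(0, \sigma^2_{\mathrm{intra},m}), $$

with all effects independent. The analysis estimates, per metric,

* $\hat\sigma^2_{\mathrm{intra}}$: the unweighted mean over phantoms of the
  per-phantom sample variance of repeats ($n-1$ denominator) — with equal
  repeat counts this is the pooled within-phantom estimator;
* $\hat\sigma^2_{\mathrm{inter}}$: the sample variance across phantoms of
  the per-phantom means;
* the total $\hat\sigma^2 = \hat\sigma^2_{\mathrm{intra}} +
  \hat\sigma^2_{\mathrm{inter}}$, and percent contributions
  $100\,\hat\sigma^2_{\mathrm{intra}}/\hat\sigma^2$ and
  $100\,\hat\sigma^2_{\mathrm{inter}}/\hat\sigma^2$, which sum to 100
  exactly;
* coefficients of variation, as percentages of the grand mean.

Two deliberate conventions deserve comment.

**No ANOVA correction.** The variance of phantom means contains a residual
within-phantom term: $E[\hat\sigma^2_{\mathrm{inter}}] =
\sigma^2_{\mathrm{inter}} + \sigma^2_{\mathrm{intra}}/n_{\mathrm{rep}}$.
A one-way ANOVA would subtract $\hat\sigma^2_{\mathrm{intra}}/n_{\mathrm{rep}}$;
the analysis here intentionally reports the raw variance of phantom means,
matching how such studies tabulate their components. The bias is small
whenever the between-phantom component dominates (at
$\sigma_{\mathrm{intra}}=1$, $\sigma_{\mathrm{inter}}=3$,
$n_{\mathrm{rep}}=10$ the expectation is $9.1$ rather than $9$), and the
parameter-recovery test quantifies it exactly.

**Two intra-COV conventions.** `decompose()` defaults to the *per-phantom*
convention — the mean over phantoms of $100\,s_p/\bar y_p$ — and also offers
the *grand-mean* convention $100\,\hat\sigma_{\mathrm{intra}}/\hat\mu$. The
two differ slightly (the per-phantom form is usually a little lower, and
only the grand-mean form satisfies the exact quadrature
$\mathrm{COV}^2_{\mathrm{total}} = \mathrm{COV}^2_{\mathrm{intra}} +
\mathrm{COV}^2_{\mathrm{inter}}$); published per-metric COV tables for this
plate type are mutually consistent only under the per-phantom reading, hence
the default. Both are exposed via `cov_intra_convention`.

## Defective-phantom screening

Before decomposition, each metric's per-phantom means are screened against
their grand mean; a phantom deviating by more than $k = 3$ standard
deviations (taken, by default, across the phantom means) on *any* metric is
excluded entirely. The screen is one-pass — no re-iteration after exclusion.

Two statistical properties of this classical rule are worth knowing, and the
package's tests document both:

* **Masking.** The outlier inflates the very SD it is compared against
  (the variance grows by roughly $\Delta^2/n$ for a shift $\Delta$ at $n$
  phantoms), which caps the attainable studentized deviation at
  $(n-1)/\sqrt{n}$ — about 4.7 at $n = 24$. A "5 SD" defect therefore lands
  near 3.4 contaminated SDs; the bundled defect emulations inject 8-SD
  shifts to sit comfortably above threshold.
* **False positives.** With 64 approximately independent Gaussian metrics
  and 24 phantoms, roughly 1.2 healthy phantom-metric pairs per table are
  expected beyond 3 SD, so screening a fully independent synthetic table
  excludes *only* the seeded defects in only about a third of realizations.
  Real plates behave better: their metrics are strongly correlated within a
  phantom (one contrast multiplier moves a whole detail series), which
  shrinks the effective number of independent tests. This is a genuine
  property of the rule, not of its implementation, and it is the reason the
  defect-screening acceptance check can fail on an unlucky seed even though
  both seeded defects are always detected.

## The synthetic phantom generator

`default_layout()` describes the plate in plate-centred millimetre
coordinates (x rightward, y downward, flat edge along $y = 0$): 12
low-contrast 5.6-mm discs, 11 + 11 high-contrast 0.5/0.25-mm discs (each
series decreasing geometrically, spanning roughly the CNR dynamic range
reported for the physical plate), 26 bar patterns log-spaced over
(1, 20] lp/mm (~5 mm wide so that variance estimates average over several
whole periods), a ten-step uniform wedge whose nominal contrasts are the
published step contrasts (95.24% down to 15.50%), and three five-step
particle wedges (median diameters 328/234/125 um) whose steps match uniform
steps 1-5 in base contrast and carry increasing particle attenuation depth.

`render_phantom_image()` evaluates the scene analytically at pixel centres
(discs and particles with one-pixel anti-aliasing; gratings integrated over
the pixel aperture along the modulation axis — point sampling would alias
high odd harmonics of the square wave back into the pass band), applies a
rigid repositioning transform, convolves with a Gaussian PSF, and adds
Gaussian-approximated Poisson noise (variance equal to the photon part of
the local mean) plus electronic noise, quantized to 16 bits.

Key parameters, defaults, and rationale:

| parameter | default | rationale |
|---|---|---|
| `pixel_pitch` | 0.1 mm | representative of the acquiring detector class |
| `blur_sigma` | 0.1 mm | places the 50%...5% MTF thresholds inside the sub-Nyquist band at the default pitch |
| `photon_level` | 40000 counts | high-dose acquisition conditions; keeps the unattenuated region within 16 bits |
| `electronic_noise_sd` | 15 counts | small relative to quantum noise, as on modern detectors |
| `repositioning_translation_sd` / `rotation_sd` | 1 mm / 0.5 deg | "small" manual repositioning; no quantitative tolerance is published, so these are plausible placeholders |
| `manufacturing_cv` (population) | user-set | no manufacturing tolerances are published; the structural-ordering study uses 0.2 (see below) |
| placement `jitter_sd` | 0.05 mm | sub-pixel manufacturing placement scatter |

Two-level structure by construction: contrast multipliers, placement jitter,
particle-density multipliers and the frozen particle texture are drawn once
per phantom (the texture stream is keyed by the phantom id, so structured
noise is a phantom property); the repositioning draw and the noise fields
are keyed by (phantom, repeat). Every output is a pure function of the seed
and these identifiers.

For strongly attenuating elements (wedge steps, bars, particle-step bases)
the manufacturing multiplier acts on the attenuation exponent — realized
contrast $1-(1-c)^m$ — so transmission stays in (0, 1) however large the
draw; for the faint discs the linear form $c\,m$ is kept, which makes
defect semantics (swap, scale) exact.

**What the generator does not emulate:** X-ray spectra and scatter, the heel
effect, detector MTF beyond a Gaussian PSF, DICOM semantics, and any
correlation between metrics beyond what shared multipliers induce. Passing
tests therefore demonstrate the correctness and calibration of the
*pipeline*, not that real plates have the simulated variance levels.

## Metric extraction

`register_template()` recovers the plate pose without iterative matching:
the plate is segmented by thresholding midway between the plate level
(median) and the brighter unattenuated surround (95th percentile); the
centroid of the semicircular mask sits $4R/3\pi$ from the circle centre
along the symmetry axis, giving the translation, and the principal axes of
the mask give the rotation. With on the order of $10^6$ plate pixels both
estimates are far below the pixel/degree level, and a bimodality-plus-area
check rejects degenerate images.

* **CNR, 5.6-mm discs** — plain ROI statistics: concentric detail ROI at
  70% of the detail diameter, background annulus beyond a 1-mm guard gap,
  `|mean(detail) - mean(bg)| / sd(bg)`. Undefined (flagged) on noiseless
  images.
* **CNR, 0.5/0.25-mm discs** — a matched filter: the expected noiseless
  detail profile (anti-aliased disc indicator under the fitted transform,
  blurred with the assumed PSF) is used as weights on the
  background-subtracted patch. The template is kept at unit contrast depth,
  so the estimate returns the detail's pre-blur contrast depth; this
  convention is insensitive to where the detail centre falls within a pixel
  (a peak-normalized template would inherit several percent of sub-pixel
  sampling jitter).
* **MTF** — the noise-corrected variance (Droege-Morin) estimator on each
  bar pattern: $M(f) = \sqrt{\max(0, s^2_{\mathrm{bar}} -
  s^2_{\mathrm{noise}})}$, normalized by half the bright-dark reference
  difference and scaled by $\sqrt2$, clipped at 1.2. The square-wave output
  is used as-is (no Coltman sine correction), which makes the unblurred
  limit $\sqrt2$ (clipped) rather than 1 — self-consistent for
  threshold-frequency readouts. Bar ROIs are trimmed to whole periods clear
  of $3\sigma$ blur margins on all sides; frequencies whose period falls
  below two pixels are flagged beyond-Nyquist. Summaries: trapezoidal area
  over the valid band, and threshold frequencies at 50/20/10/5% located by
  linear interpolation at the first downward crossing (undefined if the
  curve starts below or never falls below the fraction — the orderings
  $f_{50\%} \le f_{20\%} \le f_{10\%} \le f_{5\%}$ then follow
  automatically).
* **Step contrast** — $100\,(\bar B - \bar S)/\bar B$ with inset square
  ROIs and each step's adjacent background; positive for attenuating steps
  and exactly invariant under global intensity scaling.
* **Noise ratio** — pixel variance in a particle step over the variance in
  the uniform step of matching nominal contrast; near 1 when structured
  noise is absent.

The closed-form oracle used to validate the MTF chain is the odd-harmonic
series of the square wave, each harmonic attenuated by the Gaussian MTF
$e^{-2\pi^2\sigma^2 f^2}$ *and* the pixel-aperture sinc, recombined as the
variance estimator measures it. Agreement is required within 5% below half
the Nyquist frequency.

## Study configuration for the structural-ordering run

The full synthetic study (22 phantoms x 10 repeats at the default
acquisition settings) checks two qualitative reproductions: the
between-phantom share exceeds 50% for every metric, and the repeat COV of
the low-contrast CNR details exceeds that of the high-contrast ones. The
manufacturing CV for this run is 0.2, fixed in advance by a calibration
pilot: with manufacturing variation switched off, the median intra-phantom
COV across the 64 metrics (repositioning plus noise) is about 2%, and the
run condition requires the manufacturing CV to be at least three times the
repositioning-induced CV. The faintest 0.25-mm details are the binding
constraint — their purely noise-driven repeat COV reaches ~11% at the
default dose, which is also why the high-dose photon level is part of the
study conditions.

## Numerical choices and degenerate inputs

* All RNG streams are derived from 31-bit hashes of (seed, phantom id,
  repeat, purpose); generators never disturb the caller's RNG state.
* Noiseless, unblurred rendering reproduces nominal contrasts to better
  than $10^{-9}$ relative before quantization.
* ROI membership is by pixel-centre inclusion; indices are 1-based
  row-major in R with a recorded mm origin.
* Zero background SD, zero grand mean, a never-crossing MTF curve, or a
  phantom missing more than 20% of its repeats for a metric all yield
  flagged undefined values rather than errors; blank or separation-free
  images raise a registration-failure error.
* Variance decomposition requires at least 2 phantoms and 2 repeats per
  phantom; the screen requires at least 3 phantoms.

## Problem sizes used by the test suite

The unit tests render at 0.25- and 0.15-mm pitch to keep single images
small; the MTF oracle and the structural-ordering study run at the default
0.1-mm pitch, the latter over the full 22 x 10 design. The
parameter-recovery check uses 200 replicates of the 22 x 10 two-level
simulation. The acceptance script's image pathway uses 6 phantoms x 4
repeats at 0.15-mm pitch.

## Known limitations

* Absolute metric values are not comparable to published means for the
  physical plate: the real extraction software's ROI geometry and weighting
  are proprietary, and the renderer is not a radiographic simulation. Only
  structural and ordering behaviour is expected to transfer.
* The Gaussian-Poisson noise approximation understates skewness at very low
  counts (irrelevant at mammographic dose levels).
* The one-pass outlier rule inherits the masking and false-positive
  behaviour described above; an iterated or robust (e.g. MAD-based) screen
  would behave differently and is intentionally out of scope.
* Repositioning and manufacturing tolerances are plausible placeholders,
  not published facts; conclusions about their relative size on real plates
  require the real measurement tables.
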