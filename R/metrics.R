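# The image-quality metric operators: CNR of large and small details,
# Droege-Morin bar-pattern MTF and its summaries, step-wedge contrast, and
# structured-to-quantum noise ratio.

#' Metric-extraction options
#'
#' ROI geometry and numerical settings of the metric operators. The defaults
#' mirror the default acquisition model: `blur_sigma` is the PSF width
#' assumed when building matched-filter templates for sub-ROI details and
#' when trimming bar-pattern ROI margins.
#'
#' @param blur_sigma Assumed Gaussian PSF width, mm.
#' @param inner_frac Detail ROI diameter as a fraction of the disc diameter
#'   (large-disc CNR).
#' @param guard Guard gap between detail edge and background annulus, mm.
#' @param annulus_width Background annulus width, mm.
#' @param small_guard Extra guard beyond `3 * blur_sigma` for small-detail
#'   annuli, mm.
#' @param roi_inset Inset of square-step ROIs from the step edge, mm.
#' @param mtf_cap Upper clip for MTF values (square-wave estimates exceed 1
#'   at low frequency).
#' @return A list of class `extract_opts`.
#' @export
extract_opts <- function(blur_sigma = 0.1, inner_frac = 0.7, guard = 1,
                         annulus_width = 2, small_guard = 0.2, roi_inset = 1,
                         mtf_cap = 1.2) {
  structure(list(blur_sigma = blur_sigma, inner_frac = inner_frac,
                 guard = guard, annulus_width = annulus_width,
                 small_guard = small_guard, roi_inset = roi_inset,
                 mtf_cap = mtf_cap),
            class = "extract_opts")
}

# Matched-filter amplitude: template is peak-normalized; returns the detail
# amplitude (counts) such that a profile equal to `amplitude * template`
# is recovered exactly.
.matched_signal <- function(values, template, bg_mean) {
  sum(template * (bg_mean - values)) / sum(template^2)
}

# Blur a small patch with a separable Gaussian kernel (zero-padded edges; the
# template is ~0 near the patch edge so truncation is immaterial).
.patch_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- ceiling(3 * sigma_px)
  k <- dnorm(-r:r, sd = sigma_px); k <- k / sum(k)
  band <- function(n) {
    B <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - r):min(n, i + r)
      B[i, j] <- k[j - i + r + 1]
    }
    B
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

#' CNR of a large low-contrast disc
#'
#' Contrast-to-noise ratio of a disc large enough (diameter >= 20 pixels) for
#' plain ROI statistics: the absolute difference between the mean inside a
#' concentric disc ROI (70% of the detail diameter by default) and the mean
#' of a concentric background annulus separated by a guard gap, divided by
#' the SD of the annulus. A zero background SD (noiseless image) makes the
#' metric undefined and returns `NA`.
#'
#' @param image A `phantom_image`.
#' @param transform The plate `rigid_transform` (from [register_template()]).
#' @param disc One row of `layout$discs_large` (fields `x`, `y`, `diameter`).
#' @param opts An [extract_opts()] list.
#' @return CNR (unitless) or `NA` if undefined.
#' @export
cnr_large <- function(image, transform, disc, opts = extract_opts()) {
  r <- disc$diameter / 2
  if (disc$diameter < 20 * image$pixel_pitch)
    stop("cnr_large requires a disc diameter of at least 20 pixels")
  ctr <- .detector_from_plate(disc$x, disc$y, transform)
  inner <- .roi_disc(image, ctr$x, ctr$y, opts$inner_frac * r)
  ann <- .roi_annulus(image, ctr$x, ctr$y, r + opts$guard,
                      r + opts$guard + opts$annulus_width)
  s <- sd(ann)
  if (s == 0) return(NA_real_)
  abs(mean(inner) - mean(ann)) / s
}

#' Matched-filter signal amplitude of a small disc
#'
#' Estimates the signal of a sub-ROI detail by weighting pixels with the
#' noiseless expected detail profile: the disc indicator is sampled on the
#' pixel grid under the fitted transform (with one-pixel anti-aliasing),
#' blurred with the assumed PSF, and used as a matched filter against the
#' background-subtracted patch. The template is kept at unit contrast depth,
#' so the returned amplitude estimates the detail's pre-blur contrast depth
#' in counts — a convention that is insensitive to where the detail centre
#' falls within a pixel. A profile exactly equal to `A * template` yields
#' `A`.
#'
#' @inheritParams cnr_large
#' @param disc One row of `layout$discs_small_05` or `discs_small_025`.
#' @return Amplitude in counts, or `NA` if the template has no support on the
#'   pixel grid.
#' @export
detail_signal <- function(image, transform, disc, opts = extract_opts()) {
  r <- disc$diameter / 2
  pitch <- image$pixel_pitch
  sigma <- opts$blur_sigma
  rp <- r + 3 * sigma + 3 * pitch
  ctr <- .detector_from_plate(disc$x, disc$y, transform)
  g <- .subgrid(image, ctr$x - rp, ctr$x + rp, ctr$y - rp, ctr$y + rp)
  if (is.null(g)) stop("ROI falls outside the image")
  p <- .plate_from_detector(g$X, g$Y, transform)
  tmpl <- .disc_profile(p$x, p$y, disc$x, disc$y, r, pitch)
  tmpl <- .patch_blur(tmpl, sigma / pitch)
  if (max(tmpl) < 0.02) return(NA_real_)
  r1 <- r + 3 * sigma + opts$small_guard
  ann <- .roi_annulus(image, ctr$x, ctr$y, r1, r1 + opts$annulus_width)
  patch <- image$pixels[g$rows, g$cols, drop = FALSE]
  .matched_signal(patch, tmpl, mean(ann))
}

#' CNR of a small high-contrast disc
#'
#' Matched-filter amplitude (see [detail_signal()]) divided by the SD of the
#' background annulus. Applies to details smaller than 20 pixels across
#' (the 0.5-mm and 0.25-mm series).
#'
#' @inheritParams detail_signal
#' @return CNR (unitless) or `NA` if undefined.
#' @export
cnr_small <- function(image, transform, disc, opts = extract_opts()) {
  r <- disc$diameter / 2
  sigma <- opts$blur_sigma
  ctr <- .detector_from_plate(disc$x, disc$y, transform)
  r1 <- r + 3 * sigma + opts$small_guard
  ann <- .roi_annulus(image, ctr$x, ctr$y, r1, r1 + opts$annulus_width)
  s <- sd(ann)
  if (s == 0) return(NA_real_)
  a <- detail_signal(image, transform, disc, opts)
  if (is.na(a)) return(NA_real_)
  abs(a) / s
}

#' Bar-pattern MTF by the noise-corrected variance method
#'
#' Estimates the square-wave modulation at each grating frequency from the
#' variance of pixel values inside the bar-pattern ROI, corrected for the
#' noise variance measured in a uniform ROI (Droege-Morin): `M(f) =
#' sqrt(max(0, var_bar - var_noise))`, normalized by half the bright-dark
#' reference difference `M0`, `MTF(f) = sqrt(2) M(f) / M0`, clipped at
#' `opts$mtf_cap`. Bar ROIs are trimmed to whole periods clear of the
#' blur-affected pattern edges. Frequencies whose period falls below two
#' pixels are flagged invalid (beyond the Nyquist limit).
#'
#' @inheritParams cnr_large
#' @param layout The `phantom_layout`.
#' @return An object of class `mtf_curve`: a data frame with columns
#'   `frequency`, `mtf`, `valid`, and attribute `M0`.
#' @export
mtf_from_bars <- function(image, transform, layout, opts = extract_opts()) {
  refs <- layout$refs
  ins <- opts$roi_inset
  bright <- .roi_rect_plate(image, transform, refs$bright$x, refs$bright$y,
                            refs$bright$side - 2 * ins, refs$bright$side - 2 * ins)
  dark <- .roi_rect_plate(image, transform, refs$dark$x, refs$dark$y,
                          refs$dark$side - 2 * ins, refs$dark$side - 2 * ins)
  noise <- .roi_rect_plate(image, transform, refs$noise$x, refs$noise$y,
                           refs$noise$side - 2 * ins, refs$noise$side - 2 * ins)
  M0 <- abs(mean(bright) - mean(dark)) / 2
  if (M0 <= 0) stop("MTF normalization failed: zero bright-dark reference difference")
  var_noise <- var(noise)
  bars <- layout$bars
  mtf <- rep(NA_real_, nrow(bars))
  for (k in seq_len(nrow(bars))) {
    b <- bars[k, ]
    m_per <- ceiling((3 * opts$blur_sigma + 0.1) * b$frequency)
    m_per <- min(m_per, floor((b$n_periods - 1) / 2))
    m_mm <- m_per / b$frequency
    h_roi <- max(b$height - 2 * (3 * opts$blur_sigma + 0.1), image$pixel_pitch)
    vals <- tryCatch(.roi_rect_plate(image, transform, b$x, b$y,
                                     b$width - 2 * m_mm, h_roi),
                     error = function(e) NULL)
    if (length(vals) < 4) next   # trimmed ROI too small to measure
    M <- sqrt(max(0, var(vals) - var_noise))
    mtf[k] <- min(opts$mtf_cap, sqrt(2) * M / M0)
  }
  structure(data.frame(frequency = bars$frequency, mtf = mtf,
                       valid = 1 / bars$frequency >= 2 * image$pixel_pitch &
                         !is.na(mtf)),
            M0 = M0, class = c("mtf_curve", "data.frame"))
}

#' Area under the MTF curve
#'
#' Trapezoidal integral of the measured MTF over the valid (sub-Nyquist)
#' frequency range, in lp/mm.
#'
#' @param curve An `mtf_curve`.
#' @return Area (lp/mm), or `NA` if fewer than two valid points.
#' @export
aumtf <- function(curve) {
  f <- curve$frequency[curve$valid]
  m <- curve$mtf[curve$valid]
  if (length(f) < 2) return(NA_real_)
  sum(diff(f) * (head(m, -1) + tail(m, -1)) / 2)
}

#' Spatial frequency at a fraction of the MTF
#'
#' Locates the first downward crossing of `fraction` by linear interpolation
#' between bracketing measured points of the valid part of the curve. If the
#' curve starts below the fraction or never falls below it within the
#' measured range, the metric is undefined (`NA`).
#'
#' @param curve An `mtf_curve`.
#' @param fraction Target fraction, e.g. 0.5, 0.2, 0.1 or 0.05.
#' @return Frequency in lp/mm, or `NA`.
#' @export
freq_at_fraction <- function(curve, fraction) {
  stopifnot(fraction > 0, fraction < 1)
  f <- curve$frequency[curve$valid]
  m <- curve$mtf[curve$valid]
  if (length(f) < 2 || m[1] <= fraction) return(NA_real_)
  for (i in seq_len(length(f) - 1)) {
    if (m[i] > fraction && m[i + 1] <= fraction) {
      return(f[i] + (m[i] - fraction) / (m[i] - m[i + 1]) * (f[i + 1] - f[i]))
    }
  }
  NA_real_
}

#' Relative contrast of a uniform wedge step
#'
#' `100 * (mean(background) - mean(step)) / mean(background)`, using an inset
#' square ROI inside the step and its adjacent background ROI; attenuating
#' steps yield positive percentages.
#'
#' @inheritParams mtf_from_bars
#' @param step Step index 1..10.
#' @return Contrast in percent.
#' @export
step_contrast <- function(image, transform, layout, step,
                          opts = extract_opts()) {
  w <- layout$wedge[step, ]
  ins <- opts$roi_inset
  sv <- .roi_rect_plate(image, transform, w$x, w$y,
                        w$side - 2 * ins, w$side - 2 * ins)
  bv <- .roi_rect_plate(image, transform, w$x, w$bg_y, w$bg_side, w$bg_side)
  b <- mean(bv)
  if (b == 0) stop("zero background mean in step contrast")
  100 * (b - mean(sv)) / b
}

#' Structured-to-quantum noise ratio of a particle step
#'
#' Ratio of the pixel variance inside a microparticle-textured step to the
#' variance inside the uniform wedge step of matching nominal contrast. A
#' value near 1 means the structured (particle) noise is negligible relative
#' to quantum noise.
#'
#' @inheritParams mtf_from_bars
#' @param size_um Particle wedge median size: 328, 234 or 125.
#' @param step Step index 1..5 within the wedge.
#' @return Noise ratio (unitless), or `NA` if the matched uniform-step
#'   variance is zero.
#' @export
noise_ratio <- function(image, transform, layout, size_um, step,
                        opts = extract_opts()) {
  pr <- layout$particles[layout$particles$size_um == size_um &
                           layout$particles$step == step, ]
  if (nrow(pr) != 1) stop("unknown particle step")
  u <- layout$wedge[pr$matched_step, ]
  ins <- opts$roi_inset
  pv <- .roi_rect_plate(image, transform, pr$x, pr$y,
                        pr$side - 2 * ins, pr$side - 2 * ins)
  uv <- .roi_rect_plate(image, transform, u$x, u$y,
                        u$side - 2 * ins, u$side - 2 * ins)
  vu <- var(uv)
  if (vu == 0) return(NA_real_)
  var(pv) / vu
}
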