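# Independent oracles and small fixtures shared across tests.

# Brute-force variance decomposition: explicit loops over the defining sums,
# kept deliberately independent of decompose().
brute_decompose <- function(tab, metric) {
  sub <- tab[tab$metric == metric & tab$valid, ]
  ids <- unique(sub$phantom_id)
  pm <- pv <- pc <- numeric(length(ids))
  for (i in seq_along(ids)) {
    v <- sub$value[sub$phantom_id == ids[i]]
    n <- length(v)
    m <- 0
    for (x in v) m <- m + x
    m <- m / n
    ss <- 0
    for (x in v) ss <- ss + (x - m)^2
    pm[i] <- m
    pv[i] <- ss / (n - 1)
    pc[i] <- 100 * sqrt(ss / (n - 1)) / m
  }
  gm <- 0
  for (m in pm) gm <- gm + m
  gm <- gm / length(pm)
  ssb <- 0
  for (m in pm) ssb <- ssb + (m - gm)^2
  inter <- ssb / (length(pm) - 1)
  intra <- 0
  for (v in pv) intra <- intra + v
  intra <- intra / length(pv)
  list(grand_mean = gm, intra = intra, inter = inter, total = intra + inter,
       intra_share = 100 * intra / (intra + inter),
       inter_share = 100 * inter / (intra + inter),
       cov_intra = mean(pc),
       cov_inter = 100 * sqrt(inter) / gm,
       cov_total = 100 * sqrt(intra + inter) / gm)
}

# Closed-form square-wave response of a Gaussian-blurred, pixel-aperture
# sampled grating: odd-harmonic series of the square wave, each harmonic
# attenuated by the Gaussian MTF and the aperture sinc, recombined as the
# variance-based estimator measures it.
mtf_square_oracle <- function(f, sigma, pitch, cap = 1.2) {
  k <- seq(1, 399, by = 2)
  G <- exp(-2 * pi^2 * sigma^2 * (k * f)^2) *
    abs(sin(pi * k * f * pitch) / (pi * k * f * pitch))
  pmin(cap, (4 / pi) * sqrt(sum((G / k)^2)))
}

# A hand-built mtf_curve object (for the integral/threshold operators).
make_curve <- function(frequency, mtf, valid = TRUE) {
  structure(data.frame(frequency = frequency, mtf = mtf,
                       valid = rep_len(valid, length(frequency))),
            M0 = 1, class = c("mtf_curve", "data.frame"))
}

# A flat synthetic image (plate-free) for direct ROI-level checks.
flat_image <- function(n = 200, pitch = 0.1, level = 10000) {
  structure(list(pixels = matrix(level, n, n), pixel_pitch = pitch,
                 x0 = -n * pitch / 2, y0 = -n * pitch / 2,
                 phantom_id = "SYN", repeat_index = 1L,
                 applied_transform = rigid_transform(0, 0, 0)),
            class = "phantom_image")
}

# Quick rendering settings used throughout the unit tests: coarse enough to
# be fast, fine enough that the 5.6-mm discs stay above the 20-pixel limit.
test_system <- function(seed = 1, ...) {
  args <- list(pixel_pitch = 0.25, blur_sigma = 0.15, rng_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(system_params, args)
}
test_opts <- function(...) {
  args <- list(blur_sigma = 0.15)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(extract_opts, args)
}

# Finer settings for tests that need the full metric vector to be defined.
fine_system <- function(seed = 1, ...) {
  args <- list(pixel_pitch = 0.15, blur_sigma = 0.15, rng_seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(system_params, args)
}
fine_opts <- function(...) extract_opts(blur_sigma = 0.15, ...)
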