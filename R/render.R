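# Synthetic exposure renderer: plate scene assembly, Gaussian PSF, noise.

#' Acquisition system parameters
#'
#' Parameters of the simulated acquisition: pixel pitch, Gaussian PSF width,
#' dose surrogate, noise levels and the repositioning model. The pixel mean
#' is `background_level + photon_level * t`, where `t` is the local relative
#' transmission (1 in the plate background, `1 - contrast` inside a detail,
#' 1.5 in the unattenuated air region outside the plate); quantum noise is a
#' Gaussian approximation to Poisson statistics with variance equal to the
#' photon part of the mean, plus additive electronic noise. Quadrupling
#' `photon_level` therefore doubles the background pixel SD.
#'
#' @param pixel_pitch Detector pixel pitch in mm (default 0.1).
#' @param blur_sigma Gaussian PSF width in mm (>= 0).
#' @param photon_level Mean detector counts in the plate background (dose
#'   surrogate, > 0).
#' @param electronic_noise_sd Additive electronic noise SD in counts (>= 0).
#' @param background_level Detector offset in counts added to every pixel
#'   (noise-free, default 0).
#' @param repositioning_translation_sd SD of the per-exposure translation, mm.
#' @param repositioning_rotation_sd SD of the per-exposure rotation, degrees.
#' @param rng_seed Integer base seed; together with the phantom id and repeat
#'   index it fully determines an exposure.
#' @return An object of class `system_params`.
#' @export
system_params <- function(pixel_pitch = 0.1,
                          blur_sigma = 0.1,
                          photon_level = 40000,
                          electronic_noise_sd = 15,
                          background_level = 0,
                          repositioning_translation_sd = 1,
                          repositioning_rotation_sd = 0.5,
                          rng_seed = 1L) {
  if (pixel_pitch <= 0) stop("pixel_pitch must be > 0")
  if (photon_level <= 0) stop("photon_level must be > 0")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (electronic_noise_sd < 0 || repositioning_translation_sd < 0 ||
      repositioning_rotation_sd < 0)
    stop("noise and repositioning SDs must be >= 0")
  structure(list(pixel_pitch = pixel_pitch, blur_sigma = blur_sigma,
                 photon_level = photon_level,
                 electronic_noise_sd = electronic_noise_sd,
                 background_level = background_level,
                 repositioning_translation_sd = repositioning_translation_sd,
                 repositioning_rotation_sd = repositioning_rotation_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "system_params")
}

# Realized contrast under a manufacturing multiplier. For strongly
# attenuating elements the multiplier acts on the attenuation exponent
# (thickness/density variation), keeping transmission in (0, 1); for the
# faint contrast discs this is indistinguishable from a linear multiplier,
# which is kept there so defect semantics (swap/scale) are exact.
.realized_contrast <- function(contrast, mult, linear = FALSE) {
  if (linear) pmin(contrast * mult, 0.999) else 1 - (1 - contrast)^mult
}

# Cumulative dark-bar length of a 50%-duty square wave (dark first) over
# [0, x]; used for pixel-aperture integration of the gratings.
.cumdark <- function(x, f) {
  T <- 1 / f
  ph <- x * f
  fl <- floor(ph)
  fl * T / 2 + pmin((ph - fl) * T, T / 2)
}

# Anti-aliased disc profile: per-pixel coverage weight in [0, 1], smoothed
# over one pixel pitch so sub-pixel details contribute their area fraction.
.disc_profile <- function(X, Y, cx, cy, r, pitch) {
  d <- sqrt((X - cx)^2 + (Y - cy)^2)
  pmin(pmax(0.5 + (r - d) / pitch, 0), 1)
}

# Frozen particle texture for one step: positions uniform in the step square,
# diameters lognormal around the median. Returned in plate coordinates.
.particle_set <- function(row, density_mult, seed) {
  area <- row$side^2
  n <- max(0L, as.integer(round(row$density * density_mult * area)))
  .with_seed(seed, {
    data.frame(
      px = runif(n, row$x - row$side / 2, row$x + row$side / 2),
      py = runif(n, row$y - row$side / 2, row$y + row$side / 2),
      r = rlnorm(n, meanlog = log(row$median_diameter / 2), sdlog = 0.2)
    )
  })
}

#' Render one synthetic phantom exposure
#'
#' Renders a 16-bit grayscale exposure of a phantom instance: the semicircular
#' plate and every embedded detail are evaluated analytically at pixel centres
#' (discs with one-pixel anti-aliasing), placed under a rigid repositioning
#' transform, convolved with a Gaussian PSF, and corrupted by signal-dependent
#' quantum noise plus electronic noise. The microparticle texture is drawn
#' from a stream seeded by the phantom id only, so structured noise is frozen
#' across repeats of one phantom but differs between phantoms. The whole
#' exposure is a pure function of `(system$rng_seed, phantom_id,
#' repeat_index)`.
#'
#' @param layout A `phantom_layout`.
#' @param params A `phantom_params` instance (see
#'   [sample_phantom_population()]).
#' @param system A `system_params` object.
#' @param repeat_index Exposure number (>= 1) within the phantom's series.
#' @param transform Optional `rigid_transform` overriding the random
#'   repositioning draw (used for controlled experiments).
#' @param noise If `FALSE`, skip quantum and electronic noise (noiseless
#'   rendering reproduces nominal contrasts exactly).
#' @param quantize If `TRUE` (default) round and clamp to the 16-bit range.
#' @return An object of class `phantom_image` with fields `pixels` (matrix,
#'   rows indexed by y), `pixel_pitch`, `x0`, `y0` (grid origin in detector
#'   mm), `phantom_id`, `repeat_index` and `applied_transform`.
#' @export
render_phantom_image <- function(layout, params, system, repeat_index = 1L,
                                 transform = NULL, noise = TRUE,
                                 quantize = TRUE) {
  validate_layout(layout)
  stopifnot(inherits(params, "phantom_params"), inherits(system, "system_params"))
  R <- layout$plate_diameter / 2
  pitch <- system$pixel_pitch
  margin <- 5
  x0 <- -(R + margin); y0 <- -margin
  nx <- as.integer(round(2 * (R + margin) / pitch))
  ny <- as.integer(round((R + 2 * margin) / pitch))

  if (is.null(transform)) {
    transform <- .with_seed(
      .derive_seed(system$rng_seed, params$phantom_id, repeat_index, "pos"),
      rigid_transform(rnorm(1, 0, system$repositioning_translation_sd),
                      rnorm(1, 0, system$repositioning_translation_sd),
                      rnorm(1, 0, system$repositioning_rotation_sd)))
  }
  img <- structure(list(pixels = matrix(0, ny, nx), pixel_pitch = pitch,
                        x0 = x0, y0 = y0,
                        phantom_id = params$phantom_id,
                        repeat_index = as.integer(repeat_index),
                        applied_transform = transform),
                   class = "phantom_image")

  xs <- .img_xs(img); ys <- .img_ys(img)
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  p <- .plate_from_detector(X, Y, transform)
  inside <- p$x^2 + p$y^2 <= R^2 & p$y >= 0
  rel <- matrix(layout$air_level, ny, nx)
  rel[inside] <- 1

  cm <- params$contrast_mult
  sub <- function(cx, cy, e) {   # local sub-grid around a plate-frame bbox
    ctr <- .detector_from_plate(cx, cy, transform)
    half <- e + 2 * pitch
    cols <- .col_range(img, ctr$x - half, ctr$x + half)
    rows <- .row_range(img, ctr$y - half, ctr$y + half)
    list(rows = rows, cols = cols)
  }

  # contrast discs (anti-aliased indicator)
  for (g in c("discs_large", "discs_small_05", "discs_small_025")) {
    df <- layout[[g]]
    jit <- params$jitter[[g]]
    for (k in seq_len(nrow(df))) {
      cx <- df$x[k] + jit$dx[k]; cy <- df$y[k] + jit$dy[k]
      r <- df$diameter[k] / 2
      s <- sub(cx, cy, r + pitch)
      w <- .disc_profile(p$x[s$rows, s$cols], p$y[s$rows, s$cols], cx, cy, r, pitch)
      ck <- .realized_contrast(df$contrast[k], cm[[g]][k], linear = TRUE)
      rel[s$rows, s$cols] <- rel[s$rows, s$cols] - ck * w
    }
  }

  # bar patterns: 50%-duty square wave along plate x, integrated over the
  # pixel aperture in x (suppresses harmonic aliasing, as a real detector
  # aperture does); point-sampled across the bar height
  for (k in seq_len(nrow(layout$bars))) {
    b <- layout$bars[k, ]
    s <- sub(b$x, b$y, max(b$width, b$height) / 2)
    px <- p$x[s$rows, s$cols]; py <- p$y[s$rows, s$cols]
    x0b <- b$x - b$width / 2
    lo <- pmin(pmax(px - pitch / 2 - x0b, 0), b$width)
    hi <- pmin(pmax(px + pitch / 2 - x0b, 0), b$width)
    cov <- (.cumdark(hi, b$frequency) - .cumdark(lo, b$frequency)) / pitch
    cov[abs(py - b$y) > b$height / 2] <- 0
    rel[s$rows, s$cols] <- rel[s$rows, s$cols] -
      .realized_contrast(b$contrast, cm$bars[k]) * cov
  }

  # uniform wedge steps
  for (k in seq_len(nrow(layout$wedge))) {
    wr <- layout$wedge[k, ]
    s <- sub(wr$x, wr$y, wr$side / 2)
    px <- p$x[s$rows, s$cols]; py <- p$y[s$rows, s$cols]
    instep <- abs(px - wr$x) <= wr$side / 2 & abs(py - wr$y) <= wr$side / 2
    rel[s$rows, s$cols] <- rel[s$rows, s$cols] -
      .realized_contrast(wr$contrast, cm$wedge[k]) * instep
  }

  # dark reference square (for MTF normalization)
  dk <- layout$refs$dark
  s <- sub(dk$x, dk$y, dk$side / 2)
  px <- p$x[s$rows, s$cols]; py <- p$y[s$rows, s$cols]
  instep <- abs(px - dk$x) <= dk$side / 2 & abs(py - dk$y) <= dk$side / 2
  rel[s$rows, s$cols] <- rel[s$rows, s$cols] -
    .realized_contrast(dk$contrast, cm$dark_ref[1]) * instep

  # particle steps: base attenuation plus frozen microparticle texture that
  # further attenuates the transmitted beam where particles lie
  for (k in seq_len(nrow(layout$particles))) {
    pr <- layout$particles[k, ]
    s <- sub(pr$x, pr$y, pr$side / 2)
    px <- p$x[s$rows, s$cols]; py <- p$y[s$rows, s$cols]
    instep <- abs(px - pr$x) <= pr$side / 2 & abs(py - pr$y) <= pr$side / 2
    base <- .realized_contrast(pr$base_contrast, cm$particles_base[k])
    trans <- 1 - base
    rel[s$rows, s$cols] <- rel[s$rows, s$cols] - base * instep
    parts <- .particle_set(pr, params$density_mult[k],
                           .derive_seed(system$rng_seed, params$phantom_id,
                                        "texture", k))
    if (nrow(parts)) {
      cover <- matrix(0, length(s$rows), length(s$cols))
      ctr <- .detector_from_plate(parts$px, parts$py, transform)
      xf <- img$x0 + (s$cols[1] - 0.5) * pitch   # first local pixel centre
      yf <- img$y0 + (s$rows[1] - 0.5) * pitch
      for (q in seq_len(nrow(parts))) {
        rr <- parts$r[q] + pitch                 # AA support radius
        a1 <- max(1L, floor((ctr$y[q] - rr - yf) / pitch) + 1L)
        a2 <- min(length(s$rows), ceiling((ctr$y[q] + rr - yf) / pitch) + 1L)
        b1 <- max(1L, floor((ctr$x[q] - rr - xf) / pitch) + 1L)
        b2 <- min(length(s$cols), ceiling((ctr$x[q] + rr - xf) / pitch) + 1L)
        if (a1 > a2 || b1 > b2) next
        wy <- yf + (a1:a2 - 1) * pitch
        wx <- xf + (b1:b2 - 1) * pitch
        d <- sqrt(outer((wy - ctr$y[q])^2, (wx - ctr$x[q])^2, `+`))
        w <- pmin(pmax(0.5 + (parts$r[q] - d) / pitch, 0), 1)
        cover[a1:a2, b1:b2] <- pmax(cover[a1:a2, b1:b2], w)
      }
      rel[s$rows, s$cols] <- rel[s$rows, s$cols] -
        trans * pr$particle_depth * cover * instep
    }
  }

  if (system$blur_sigma > 0)
    rel <- EBImage::gblur(rel, sigma = system$blur_sigma / pitch)

  counts <- system$background_level + system$photon_level * rel
  if (noise) {
    photon_part <- pmax(system$photon_level * rel, 0)
    counts <- counts + .with_seed(
      .derive_seed(system$rng_seed, params$phantom_id, repeat_index, "noise"),
      rnorm(length(counts), 0, sqrt(photon_part)) +
        rnorm(length(counts), 0, system$electronic_noise_sd))
    counts <- matrix(counts, ny, nx)
  }
  if (quantize) counts <- pmin(pmax(round(counts), 0), 65535)
  img$pixels <- counts
  img
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("phantom image %s repeat %d: %d x %d px at %.3f mm, dx=%.2f dy=%.2f rot=%.2f\n",
              x$phantom_id, x$repeat_index, nrow(x$pixels), ncol(x$pixels),
              x$pixel_pitch, x$applied_transform$dx, x$applied_transform$dy,
              x$applied_transform$rotation))
  invisible(x)
}

#' Write / read a phantom image
#'
#' Images are stored as 16-bit grayscale TIFF (or ASCII PGM) with a JSON
#' sidecar (`<path>.json`) holding the pixel pitch, grid origin, phantom id,
#' repeat index and applied transform.
#'
#' @param img A `phantom_image`.
#' @param path Output path (`.tif`/`.tiff` or `.pgm`).
#' @return `write_phantom_image` returns `path` invisibly; the reader returns
#'   a `phantom_image`.
#' @export
write_phantom_image <- function(img, path) {
  stopifnot(inherits(img, "phantom_image"))
  px <- pmin(pmax(round(img$pixels), 0), 65535)
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(px), nrow(px)), "65535"), con)
    write(t(px), con, ncolumns = 16)
  } else {
    tiff::writeTIFF(px / 65535, path, bits.per.sample = 16)
  }
  meta <- list(pixel_pitch = img$pixel_pitch, x0 = img$x0, y0 = img$y0,
               phantom_id = img$phantom_id, repeat_index = img$repeat_index,
               applied_transform = unclass(img$applied_transform))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phantom_image
#' @export
read_phantom_image <- function(path) {
  if (grepl("\\.pgm$", path, ignore.case = TRUE)) {
    txt <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
    stopifnot(txt[1] == "P2")
    nc <- as.integer(txt[2]); nr <- as.integer(txt[3])
    px <- matrix(as.numeric(txt[-(1:4)]), nr, nc, byrow = TRUE)
  } else {
    px <- round(tiff::readTIFF(path) * 65535)
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing image sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  tf <- meta$applied_transform
  structure(list(pixels = px, pixel_pitch = meta$pixel_pitch,
                 x0 = meta$x0, y0 = meta$y0,
                 phantom_id = meta$phantom_id,
                 repeat_index = as.integer(meta$repeat_index),
                 applied_transform = rigid_transform(tf$dx, tf$dy, tf$rotation)),
            class = "phantom_image")
}
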