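# Full-vector extraction: registration followed by all 64 metric operators.

#' Extract all 64 image-quality metrics from one image
#'
#' Registers the plate template ([register_template()]) and runs every metric
#' operator: the 34 CNRs, the 5 MTF summaries, the 10 step contrasts and the
#' 15 noise ratios. The result is a pure, deterministic function of the
#' image. Undefined metrics (e.g. CNR on a noiseless image) carry `valid =
#' FALSE` and `NA` values; a registration failure propagates as an error.
#'
#' @param image A `phantom_image`.
#' @param layout The `phantom_layout`.
#' @param opts An [extract_opts()] list.
#' @param transform Optional known `rigid_transform`; when supplied,
#'   registration is skipped.
#' @return A `metric_vector`: data frame with 64 rows and columns `metric`,
#'   `group`, `value`, `valid`; the fitted transform is kept in attribute
#'   `"transform"`.
#' @examples
#' \donttest{
#' lay <- default_layout()
#' sys <- system_params(pixel_pitch = 0.4, rng_seed = 7)
#' pop <- sample_phantom_population(lay, 1, 0.1, seed = 7)
#' img <- render_phantom_image(lay, pop[[1]], sys, 1)
#' mv <- extract_all(img, lay, extract_opts(blur_sigma = sys$blur_sigma))
#' }
#' @export
extract_all <- function(image, layout, opts = extract_opts(),
                        transform = NULL) {
  if (is.null(transform)) transform <- register_template(image, layout)
  reg <- metric_registry()
  vals <- setNames(rep(NA_real_, nrow(reg)), reg$metric)

  for (k in seq_len(nrow(layout$discs_large)))
    vals[sprintf("CNR5.6mm#%d", k)] <-
      cnr_large(image, transform, layout$discs_large[k, ], opts)
  for (k in seq_len(nrow(layout$discs_small_05)))
    vals[sprintf("CNR0.5mm#%d", k)] <-
      cnr_small(image, transform, layout$discs_small_05[k, ], opts)
  for (k in seq_len(nrow(layout$discs_small_025)))
    vals[sprintf("CNR0.25mm#%d", k)] <-
      cnr_small(image, transform, layout$discs_small_025[k, ], opts)

  curve <- mtf_from_bars(image, transform, layout, opts)
  vals["AUMTF"] <- aumtf(curve)
  vals["SpFreq@50%MTF"] <- freq_at_fraction(curve, 0.5)
  vals["SpFreq@20%MTF"] <- freq_at_fraction(curve, 0.2)
  vals["SpFreq@10%MTF"] <- freq_at_fraction(curve, 0.1)
  vals["SpFreq@5%MTF"] <- freq_at_fraction(curve, 0.05)

  for (k in 1:10)
    vals[sprintf("Contrast#%d", k)] <-
      step_contrast(image, transform, layout, k, opts)
  for (size in c(328, 234, 125))
    for (k in 1:5)
      vals[sprintf("NR%dum#%d", size, k)] <-
        noise_ratio(image, transform, layout, size, k, opts)

  out <- data.frame(metric = reg$metric, group = reg$group,
                    value = unname(vals), valid = !is.na(vals))
  attr(out, "transform") <- transform
  class(out) <- c("metric_vector", "data.frame")
  out
}

#' Extract a measurement table from a series of images
#'
#' Runs [extract_all()] on each image (in memory, or read from TIFF/PGM
#' paths) and stacks the results into a long-format `measurement_table`.
#'
#' @param images A list of `phantom_image` objects, or a character vector of
#'   image file paths (each with its JSON sidecar).
#' @param layout The `phantom_layout`.
#' @param opts An [extract_opts()] list.
#' @return A `measurement_table` with one row per image x metric.
#' @export
extract_images <- function(images, layout, opts = extract_opts()) {
  if (is.character(images)) images <- lapply(images, read_phantom_image)
  rows <- lapply(images, function(img) {
    mv <- extract_all(img, layout, opts)
    data.frame(phantom_id = img$phantom_id, repeat_index = img$repeat_index,
               metric = mv$metric, value = mv$value, valid = mv$valid)
  })
  .as_measurement_table(do.call(rbind, rows))
}
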