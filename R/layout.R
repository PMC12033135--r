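# Geometric description of the semicircular test plate and its details.

#' Default test-plate layout
#'
#' Builds the nominal layout of a TORMAS-style semicircular mammography QC
#' test plate: a 220-mm semicircular plate embedding (1) a resolution grating
#' of 26 bar patterns spanning spatial frequencies in (1, 20] lp/mm, (2) a
#' contrast-detail set of 12 low-contrast 5.6-mm discs and two series of 11
#' high-contrast discs (0.5 mm and 0.25 mm), (3) a ten-step uniform grey-scale
#' wedge of 8-mm square steps, and (4) three five-step wedges textured with
#' microparticles of median diameter 328, 234 and 125 um, each particle step
#' matched by nominal contrast to one step of the uniform wedge.
#'
#' Coordinates are plate-centred millimetres with x rightward and y downward;
#' the flat (chest-wall) edge of the plate lies along y = 0 and the plate
#' occupies y >= 0. Contrasts are relative attenuation fractions in (0, 1);
#' each contrast-detail series decreases geometrically so that the rendered
#' CNR series declines monotonically, as on the physical plate. The nominal
#' step contrasts of the uniform wedge are the published mean step contrasts
#' for this plate type (95.24% down to 15.50%).
#'
#' @param plate_diameter Plate diameter in mm (nominal 220).
#' @return An object of class `phantom_layout`.
#' @examples
#' lay <- default_layout()
#' nrow(lay$discs_large)  # 12
#' @export
default_layout <- function(plate_diameter = 220) {
  R <- plate_diameter / 2

  # resolution grating: 26 log-spaced frequencies in (1, 20] lp/mm, two rows;
  # each pattern holds an integer number of periods (~5 mm wide, 3 mm tall,
  # wide enough that variance estimates average over several whole periods)
  freq <- 1.02 * (20 / 1.02)^((0:25) / 25)
  n_periods <- pmax(3L, round(5 * freq))
  bars <- data.frame(
    id = 1:26,
    x = rep(seq(-84, 84, by = 14), length.out = 26),
    y = rep(c(6, 12), each = 13),
    frequency = freq,
    n_periods = n_periods,
    width = n_periods / freq,
    height = 4,
    contrast = 0.5
  )

  discs_large <- data.frame(
    id = 1:12,
    x = seq(-77, 77, by = 14),
    y = 30,
    diameter = 5.6,
    contrast = 0.16 * 0.696^(0:11)
  )
  discs_small_05 <- data.frame(
    id = 1:11,
    x = seq(-70, 70, by = 14),
    y = 42,
    diameter = 0.5,
    contrast = 0.5 * 0.715^(0:10)
  )
  discs_small_025 <- data.frame(
    id = 1:11,
    x = seq(-70, 70, by = 14),
    y = 48,
    diameter = 0.25,
    contrast = 0.6 * 0.746^(0:10)
  )

  wedge <- data.frame(
    step = 1:10,
    x = seq(-63, 63, by = 14),
    y = 66,
    side = 8,
    contrast = c(95.24, 86.86, 83.29, 77.84, 71.04,
                 59.08, 52.05, 42.51, 30.46, 15.50) / 100,
    bg_y = 56,       # adjacent background ROI centre for the contrast metric
    bg_side = 5
  )

  # particle wedges: median diameter (mm), particle surface density (mm^-2),
  # extra attenuation depth per step (fraction of the transmitted beam)
  pw <- expand.grid(step = 1:5, size_um = c(328, 234, 125))
  particles <- data.frame(
    size_um = pw$size_um,
    step = pw$step,
    x = rep(seq(-28, 28, by = 14), 3),
    y = rep(c(78, 88, 98), each = 5),
    side = 8,
    matched_step = pw$step,
    base_contrast = c(95.24, 86.86, 83.29, 77.84, 71.04)[pw$step] / 100,
    particle_depth = 0.15 + 0.0375 * (pw$step - 1),
    density = c(`328` = 2.4, `234` = 4.5, `125` = 9)[as.character(pw$size_um)],
    median_diameter = pw$size_um / 1000
  )

  refs <- list(
    bright = list(x = -100, y = 8, side = 8, contrast = 0),
    dark   = list(x = 100,  y = 8, side = 8, contrast = 0.5),
    noise  = list(x = -60,  y = 84, side = 8)
  )

  layout <- structure(list(
    plate_diameter = plate_diameter,
    air_level = 1.5,           # relative intensity outside the plate
    discs_large = discs_large,
    discs_small_05 = discs_small_05,
    discs_small_025 = discs_small_025,
    bars = bars,
    wedge = wedge,
    particles = particles,
    refs = refs
  ), class = "phantom_layout")
  validate_layout(layout)
  layout
}

#' Validate a plate layout
#'
#' Checks the structural invariants of a [default_layout()]-style layout:
#' detail counts 12/11/11/26/10/15, strictly increasing bar frequencies in
#' (1, 20] lp/mm, particle-to-uniform step matching in 1..10, and all details
#' (with their extents) inside the semicircular plate.
#'
#' @param layout A `phantom_layout`.
#' @return The layout, invisibly; errors if an invariant is violated.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "phantom_layout"))
  R <- layout$plate_diameter / 2
  if (nrow(layout$discs_large) != 12L) stop("expected 12 low-contrast discs")
  if (nrow(layout$discs_small_05) != 11L) stop("expected 11 discs of 0.5 mm")
  if (nrow(layout$discs_small_025) != 11L) stop("expected 11 discs of 0.25 mm")
  if (nrow(layout$bars) != 26L) stop("expected 26 bar patterns")
  if (nrow(layout$wedge) != 10L) stop("expected 10 uniform wedge steps")
  if (nrow(layout$particles) != 15L) stop("expected 15 particle steps")
  f <- layout$bars$frequency
  if (any(diff(f) <= 0) || any(f <= 1) || any(f > 20))
    stop("bar frequencies must be strictly increasing in (1, 20] lp/mm")
  if (!all(layout$particles$matched_step %in% 1:10))
    stop("particle steps must match a uniform wedge step in 1..10")
  inside <- function(x, y, e) {
    all(sqrt((abs(x) + e)^2 + (y + e)^2) <= R & y - e >= 0)
  }
  with(layout$discs_large, stopifnot(inside(x, y, diameter / 2)))
  with(layout$discs_small_05, stopifnot(inside(x, y, diameter / 2)))
  with(layout$discs_small_025, stopifnot(inside(x, y, diameter / 2)))
  with(layout$bars, stopifnot(inside(x, y, pmax(width, height) / 2)))
  with(layout$wedge, stopifnot(inside(x, y, side / 2), inside(x, bg_y, bg_side / 2)))
  with(layout$particles, stopifnot(inside(x, y, side / 2)))
  invisible(layout)
}

#' @export
print.phantom_layout <- function(x, ...) {
  cat(sprintf("semicircular test plate, diameter %.0f mm\n", x$plate_diameter))
  cat(sprintf("  %d + %d + %d contrast discs (5.6 / 0.5 / 0.25 mm)\n",
              nrow(x$discs_large), nrow(x$discs_small_05), nrow(x$discs_small_025)))
  cat(sprintf("  %d bar patterns, %.2f-%.1f lp/mm\n",
              nrow(x$bars), min(x$bars$frequency), max(x$bars$frequency)))
  cat(sprintf("  %d-step uniform wedge, %d particle steps\n",
              nrow(x$wedge), nrow(x$particles)))
  invisible(x)
}

#' Write / read a layout as JSON
#'
#' @param layout A `phantom_layout`.
#' @param path File path.
#' @return `write_layout` returns `path` invisibly; `read_layout` returns the
#'   layout.
#' @export
write_layout <- function(layout, path) {
  validate_layout(layout)
  jsonlite::write_json(unclass(layout), path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("discs_large", "discs_small_05", "discs_small_025",
               "bars", "wedge", "particles"))
    obj[[nm]] <- as.data.frame(obj[[nm]])
  layout <- structure(obj, class = "phantom_layout")
  validate_layout(layout)
  layout
}
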