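# Internal helpers: seeding, geometry, pixel/ROI access.

# Deterministic 31-bit hash of a string (djb2 variant, exact in doubles).
.hash_string <- function(s) {
  h <- 5381
  for (x in utf8ToInt(s)) h <- (h * 33 + x) %% 2147483647
  as.integer(h)
}

# Mix an arbitrary sequence of integers/strings into one 31-bit seed.
.derive_seed <- function(...) {
  h <- 104729
  for (p in unlist(list(...))) {
    v <- if (is.character(p)) .hash_string(p) else as.integer(p) %% 2147483647L
    h <- (h * 69069 + as.numeric(v)) %% 2147483647
  }
  as.integer(h)
}

# Evaluate code under a seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.deg2rad <- function(d) d * pi / 180

#' Rigid plate-to-detector transform
#'
#' A rigid transform describing where the test plate sits on the detector:
#' a rotation about the plate centre followed by a translation, both in
#' detector coordinates (x rightward, y downward, millimetres).
#'
#' @param dx,dy Translation in mm.
#' @param rotation Rotation in degrees about the plate centre.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, rotation = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(rotation))
  structure(list(dx = dx, dy = dy, rotation = rotation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: dx = %.4f mm, dy = %.4f mm, rotation = %.4f deg\n",
              x$dx, x$dy, x$rotation))
  invisible(x)
}

# plate -> detector: q = R p + t
.detector_from_plate <- function(px, py, tf) {
  th <- .deg2rad(tf$rotation)
  c0 <- cos(th); s0 <- sin(th)
  list(x = c0 * px - s0 * py + tf$dx,
       y = s0 * px + c0 * py + tf$dy)
}

# detector -> plate: p = R^T (q - t)
.plate_from_detector <- function(qx, qy, tf) {
  th <- .deg2rad(tf$rotation)
  c0 <- cos(th); s0 <- sin(th)
  ux <- qx - tf$dx; uy <- qy - tf$dy
  list(x = c0 * ux + s0 * uy,
       y = -s0 * ux + c0 * uy)
}

# --- pixel grid helpers -----------------------------------------------------
# A phantom_image stores its grid origin (x0, y0) = coordinates of the outer
# corner of pixel (1,1); pixel centres are x0 + (j - 0.5) * pitch etc.

.img_xs <- function(img) img$x0 + (seq_len(ncol(img$pixels)) - 0.5) * img$pixel_pitch
.img_ys <- function(img) img$y0 + (seq_len(nrow(img$pixels)) - 0.5) * img$pixel_pitch

# Column/row index ranges covering [lo, hi] in mm (clipped to the image).
.col_range <- function(img, lo, hi) {
  j1 <- max(1L, floor((lo - img$x0) / img$pixel_pitch) + 1L)
  j2 <- min(ncol(img$pixels), ceiling((hi - img$x0) / img$pixel_pitch))
  if (j1 > j2) integer(0) else j1:j2
}
.row_range <- function(img, lo, hi) {
  i1 <- max(1L, floor((lo - img$y0) / img$pixel_pitch) + 1L)
  i2 <- min(nrow(img$pixels), ceiling((hi - img$y0) / img$pixel_pitch))
  if (i1 > i2) integer(0) else i1:i2
}

# Local sub-grid around a detector-frame bounding box; returns pixel-centre
# coordinate matrices plus index vectors.
.subgrid <- function(img, xlo, xhi, ylo, yhi) {
  cols <- .col_range(img, xlo, xhi)
  rows <- .row_range(img, ylo, yhi)
  if (!length(cols) || !length(rows)) return(NULL)
  xs <- img$x0 + (cols - 0.5) * img$pixel_pitch
  ys <- img$y0 + (rows - 0.5) * img$pixel_pitch
  list(rows = rows, cols = cols,
       X = matrix(xs, nrow = length(rows), ncol = length(cols), byrow = TRUE),
       Y = matrix(ys, nrow = length(rows), ncol = length(cols)))
}

# Values of pixels whose centres lie in a detector-frame disc / annulus.
.roi_disc <- function(img, cx, cy, r) {
  g <- .subgrid(img, cx - r, cx + r, cy - r, cy + r)
  if (is.null(g)) stop("ROI falls outside the image")
  d2 <- (g$X - cx)^2 + (g$Y - cy)^2
  vals <- img$pixels[g$rows, g$cols, drop = FALSE][d2 <= r^2]
  if (!length(vals)) stop("ROI contains no pixels")
  vals
}

.roi_annulus <- function(img, cx, cy, r1, r2) {
  g <- .subgrid(img, cx - r2, cx + r2, cy - r2, cy + r2)
  if (is.null(g)) stop("ROI falls outside the image")
  d2 <- (g$X - cx)^2 + (g$Y - cy)^2
  vals <- img$pixels[g$rows, g$cols, drop = FALSE][d2 > r1^2 & d2 <= r2^2]
  if (!length(vals)) stop("ROI contains no pixels")
  vals
}

# Values of pixels whose *plate-frame* coordinates lie in an axis-aligned
# rectangle (used for bar patterns and wedge steps, which rotate with the
# plate). `tf` maps plate to detector coordinates.
.roi_rect_plate <- function(img, tf, cx, cy, w, h) {
  half <- sqrt((w / 2)^2 + (h / 2)^2) + img$pixel_pitch
  ctr <- .detector_from_plate(cx, cy, tf)
  g <- .subgrid(img, ctr$x - half, ctr$x + half, ctr$y - half, ctr$y + half)
  if (is.null(g)) stop("ROI falls outside the image")
  p <- .plate_from_detector(g$X, g$Y, tf)
  keep <- abs(p$x - cx) <= w / 2 & abs(p$y - cy) <= h / 2
  vals <- img$pixels[g$rows, g$cols, drop = FALSE][keep]
  if (!length(vals)) stop("ROI contains no pixels")
  vals
}
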