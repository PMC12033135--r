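# Template registration: recover the rigid plate transform from an image.

#' Register the plate template to an image
#'
#' Recovers the rigid transform (translation + rotation about the plate
#' centre) that places the semicircular plate in the image, so that all ROIs
#' can be located dynamically regardless of the small translations and
#' rotations introduced by manual repositioning. The plate is segmented by
#' thresholding midway between the plate background and the brighter
#' unattenuated region outside it; the translation follows from the mask
#' centroid (the centroid of a semicircle sits 4R/3pi from its centre along
#' the symmetry axis) and the rotation from the orientation of the mask's
#' principal axes. With ~1e6 plate pixels both estimates are far below the
#' pixel/degree level.
#'
#' A similarity check guards against degenerate inputs: the foreground/
#' background separation must exceed `min_separation` times the plate level
#' and the segmented area must match the plate area within `area_tol`,
#' otherwise a registration-failure error is raised and the image is rejected.
#'
#' @param image A `phantom_image`.
#' @param layout The `phantom_layout` rendered in the image.
#' @param area_tol Maximum relative deviation of the segmented area from the
#'   nominal plate area.
#' @param min_separation Minimum relative intensity separation between plate
#'   and surround.
#' @return A `rigid_transform` with attribute `"score"` (area agreement).
#' @export
register_template <- function(image, layout, area_tol = 0.15,
                              min_separation = 0.2) {
  stopifnot(inherits(image, "phantom_image"))
  validate_layout(layout)
  R <- layout$plate_diameter / 2
  px <- image$pixels
  lvl_plate <- median(px)                  # plate background dominates
  lvl_air <- quantile(px, 0.95, names = FALSE)
  if (!is.finite(lvl_plate) || lvl_plate <= 0 ||
      (lvl_air - lvl_plate) < min_separation * max(lvl_plate, 1))
    stop("registration failure: no plate/background separation in image")
  thr <- (lvl_plate + lvl_air) / 2
  mask <- px < thr
  n <- sum(mask)
  area <- n * image$pixel_pitch^2
  a0 <- pi * R^2 / 2
  score <- 1 - abs(area - a0) / a0
  if (score < 1 - area_tol)
    stop(sprintf("registration failure: segmented area %.0f mm^2 vs expected %.0f mm^2",
                 area, a0))

  xs <- .img_xs(image); ys <- .img_ys(image)
  m <- mask * 1
  colmass <- colSums(m); rowmass <- rowSums(m)
  mx <- sum(colmass * xs) / n
  my <- sum(rowmass * ys) / n
  mxx <- sum(colmass * xs^2) / n - mx^2
  myy <- sum(rowmass * ys^2) / n - my^2
  mxy <- as.numeric(ys %*% m %*% xs) / n - mx * my
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi

  yc <- 4 * R / (3 * pi)                   # centroid offset along symmetry axis
  th <- .deg2rad(theta)
  ctr_x <- mx - (-sin(th) * yc)
  ctr_y <- my - (cos(th) * yc)
  tf <- rigid_transform(ctr_x, ctr_y, theta)
  attr(tf, "score") <- score
  tf
}
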