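# Per-phantom manufacturing parameters: contrast multipliers, placement
# jitter, particle-density multipliers, and injectable defects.

.mult_groups <- c("discs_large", "discs_small_05", "discs_small_025",
                  "bars", "wedge", "particles_base", "dark_ref")
.jitter_groups <- c("discs_large", "discs_small_05", "discs_small_025")

.group_sizes <- function(layout) {
  c(discs_large = nrow(layout$discs_large),
    discs_small_05 = nrow(layout$discs_small_05),
    discs_small_025 = nrow(layout$discs_small_025),
    bars = nrow(layout$bars),
    wedge = nrow(layout$wedge),
    particles_base = nrow(layout$particles),
    dark_ref = 1L)
}

# i.i.d. multipliers with mean 1 and coefficient of variation cv; lognormal so
# they are strictly positive. cv = 0 returns exactly 1.
.rmult <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Sample a population of phantom instances
#'
#' Draws `n` sets of per-phantom manufacturing parameters around the nominal
#' layout: one contrast multiplier per embedded detail/step (i.i.d., mean 1,
#' coefficient of variation `manufacturing_cv`), bounded placement jitter for
#' the contrast discs, and one particle-density multiplier per particle step.
#' These parameters are the between-phantom (manufacturing) level of the
#' two-level variability model; repositioning and noise are drawn per exposure
#' by [render_phantom_image()].
#'
#' @param layout A `phantom_layout`.
#' @param n Number of phantoms (>= 1).
#' @param manufacturing_cv Coefficient of variation of the contrast and
#'   density multipliers (>= 0; 0 gives identical phantoms).
#' @param seed Integer seed; the output is a pure function of
#'   `(layout, n, manufacturing_cv, seed)`.
#' @param jitter_sd Standard deviation of detail placement jitter in mm.
#' @param jitter_max Hard bound on placement jitter in mm (draws are
#'   truncated) so details cannot overlap their neighbours.
#' @return A list of `n` objects of class `phantom_params`.
#' @examples
#' pop <- sample_phantom_population(default_layout(), 3, 0.1, seed = 1)
#' pop[[1]]$phantom_id
#' @export
sample_phantom_population <- function(layout, n, manufacturing_cv, seed,
                                      jitter_sd = 0.05, jitter_max = 0.5) {
  validate_layout(layout)
  if (n < 1) stop("n must be >= 1")
  if (manufacturing_cv < 0) stop("manufacturing_cv must be >= 0")
  if (jitter_sd < 0 || jitter_max < 0) stop("jitter parameters must be >= 0")
  sizes <- .group_sizes(layout)
  .with_seed(.derive_seed(seed, "population"), {
    lapply(seq_len(n), function(i) {
      cm <- lapply(sizes, function(k) .rmult(k, manufacturing_cv))
      jit <- lapply(.jitter_groups, function(g) {
        k <- sizes[[g]]
        data.frame(dx = pmin(pmax(rnorm(k, 0, jitter_sd), -jitter_max), jitter_max),
                   dy = pmin(pmax(rnorm(k, 0, jitter_sd), -jitter_max), jitter_max))
      })
      names(jit) <- .jitter_groups
      structure(list(
        phantom_id = sprintf("PH%03d", i),
        contrast_mult = cm,
        density_mult = .rmult(sizes[["particles_base"]], manufacturing_cv),
        jitter = jit,
        defects = list()
      ), class = "phantom_params")
    })
  })
}

#' @export
print.phantom_params <- function(x, ...) {
  cat(sprintf("phantom %s: %d contrast multipliers, %d defects\n",
              x$phantom_id, length(unlist(x$contrast_mult)), length(x$defects)))
  invisible(x)
}

#' Specify a phantom defect
#'
#' Two defect kinds are supported, mirroring the anomalies that defective
#' plates show in practice: `"swap_details"` exchanges the realized contrasts
#' of two details of the same group (so a graded CNR series inverts between
#' the two positions, as when two physical details were exchanged during
#' assembly), and `"scale_detail_contrast"` multiplies one detail's realized
#' contrast by `factor` (an anomalously weak or strong detail).
#'
#' @param kind `"swap_details"` or `"scale_detail_contrast"`.
#' @param group Detail group: `"discs_large"`, `"discs_small_05"` or
#'   `"discs_small_025"` (or any multiplier group).
#' @param targets Integer indices within the group: two for a swap, one for a
#'   scaling.
#' @param factor Positive scale factor (scaling defects only).
#' @return An object of class `defect_spec`.
#' @export
defect_spec <- function(kind = c("swap_details", "scale_detail_contrast"),
                        group, targets, factor = 1) {
  kind <- match.arg(kind)
  if (!group %in% .mult_groups) stop("unknown detail group: ", group)
  if (kind == "swap_details" && length(targets) != 2L)
    stop("swap_details needs exactly two target indices")
  if (kind == "scale_detail_contrast" && length(targets) != 1L)
    stop("scale_detail_contrast needs exactly one target index")
  if (factor <= 0) stop("scale factor must be > 0")
  structure(list(kind = kind, group = group,
                 targets = as.integer(targets), factor = factor),
            class = "defect_spec")
}

#' Inject a defect into a phantom instance
#'
#' Applies a [defect_spec()] to a `phantom_params` object. A swap exchanges
#' the realized contrasts of the two targeted details (the multipliers are
#' rewritten so that detail i renders with detail j's contrast and vice
#' versa); a scaling multiplies one detail's contrast multiplier by `factor`.
#' All other fields are unchanged.
#'
#' @param params A `phantom_params` object.
#' @param defect A `defect_spec`.
#' @param layout The `phantom_layout` the params belong to (needed to resolve
#'   nominal contrasts for a swap).
#' @return The modified `phantom_params`.
#' @export
inject_defect <- function(params, defect, layout) {
  stopifnot(inherits(params, "phantom_params"), inherits(defect, "defect_spec"))
  m <- params$contrast_mult[[defect$group]]
  if (is.null(m) || any(defect$targets < 1L) || any(defect$targets > length(m)))
    stop("defect target does not exist in group ", defect$group)
  nominal <- switch(defect$group,
    discs_large = layout$discs_large$contrast,
    discs_small_05 = layout$discs_small_05$contrast,
    discs_small_025 = layout$discs_small_025$contrast,
    bars = layout$bars$contrast,
    wedge = layout$wedge$contrast,
    particles_base = layout$particles$base_contrast,
    dark_ref = layout$refs$dark$contrast)
  if (defect$kind == "swap_details") {
    i <- defect$targets[1]; j <- defect$targets[2]
    ci <- nominal[i] * m[i]; cj <- nominal[j] * m[j]
    m[i] <- cj / nominal[i]   # detail i now renders with detail j's contrast
    m[j] <- ci / nominal[j]
  } else {
    m[defect$targets] <- m[defect$targets] * defect$factor
  }
  params$contrast_mult[[defect$group]] <- m
  params$defects <- c(params$defects, list(defect))
  params
}
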