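# Published per-metric reference summaries for a 24-phantom (22 after
# exclusion) x 10-repeat reproducibility study of this plate type, shipped as
# plain-text tables. They serve as realistic simulation inputs and as checks
# for the summary computations.

#' Published reference summary tables
#'
#' Per-metric intra/inter/total variances (with grand means and total SDs)
#' and per-metric intra/inter/total coefficients of variation, as published
#' for a 22-phantom, 10-repeat reproducibility study of this plate type.
#'
#' @return `reference_variances()` and `reference_covs()` each return a data
#'   frame with one row per registry metric.
#' @export
reference_variances <- function() {
  read.csv(system.file("extdata", "reference_variances.csv",
                       package = "phantomqc"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname reference_variances
#' @export
reference_covs <- function() {
  read.csv(system.file("extdata", "reference_covs.csv",
                       package = "phantomqc"),
           stringsAsFactors = FALSE, check.names = FALSE)
}

#' Two-level simulation spec at the reference study's scale
#'
#' Builds a [two_level_spec()] whose per-metric grand means and intra/inter
#' SDs are taken from the reference variance table, at a chosen design size.
#' Useful for simulating realistic measurement tables without rendering
#' images.
#'
#' @param n_phantoms,n_repeats Design size (defaults 24 phantoms x 10
#'   repeats, the pre-exclusion study design).
#' @param seed Integer seed.
#' @return A `two_level_spec` over the 64 registry metrics.
#' @export
reference_simulation_spec <- function(n_phantoms = 24, n_repeats = 10,
                                      seed = 1L) {
  v <- reference_variances()
  two_level_spec(mu = setNames(v$mean, v$metric),
                 sigma_intra = sqrt(v$intra_var),
                 sigma_inter = sqrt(v$inter_var),
                 n_phantoms = n_phantoms, n_repeats = n_repeats, seed = seed)
}
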