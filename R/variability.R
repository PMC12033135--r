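# Variance-component analysis: defective-phantom screening, intra/inter
# decomposition, coefficients of variation, and group summaries.

#' Screen for defective phantoms
#'
#' For each metric, the per-phantom means (over repeats) are compared with
#' their grand mean; phantoms deviating by more than `k` standard deviations
#' are flagged as outliers. The screen is a single pass (no re-iteration
#' after exclusion), and the excluded set is the union of phantoms flagged on
#' any metric — a phantom defective on one detail is removed entirely.
#'
#' @param table A `measurement_table` with at least 3 phantoms.
#' @param k SD multiplier (default 3).
#' @param sd_convention `"phantom_means"` (default): the SD is taken across
#'   the per-phantom means; `"all_values"`: across all individual
#'   measurements.
#' @return An object of class `outlier_report`: list with `per_metric` (grand
#'   mean and SD per metric), `flagged` (phantom, metric, deviation in SD
#'   units) and `excluded` (phantom ids).
#' @export
detect_defective <- function(table, k = 3,
                             sd_convention = c("phantom_means", "all_values")) {
  stopifnot(inherits(table, "measurement_table"))
  sd_convention <- match.arg(sd_convention)
  tab <- table[table$valid & !is.na(table$value), ]
  if (length(unique(tab$phantom_id)) < 3)
    stop("outlier screening needs at least 3 phantoms")
  flagged <- list(); per_metric <- list()
  for (m in unique(tab$metric)) {
    sub <- tab[tab$metric == m, ]
    pm <- tapply(sub$value, sub$phantom_id, mean)
    grand <- mean(pm)
    s <- if (sd_convention == "phantom_means") sd(pm) else sd(sub$value)
    per_metric[[m]] <- data.frame(metric = m, grand_mean = grand, sd = s)
    if (is.na(s) || s == 0) next
    dev <- (pm - grand) / s
    hit <- abs(dev) > k
    if (any(hit))
      flagged[[m]] <- data.frame(phantom_id = names(pm)[hit], metric = m,
                                 deviation_sd = unname(dev[hit]))
  }
  flagged <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(phantom_id = character(), metric = character(),
               deviation_sd = numeric())
  rownames(flagged) <- NULL
  structure(list(per_metric = do.call(rbind, per_metric),
                 flagged = flagged,
                 excluded = sort(unique(flagged$phantom_id)),
                 k = k, sd_convention = sd_convention),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("outlier screen (+/- %g SD, %s): %d phantom(s) excluded\n",
              x$k, x$sd_convention, length(x$excluded)))
  if (nrow(x$flagged)) print(x$flagged)
  invisible(x)
}

#' Remove excluded phantoms from a table
#'
#' @param table A `measurement_table`.
#' @param report An `outlier_report` from [detect_defective()] (or a
#'   character vector of phantom ids).
#' @return The table without the excluded phantoms.
#' @export
remove_excluded <- function(table, report) {
  ids <- if (inherits(report, "outlier_report")) report$excluded else report
  .as_measurement_table(table[!table$phantom_id %in% ids, ])
}

#' Intra/inter-phantom variance decomposition
#'
#' For each metric: the intra-phantom variance is the unweighted mean over
#' phantoms of the per-phantom sample variance of the repeats (n-1
#' denominator); the inter-phantom variance is the sample variance of the
#' per-phantom means across phantoms; the total is their sum, and the two
#' percent contributions are each component over the total times 100.
#' Coefficients of variation: `COV_inter = 100 sqrt(inter) / mean` and
#' `COV_total = 100 sqrt(total) / mean`; `COV_intra` is, by default, the
#' unweighted mean over phantoms of the per-phantom `100 sd / mean`
#' (convention `"per_phantom"`); convention `"grand_mean"` uses
#' `100 sqrt(intra) / grand mean` instead.
#'
#' Invalid values are dropped pairwise per metric; a metric is undefined if
#' any phantom retains fewer than 2 or less than 80% of the expected
#' repeats, and its COVs are undefined if its grand mean is 0.
#'
#' @param table A `measurement_table` (after exclusion of defective
#'   phantoms).
#' @param cov_intra_convention `"per_phantom"` (default) or `"grand_mean"`.
#' @return A `variance_decomposition`: data frame with one row per metric and
#'   columns `metric`, `group`, `n_phantoms`, `n_repeats`, `grand_mean`,
#'   `intra_var`, `inter_var`, `total_var`, `intra_share`, `inter_share`,
#'   `cov_intra`, `cov_inter`, `cov_total`, `valid`.
#' @examples
#' sp <- two_level_spec(mu = c(a = 100), sigma_intra = 1, sigma_inter = 3,
#'                      n_phantoms = 6, n_repeats = 4, seed = 2)
#' decompose(simulate_measurement_table(sp))
#' @export
decompose <- function(table, cov_intra_convention = c("per_phantom", "grand_mean")) {
  stopifnot(inherits(table, "measurement_table"))
  cov_intra_convention <- match.arg(cov_intra_convention)
  tab <- table[table$valid & !is.na(table$value), ]
  reg <- metric_registry()
  n_expected <- max(tapply(tab$repeat_index, paste(tab$phantom_id, tab$metric),
                           function(x) length(unique(x))))
  rows <- lapply(unique(tab$metric), function(m) {
    sub <- tab[tab$metric == m, ]
    counts <- tapply(sub$value, sub$phantom_id, length)
    row <- data.frame(metric = m,
                      group = if (m %in% reg$metric) reg$group[match(m, reg$metric)]
                              else NA_character_,
                      n_phantoms = length(counts), n_repeats = max(counts),
                      grand_mean = NA_real_, intra_var = NA_real_,
                      inter_var = NA_real_, total_var = NA_real_,
                      intra_share = NA_real_, inter_share = NA_real_,
                      cov_intra = NA_real_, cov_inter = NA_real_,
                      cov_total = NA_real_, valid = FALSE)
    if (length(counts) < 2 || any(counts < 2) || any(counts < 0.8 * n_expected))
      return(row)
    pmeans <- tapply(sub$value, sub$phantom_id, mean)
    pvars <- tapply(sub$value, sub$phantom_id, var)
    psds <- sqrt(pvars)
    row$grand_mean <- mean(pmeans)
    row$intra_var <- mean(pvars)
    row$inter_var <- var(pmeans)
    row$total_var <- row$intra_var + row$inter_var
    if (row$total_var > 0) {
      row$intra_share <- 100 * row$intra_var / row$total_var
      row$inter_share <- 100 * row$inter_var / row$total_var
    }
    if (row$grand_mean != 0) {
      row$cov_intra <- if (cov_intra_convention == "per_phantom")
        mean(100 * psds / pmeans) else 100 * sqrt(row$intra_var) / row$grand_mean
      row$cov_inter <- 100 * sqrt(row$inter_var) / row$grand_mean
      row$cov_total <- 100 * sqrt(row$total_var) / row$grand_mean
    }
    row$valid <- TRUE
    row
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Coerce a data frame to a variance decomposition
#'
#' Builds a `variance_decomposition` from externally supplied per-metric
#' summaries — e.g. a published table of intra/inter variances or COVs.
#' Shares are (re)computed from `intra_var`/`inter_var` when present; COV
#' columns are passed through when present.
#'
#' @param df A data frame with column `metric` and any of `intra_var`,
#'   `inter_var`, `cov_intra`, `cov_inter`, `cov_total`, `mean`.
#' @return A `variance_decomposition`.
#' @export
as_variance_decomposition <- function(df) {
  stopifnot("metric" %in% names(df))
  reg <- metric_registry()
  out <- data.frame(metric = df$metric,
                    group = reg$group[match(df$metric, reg$metric)],
                    n_phantoms = NA_integer_, n_repeats = NA_integer_,
                    grand_mean = if (!is.null(df$mean)) df$mean else NA_real_,
                    intra_var = if (!is.null(df$intra_var)) df$intra_var else NA_real_,
                    inter_var = if (!is.null(df$inter_var)) df$inter_var else NA_real_,
                    total_var = NA_real_, intra_share = NA_real_,
                    inter_share = NA_real_,
                    cov_intra = if (!is.null(df$cov_intra)) df$cov_intra else NA_real_,
                    cov_inter = if (!is.null(df$cov_inter)) df$cov_inter else NA_real_,
                    cov_total = if (!is.null(df$cov_total)) df$cov_total else NA_real_,
                    valid = TRUE)
  have_vars <- !is.na(out$intra_var) & !is.na(out$inter_var)
  out$total_var[have_vars] <- out$intra_var[have_vars] + out$inter_var[have_vars]
  pos <- have_vars & out$total_var > 0
  out$intra_share[pos] <- 100 * out$intra_var[pos] / out$total_var[pos]
  out$inter_share[pos] <- 100 * out$inter_var[pos] / out$total_var[pos]
  class(out) <- c("variance_decomposition", "data.frame")
  out
}

#' Group summaries of a variance decomposition
#'
#' Unweighted mean and min-max range of the intra- and inter-phantom COVs and
#' of the inter-phantom percent contribution, per metric group (CNR, MTF,
#' Contrast, NR). Requires the decomposition to cover all 64 registry
#' metrics; missing metrics are reported by name.
#'
#' @param decomp A `variance_decomposition`.
#' @return A `group_summary` data frame with one row per group.
#' @export
summarize_groups <- function(decomp) {
  stopifnot(inherits(decomp, "variance_decomposition"))
  reg <- metric_registry()
  missing <- setdiff(reg$metric, decomp$metric)
  if (length(missing))
    stop("decomposition is missing metrics: ", paste(missing, collapse = ", "))
  d <- decomp[match(reg$metric, decomp$metric), ]
  d$group <- reg$group
  stat <- function(x, f) if (all(is.na(x))) NA_real_ else f(x, na.rm = TRUE)
  rows <- lapply(c("CNR", "MTF", "Contrast", "NR"), function(g) {
    s <- d[d$group == g, ]
    data.frame(group = g, n_metrics = nrow(s),
               cov_intra_mean = stat(s$cov_intra, mean),
               cov_intra_min = stat(s$cov_intra, min),
               cov_intra_max = stat(s$cov_intra, max),
               cov_inter_mean = stat(s$cov_inter, mean),
               cov_inter_min = stat(s$cov_inter, min),
               cov_inter_max = stat(s$cov_inter, max),
               inter_share_mean = stat(s$inter_share, mean),
               inter_share_min = stat(s$inter_share, min),
               inter_share_max = stat(s$inter_share, max))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("group_summary", "data.frame")
  out
}
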