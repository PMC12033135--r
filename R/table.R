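# Measurement tables: the 64-metric registry, the direct two-level simulator,
# delimited-text I/O, and table-level defect injection.

#' The 64-metric registry
#'
#' Names and group labels of the 64 image-quality metrics measured on the
#' plate: 34 contrast-to-noise ratios (12 low-contrast 5.6-mm discs, 11 + 11
#' high-contrast 0.5/0.25-mm discs), 5 MTF-related metrics (area under the
#' MTF and the spatial frequencies at 50/20/10/5% of MTF), 10 step-wedge
#' contrasts, and 15 noise ratios (3 particle sizes x 5 steps).
#'
#' @return A data frame with columns `metric`, `group` (one of CNR, MTF,
#'   Contrast, NR), `subgroup` and `index`.
#' @export
metric_registry <- function() {
  rbind(
    data.frame(metric = sprintf("CNR5.6mm#%d", 1:12), group = "CNR",
               subgroup = "CNR5.6mm", index = 1:12),
    data.frame(metric = sprintf("CNR0.5mm#%d", 1:11), group = "CNR",
               subgroup = "CNR0.5mm", index = 1:11),
    data.frame(metric = sprintf("CNR0.25mm#%d", 1:11), group = "CNR",
               subgroup = "CNR0.25mm", index = 1:11),
    data.frame(metric = c("AUMTF", "SpFreq@50%MTF", "SpFreq@20%MTF",
                          "SpFreq@10%MTF", "SpFreq@5%MTF"),
               group = "MTF", subgroup = "MTF", index = 1:5),
    data.frame(metric = sprintf("Contrast#%d", 1:10), group = "Contrast",
               subgroup = "Contrast", index = 1:10),
    data.frame(metric = sprintf("NR328um#%d", 1:5), group = "NR",
               subgroup = "NR328um", index = 1:5),
    data.frame(metric = sprintf("NR234um#%d", 1:5), group = "NR",
               subgroup = "NR234um", index = 1:5),
    data.frame(metric = sprintf("NR125um#%d", 1:5), group = "NR",
               subgroup = "NR125um", index = 1:5)
  )
}

.as_measurement_table <- function(df) {
  stopifnot(all(c("phantom_id", "repeat_index", "metric", "value") %in% names(df)))
  if (is.null(df$valid)) df$valid <- !is.na(df$value)
  class(df) <- c("measurement_table", "data.frame")
  df
}

#' Two-level simulation specification
#'
#' Defines a direct simulation of the phantom x repeat x metric measurement
#' structure: `value(p, r, m) = mu_m + b_{p,m} + e_{p,r,m}` with
#' `b ~ N(0, sigma_inter^2)` (manufacturing level, constant over repeats of
#' one phantom) and `e ~ N(0, sigma_intra^2)` (exposure level), independent.
#'
#' @param mu Named numeric vector of per-metric grand means (names are metric
#'   names; defaults to the 64-metric registry if unnamed of length 64).
#' @param sigma_intra,sigma_inter Per-metric SDs (recycled to `length(mu)`),
#'   all >= 0.
#' @param n_phantoms,n_repeats Design size (>= 2 each).
#' @param seed Integer seed.
#' @return An object of class `two_level_spec`.
#' @export
two_level_spec <- function(mu, sigma_intra, sigma_inter,
                           n_phantoms, n_repeats, seed = 1L) {
  if (is.null(names(mu))) {
    reg <- metric_registry()
    names(mu) <- if (length(mu) == nrow(reg)) reg$metric
                 else sprintf("metric%03d", seq_along(mu))
  }
  sigma_intra <- rep_len(sigma_intra, length(mu))
  sigma_inter <- rep_len(sigma_inter, length(mu))
  if (any(sigma_intra < 0) || any(sigma_inter < 0)) stop("SDs must be >= 0")
  if (n_phantoms < 2 || n_repeats < 2) stop("need >= 2 phantoms and >= 2 repeats")
  structure(list(mu = mu, sigma_intra = sigma_intra, sigma_inter = sigma_inter,
                 n_phantoms = as.integer(n_phantoms),
                 n_repeats = as.integer(n_repeats),
                 seed = as.integer(seed)),
            class = "two_level_spec")
}

#' Simulate a measurement table from a two-level specification
#'
#' @param spec A [two_level_spec()].
#' @return A `measurement_table` data frame with columns `phantom_id`,
#'   `repeat_index`, `metric`, `value`, `valid`, deterministic under the
#'   spec's seed.
#' @examples
#' sp <- two_level_spec(mu = c(a = 100), sigma_intra = 1, sigma_inter = 3,
#'                      n_phantoms = 4, n_repeats = 3, seed = 1)
#' head(simulate_measurement_table(sp))
#' @export
simulate_measurement_table <- function(spec) {
  stopifnot(inherits(spec, "two_level_spec"))
  m <- length(spec$mu)
  ids <- sprintf("PH%03d", seq_len(spec$n_phantoms))
  .with_seed(.derive_seed(spec$seed, "two-level"), {
    b <- matrix(rnorm(spec$n_phantoms * m, 0, rep(spec$sigma_inter, each = spec$n_phantoms)),
                spec$n_phantoms, m)
    out <- vector("list", spec$n_phantoms)
    for (p in seq_len(spec$n_phantoms)) {
      e <- matrix(rnorm(spec$n_repeats * m, 0, rep(spec$sigma_intra, each = spec$n_repeats)),
                  spec$n_repeats, m)
      vals <- sweep(e, 2, spec$mu + b[p, ], `+`)
      out[[p]] <- data.frame(
        phantom_id = ids[p],
        repeat_index = rep(seq_len(spec$n_repeats), times = m),
        metric = rep(names(spec$mu), each = spec$n_repeats),
        value = as.vector(vals))
    }
    .as_measurement_table(do.call(rbind, out))
  })
}

#' Inject a table-level single-metric defect
#'
#' Shifts all repeats of one phantom on one metric by `shift_sd` times the
#' between-phantom SD of that metric's phantom means (computed from the table
#' before injection). This emulates, at the measurement-table level, a
#' defective detail that displaces one phantom's mean far from the grand mean.
#'
#' @param table A `measurement_table`.
#' @param phantom_id,metric The targeted phantom and metric.
#' @param shift_sd Shift magnitude in units of the phantom-mean SD.
#' @return The modified table.
#' @export
inject_table_defect <- function(table, phantom_id, metric, shift_sd) {
  stopifnot(inherits(table, "measurement_table"))
  rows <- table$metric == metric
  if (!any(rows)) stop("unknown metric: ", metric)
  pm <- tapply(table$value[rows], table$phantom_id[rows], mean)
  tgt <- rows & table$phantom_id == phantom_id
  if (!any(tgt)) stop("unknown phantom: ", phantom_id)
  table$value[tgt] <- table$value[tgt] + shift_sd * sd(pm)
  table
}

#' Write / read a measurement table as delimited text
#'
#' Long-format CSV with header `phantom_id,repeat_index,metric,value,valid`.
#'
#' @param table A `measurement_table`.
#' @param path File path.
#' @return `write_measurement_table` returns `path` invisibly; the reader
#'   returns a `measurement_table`.
#' @export
write_measurement_table <- function(table, path) {
  stopifnot(inherits(table, "measurement_table"))
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_measurement_table
#' @export
read_measurement_table <- function(path) {
  .as_measurement_table(read.csv(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
}
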