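make_table <- function(values_by_phantom, metric = "m") {
  rows <- do.call(rbind, lapply(seq_along(values_by_phantom), function(p) {
    v <- values_by_phantom[[p]]
    data.frame(phantom_id = sprintf("PH%03d", p), repeat_index = seq_along(v),
               metric = metric, value = v, valid = TRUE)
  }))
  class(rows) <- c("measurement_table", "data.frame")
  rows
}

test_that("the hand-computed two-phantom example decomposes exactly", {
  tab <- make_table(list(c(10, 12), c(14, 16)))
  d <- decompose(tab)
  expect_equal(d$intra_var, 2)
  expect_equal(d$inter_var, 8)
  expect_equal(d$total_var, 10)
  expect_equal(d$inter_share, 80)
  expect_equal(d$intra_share, 20)
})

test_that("decompose matches a brute-force loop implementation on small tables", {
  set.seed(71)
  for (np in 2:4) {
    for (nr in 2:3) {
      tab <- make_table(lapply(seq_len(np), function(i) 5 + rnorm(nr, sd = 2)))
      d <- decompose(tab)
      o <- brute_decompose(tab, "m")
      expect_equal(d$intra_var, o$intra, tolerance = 1e-12)
      expect_equal(d$inter_var, o$inter, tolerance = 1e-12)
      expect_equal(d$total_var, o$total, tolerance = 1e-12)
      expect_equal(d$inter_share, o$inter_share, tolerance = 1e-12)
      expect_equal(d$grand_mean, o$grand_mean, tolerance = 1e-12)
      expect_equal(d$cov_intra, o$cov_intra, tolerance = 1e-12)
      expect_equal(d$cov_inter, o$cov_inter, tolerance = 1e-12)
      expect_equal(d$cov_total, o$cov_total, tolerance = 1e-12)
    }
  }
})

test_that("decomposition invariants hold on simulated tables", {
  sp <- reference_simulation_spec(n_phantoms = 8, n_repeats = 4, seed = 5)
  d <- decompose(simulate_measurement_table(sp))
  expect_true(all(d$valid))
  expect_equal(d$total_var, d$intra_var + d$inter_var)
  expect_equal(d$intra_share + d$inter_share, rep(100, 64))
  expect_true(all(d$intra_var >= 0 & d$inter_var >= 0))
  # with the grand-mean convention the COVs satisfy exact quadrature
  dg <- decompose(simulate_measurement_table(sp),
                  cov_intra_convention = "grand_mean")
  expect_equal(dg$cov_total^2, dg$cov_intra^2 + dg$cov_inter^2,
               tolerance = 1e-9)
  # per-phantom convention differs from (and is usually near) the grand-mean one
  expect_false(all(d$cov_intra == dg$cov_intra))
})

test_that("degenerate identical measurements yield zero variance, undefined shares", {
  tab <- make_table(list(rep(7, 3), rep(7, 3), rep(7, 3)))
  d <- decompose(tab)
  expect_equal(d$intra_var, 0)
  expect_equal(d$inter_var, 0)
  expect_true(is.na(d$inter_share))
  # zero grand mean: COVs undefined
  tab0 <- make_table(list(c(-1, 1), c(2, -2)))
  d0 <- decompose(tab0)
  expect_true(is.na(d0$cov_inter))
  expect_false(is.na(d0$intra_var))
})

test_that("a phantom missing too many repeats makes the metric undefined", {
  sp <- two_level_spec(mu = c(a = 10, b = 20), sigma_intra = 1,
                       sigma_inter = 1, n_phantoms = 4, n_repeats = 10, seed = 2)
  tab <- simulate_measurement_table(sp)
  drop <- tab$metric == "a" & tab$phantom_id == "PH002" & tab$repeat_index <= 3
  tab$valid[drop] <- FALSE
  d <- decompose(tab)
  expect_false(d$valid[d$metric == "a"])
  expect_true(d$valid[d$metric == "b"])
})

test_that("outlier screening flags constructed defects and spares clean phantoms", {
  # note the screen is one-pass: the defect inflates the SD it is compared
  # against (variance grows by ~shift^2/n), so detectability needs either a
  # large shift or enough phantoms; 8 SD at n = 24 sits at ~4 contaminated SDs
  sp <- two_level_spec(mu = c(a = 100, b = 50), sigma_intra = 1,
                       sigma_inter = 2, n_phantoms = 24, n_repeats = 6, seed = 9)
  tab <- simulate_measurement_table(sp)
  bad <- inject_table_defect(tab, "PH007", "a", shift_sd = 8)
  rep <- detect_defective(bad, k = 3)
  expect_true("PH007" %in% rep$excluded)
  expect_identical(rep$flagged$metric[rep$flagged$phantom_id == "PH007"], "a")
  clean <- remove_excluded(bad, rep)
  expect_false("PH007" %in% clean$phantom_id)
  expect_identical(length(unique(clean$phantom_id)), 23L)

  # identical phantoms: zero SD, nothing flagged
  tab0 <- make_table(list(rep(5, 3), rep(5, 3), rep(5, 3)))
  expect_length(detect_defective(tab0)$excluded, 0)

  expect_error(detect_defective(make_table(list(1:3, 4:6))), "3 phantoms")
})

test_that("group summaries require full coverage and average correctly", {
  covs <- reference_covs()
  # constant COVs: every group mean equals the constant with zero range
  const <- as_variance_decomposition(
    data.frame(metric = covs$metric, cov_intra = 3, cov_inter = 3))
  gs <- summarize_groups(const)
  expect_equal(gs$cov_intra_mean, rep(3, 4))
  expect_equal(gs$cov_intra_min, gs$cov_intra_max)

  short <- as_variance_decomposition(
    data.frame(metric = covs$metric[-5], cov_intra = covs$cov_intra[-5]))
  expect_error(summarize_groups(short), covs$metric[5], fixed = TRUE)
})
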