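lay <- default_layout()
tf0 <- rigid_transform(0, 0, 0)

test_that("large-disc CNR matches its analytic expectation under noise", {
  # synthetic disc of depth D on background B with noise SD s: CNR ~ D/s
  B <- 10000; D <- 150; s <- 60
  disc <- list(x = 0, y = 0, diameter = 5.6)
  base <- flat_image(n = 200, pitch = 0.1, level = B)
  dmat <- sqrt(outer(phantomqc:::.img_ys(base)^2,
                     phantomqc:::.img_xs(base)^2, `+`))
  signal <- base$pixels - D * (dmat <= disc$diameter / 2)
  set.seed(99)
  cnrs <- replicate(100, {
    img <- base
    img$pixels <- signal + matrix(rnorm(length(signal), 0, s), nrow(signal))
    cnr_large(img, tf0, disc)
  })
  expect_lt(abs(mean(cnrs) - D / s), 3 * sd(cnrs) / sqrt(100) + 0.02)
  # noiseless image: zero background SD -> undefined metric
  noiseless <- base; noiseless$pixels <- signal
  expect_true(is.na(cnr_large(noiseless, tf0, disc)))
  expect_error(cnr_large(base, tf0, list(x = 0, y = 0, diameter = 1)), "20 pixels")
})

test_that("noiseless detail signals decrease strictly along each graded series", {
  sys <- fine_system(seed = 12)
  pop <- sample_phantom_population(lay, 1, 0, seed = 12, jitter_sd = 0)
  img <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                              noise = FALSE, quantize = FALSE)
  large <- sapply(seq_len(12), function(k) {
    d <- lay$discs_large[k, ]
    inner <- phantomqc:::.roi_disc(img, d$x, d$y, 0.35 * d$diameter)
    ann <- phantomqc:::.roi_annulus(img, d$x, d$y, d$diameter / 2 + 1,
                                    d$diameter / 2 + 3)
    mean(ann) - mean(inner)
  })
  expect_true(all(diff(large) < 0))
  for (g in c("discs_small_05", "discs_small_025")) {
    amps <- sapply(seq_len(nrow(lay[[g]])), function(k)
      detail_signal(img, tf0, lay[[g]][k, ], fine_opts()))
    expect_true(all(diff(amps) < 0))
  }
})

test_that("the matched filter recovers blurred sub-ROI amplitudes and is linear", {
  sys <- fine_system(seed = 13)
  pop <- sample_phantom_population(lay, 1, 0, seed = 13, jitter_sd = 0)
  img <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                              noise = FALSE, quantize = FALSE)
  # expected amplitude: the pre-blur contrast depth, contrast x dose
  d <- lay$discs_small_05[2, ]
  a <- detail_signal(img, tf0, d, fine_opts())
  expect_lt(abs(a / (d$contrast * sys$photon_level) - 1), 0.02)

  # halving one realized contrast halves the extracted signal (noiseless)
  half <- inject_defect(pop[[1]], defect_spec("scale_detail_contrast",
                                              "discs_small_025", 4, 0.5), lay)
  img_h <- render_phantom_image(lay, half, sys, 1, transform = tf0,
                                noise = FALSE, quantize = FALSE)
  d4 <- lay$discs_small_025[4, ]
  expect_lt(abs(detail_signal(img_h, tf0, d4, fine_opts()) /
                detail_signal(img, tf0, d4, fine_opts()) - 0.5), 0.01)
})

test_that("a swapped pair of high-contrast details inverts the CNR ordering", {
  sys <- fine_system(seed = 14)
  pop <- sample_phantom_population(lay, 1, 0, seed = 14)
  good <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0)
  bad_params <- inject_defect(pop[[1]], defect_spec("swap_details",
                                                    "discs_small_05", c(1, 2)), lay)
  bad <- render_phantom_image(lay, bad_params, sys, 1, transform = tf0)
  c_good <- sapply(1:2, function(k)
    cnr_small(good, tf0, lay$discs_small_05[k, ], fine_opts()))
  c_bad <- sapply(1:2, function(k)
    cnr_small(bad, tf0, lay$discs_small_05[k, ], fine_opts()))
  expect_gt(c_good[1], c_good[2])
  expect_lt(c_bad[1], c_bad[2])
})

test_that("MTF curve summaries behave on hand-built curves", {
  flat <- make_curve(c(1, 20), c(1, 1))
  expect_equal(aumtf(flat), 19)
  tri <- make_curve(c(1, 20), c(1, 0))
  expect_equal(aumtf(tri), 9.5)
  expect_equal(freq_at_fraction(tri, 0.5), 10.5)
  curve <- make_curve(seq(1, 10), exp(-0.08 * seq(1, 10)^2))
  fr <- sapply(c(0.5, 0.2, 0.1, 0.05), freq_at_fraction, curve = curve)
  expect_true(all(diff(fr) >= 0))
  # starts below the fraction, or never crosses: undefined
  expect_true(is.na(freq_at_fraction(make_curve(1:5, rep(0.4, 5)), 0.5)))
  expect_true(is.na(freq_at_fraction(make_curve(1:5, rep(0.6, 5)), 0.5)))
  one_pt <- make_curve(c(1, 2), c(1, 1), valid = c(TRUE, FALSE))
  expect_true(is.na(aumtf(one_pt)))
})

test_that("noise-dominated bar patterns clip to zero modulation", {
  sys <- test_system(seed = 15, blur_sigma = 0.4)
  pop <- sample_phantom_population(lay, 1, 0, seed = 15)
  img <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0)
  curve <- mtf_from_bars(img, tf0, lay, test_opts(blur_sigma = 0.4))
  v <- curve$mtf[curve$valid & curve$frequency > 1.3]
  expect_true(any(v == 0))
  expect_true(all(v < 0.2))
})

test_that("step contrasts reproduce nominal attenuations and are dose invariant", {
  sys <- fine_system(seed = 16)
  pop <- sample_phantom_population(lay, 1, 0, seed = 16)
  img <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                              noise = FALSE, quantize = FALSE)
  for (k in c(1, 5, 10)) {
    expect_lt(abs(step_contrast(img, tf0, lay, k) -
                  100 * lay$wedge$contrast[k]), 0.1)
  }
  # flat image: step equals background -> 0%
  flat <- flat_image(n = 1100, pitch = 0.25, level = 5000)
  expect_equal(step_contrast(flat, tf0, lay, 3), 0)
  # scaling the whole image leaves contrast unchanged exactly
  noisy <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                                quantize = FALSE)
  scaled <- noisy; scaled$pixels <- noisy$pixels * 3
  for (k in c(2, 7)) {
    expect_equal(step_contrast(scaled, tf0, lay, k),
                 step_contrast(noisy, tf0, lay, k))
  }
})

test_that("noise ratios reflect structured texture: absence, amplitude, size", {
  sys <- test_system(seed = 17)
  pop <- sample_phantom_population(lay, 1, 0, seed = 17)
  # no particles -> NR ~ 1
  bare <- pop[[1]]; bare$density_mult <- rep(0, 15)
  img0 <- render_phantom_image(lay, bare, sys, 1, transform = tf0)
  for (s in c(328, 125)) {
    expect_lt(abs(noise_ratio(img0, tf0, lay, s, 3, test_opts()) - 1), 0.35)
  }
  # doubling particle depth quadruples the structured variance (noiseless)
  deeper <- lay
  deeper$particles$particle_depth <- 2 * lay$particles$particle_depth
  a <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                            noise = FALSE, quantize = FALSE)
  b <- render_phantom_image(deeper, pop[[1]], sys, 1, transform = tf0,
                            noise = FALSE, quantize = FALSE)
  pr <- lay$particles[lay$particles$size_um == 328 & lay$particles$step == 4, ]
  va <- var(phantomqc:::.roi_rect_plate(a, tf0, pr$x, pr$y, 6, 6))
  vb <- var(phantomqc:::.roi_rect_plate(b, tf0, pr$x, pr$y, 6, 6))
  expect_lt(abs(vb / va - 4), 1e-6)
  # at equal area coverage, larger particles produce more structured variance
  eq <- lay
  cover <- 0.15
  e_r2 <- (eq$particles$median_diameter / 2)^2 * exp(2 * 0.2^2)
  eq$particles$density <- cover / (pi * e_r2)
  sysf <- fine_system(seed = 17)
  imgf <- render_phantom_image(eq, pop[[1]], sysf, 1, transform = tf0,
                               noise = FALSE, quantize = FALSE)
  vs <- sapply(c(125, 234, 328), function(s) {
    pr <- eq$particles[eq$particles$size_um == s & eq$particles$step == 4, ]
    var(phantomqc:::.roi_rect_plate(imgf, tf0, pr$x, pr$y, 6, 6))
  })
  expect_true(all(diff(vs) > 0))
})

test_that("CNR scales inversely with noise (quadrupled dose doubles CNR)", {
  pop <- sample_phantom_population(lay, 1, 0, seed = 18)
  cnr_at <- function(P) {
    sys <- test_system(seed = 18, photon_level = P)
    mean(sapply(1:3, function(r) {
      img <- render_phantom_image(lay, pop[[1]], sys, r, transform = tf0)
      cnr_large(img, tf0, lay$discs_large[3, ], test_opts())
    }))
  }
  expect_lt(abs(cnr_at(40000) / cnr_at(10000) - 2), 0.2)
})

test_that("extraction is complete, deterministic and transform equivariant", {
  sys <- fine_system(seed = 19)
  # jitter-free phantom so the check isolates sampling/interpolation effects
  # (placement jitter is a modelled manufacturing property, not an extraction
  # artefact)
  pop <- sample_phantom_population(lay, 1, 0.05, seed = 19, jitter_sd = 0)
  img <- render_phantom_image(lay, pop[[1]], sys, 1)
  mv1 <- extract_all(img, lay, fine_opts())
  mv2 <- extract_all(img, lay, fine_opts())
  expect_identical(nrow(mv1), 64L)
  expect_true(all(mv1$valid))
  expect_identical(mv1$value, mv2$value)

  # equivariance on noiseless renders under a known transform
  tfA <- rigid_transform(2, -1, 1)
  i0 <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                             noise = FALSE, quantize = FALSE)
  iA <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tfA,
                             noise = FALSE, quantize = FALSE)
  for (k in c(1, 5, 10)) {
    c0 <- step_contrast(i0, tf0, lay, k)
    cA <- step_contrast(iA, tfA, lay, k)
    expect_lt(abs(cA / c0 - 1), 0.01)
  }
  m0 <- mtf_from_bars(i0, tf0, lay, fine_opts())
  mA <- mtf_from_bars(iA, tfA, lay, fine_opts())
  for (fr in c(0.5, 0.2, 0.1, 0.05)) {
    expect_lt(abs(freq_at_fraction(mA, fr) / freq_at_fraction(m0, fr) - 1), 0.02)
  }
  for (k in c(1, 6)) {
    d <- lay$discs_small_05[k, ]
    expect_lt(abs(detail_signal(iA, tfA, d, fine_opts()) /
                  detail_signal(i0, tf0, d, fine_opts()) - 1), 0.01)
  }
})
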