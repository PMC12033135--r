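lay <- default_layout()

test_that("noiseless unblurred rendering reproduces nominal contrasts exactly", {
  sys <- system_params(pixel_pitch = 0.25, blur_sigma = 0, rng_seed = 2)
  pop <- sample_phantom_population(lay, 1, 0, seed = 2, jitter_sd = 0)
  img <- render_phantom_image(lay, pop[[1]], sys, 1,
                              transform = rigid_transform(0, 0, 0),
                              noise = FALSE, quantize = FALSE)
  P <- sys$photon_level
  # background pixels far from any detail
  bg <- phantomqc:::.roi_disc(img, -95, 30, 3)
  expect_equal(max(abs(bg - P)), 0)
  for (k in c(1, 6, 12)) {
    d <- lay$discs_large[k, ]
    interior <- phantomqc:::.roi_disc(img, d$x, d$y, d$diameter / 2 - 0.3)
    expect_lt(max(abs(interior - P * (1 - d$contrast))) / P, 1e-9)
  }
  w <- lay$wedge[1, ]
  step <- phantomqc:::.roi_rect_plate(img, rigid_transform(0, 0, 0),
                                      w$x, w$y, w$side - 1, w$side - 1)
  expect_lt(max(abs(step - P * (1 - w$contrast))) / P, 1e-9)
})

test_that("rendering is deterministic and particle texture is frozen per phantom", {
  sys <- test_system(seed = 7)
  pop <- sample_phantom_population(lay, 2, 0, seed = 7)
  a <- render_phantom_image(lay, pop[[1]], sys, 1)
  b <- render_phantom_image(lay, pop[[1]], sys, 1)
  expect_identical(a$pixels, b$pixels)

  # same phantom, two repeats, fixed transform, no noise -> identical texture
  i1 <- render_phantom_image(lay, pop[[1]], sys, 1,
                             transform = rigid_transform(0, 0, 0), noise = FALSE)
  i2 <- render_phantom_image(lay, pop[[1]], sys, 2,
                             transform = rigid_transform(0, 0, 0), noise = FALSE)
  expect_identical(i1$pixels, i2$pixels)

  # different phantoms -> different texture in the particle steps
  j1 <- render_phantom_image(lay, pop[[2]], sys, 1,
                             transform = rigid_transform(0, 0, 0), noise = FALSE)
  pr <- lay$particles[lay$particles$size_um == 328 & lay$particles$step == 5, ]
  tf0 <- rigid_transform(0, 0, 0)
  v1 <- phantomqc:::.roi_rect_plate(i1, tf0, pr$x, pr$y, 6, 6)
  v2 <- phantomqc:::.roi_rect_plate(j1, tf0, pr$x, pr$y, 6, 6)
  expect_gt(max(abs(v1 - v2)), 0)

  # with noise on, repeats of one phantom differ
  n1 <- render_phantom_image(lay, pop[[1]], sys, 1,
                             transform = rigid_transform(0, 0, 0))
  n2 <- render_phantom_image(lay, pop[[1]], sys, 2,
                             transform = rigid_transform(0, 0, 0))
  expect_gt(max(abs(n1$pixels - n2$pixels)), 0)
})

test_that("quantum noise follows the dose surrogate (quadrupled dose doubles SD)", {
  pop <- sample_phantom_population(lay, 1, 0, seed = 4)
  tf0 <- rigid_transform(0, 0, 0)
  sds <- sapply(c(10000, 40000), function(P) {
    sys <- test_system(seed = 4, photon_level = P)
    img <- render_phantom_image(lay, pop[[1]], sys, 1, transform = tf0,
                                quantize = FALSE)
    sd(phantomqc:::.roi_rect_plate(img, tf0, lay$refs$noise$x,
                                   lay$refs$noise$y, 7, 7))
  })
  expect_lt(abs(sds[2] / sds[1] - 2), 0.1)
})

test_that("rendered images are valid 16-bit rasters and round-trip through TIFF", {
  sys <- test_system(seed = 8)
  pop <- sample_phantom_population(lay, 1, 0.1, seed = 8)
  img <- render_phantom_image(lay, pop[[1]], sys, 3)
  expect_true(all(img$pixels >= 0 & img$pixels <= 65535))
  expect_true(all(img$pixels == round(img$pixels)))
  path <- tempfile(fileext = ".tif")
  write_phantom_image(img, path)
  back <- read_phantom_image(path)
  expect_equal(back$pixels, img$pixels, ignore_attr = TRUE)
  expect_equal(back$pixel_pitch, img$pixel_pitch)
  expect_identical(back$phantom_id, img$phantom_id)
  expect_identical(back$repeat_index, img$repeat_index)
  expect_equal(back$applied_transform$rotation, img$applied_transform$rotation)
  unlink(c(path, paste0(path, ".json")))
})

test_that("PGM output round-trips", {
  img <- flat_image(n = 20, level = 1234)
  img$pixels[3, 7] <- 42
  path <- tempfile(fileext = ".pgm")
  write_phantom_image(img, path)
  back <- read_phantom_image(path)
  expect_equal(back$pixels, img$pixels, ignore_attr = TRUE)
  unlink(c(path, paste0(path, ".json")))
})

test_that("invalid system parameters are rejected", {
  expect_error(system_params(blur_sigma = -1), "blur")
  expect_error(system_params(photon_level = 0), "photon")
  expect_error(system_params(pixel_pitch = 0), "pitch")
  expect_error(system_params(electronic_noise_sd = -2), "SD")
})
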