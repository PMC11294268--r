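test_that("band sampling returns the expected counts and values", {
  # constant image: every sample equals the constant
  img <- matrix(42, 50, 50)
  disc <- disc_mask(50, 50, r = 12)
  ct <- extract_contour(disc)
  s <- sample_boundary_band(img, ct, 10, mask = disc)
  expect_equal(range(s), c(42, 42), tolerance = 1e-12)

  # fully interior contour: exactly 2*h + 1 samples per contour point
  expect_length(s, nrow(ct) * 21L)
  pp <- attr(s, "per_point")
  expect_true(all(pp$inward == 10L & pp$outward == 10L))

  expect_error(sample_boundary_band(img, ct, halfwidth = 0), "halfwidth")
  far <- cbind(row = 60, col = 60)
  expect_error(sample_boundary_band(img, far, 10), "outside")
})

test_that("a vertical step edge yields samples from exactly the two plateaus", {
  img <- cbind(matrix(0, 64, 32), matrix(255, 64, 32))
  mask <- cbind(matrix(TRUE, 64, 32), matrix(FALSE, 64, 32))
  s <- sample_boundary_band(img, extract_contour(mask), 10, mask = mask)
  expect_true(all(s %in% c(0, 255)))
  expect_gt(mean(s == 0), 0.4)   # both plateaus are represented
  expect_gt(mean(s == 255), 0.2)
})

test_that("densities are normalised and reflect the sample structure", {
  set.seed(31)
  narrow <- rnorm(500, mean = 120, sd = 4)
  d <- estimate_density(narrow)
  expect_equal(sum(diff(d$x) * (head(d$y, -1) + tail(d$y, -1)) / 2), 1,
               tolerance = 1e-3)
  expect_lt(abs(d$x[which.max(d$y)] - 120), 5)

  two_pt <- rep(c(0, 255), 400)
  d2 <- estimate_density(two_pt)
  expect_equal(classify_modality(d2), "bimodal")
  pk <- sort(d2$x[order(d2$y, decreasing = TRUE)[1:2]])
  expect_lt(pk[1], 20); expect_gt(pk[2], 235)

  # degenerate: constant samples are unimodal by convention
  d3 <- estimate_density(rep(77, 50))
  expect_true(d3$degenerate)
  expect_equal(classify_modality(d3), "unimodal")
})

test_that("modality classification counts well-separated mixture components", {
  set.seed(8)
  one <- rnorm(1200, 128, 10)
  two <- c(rnorm(600, 60, 8), rnorm(600, 190, 8))    # > 5 sigma apart
  three <- c(rnorm(400, 40, 6), rnorm(400, 128, 6), rnorm(400, 215, 6))
  expect_equal(classify_modality(estimate_density(one)), "unimodal")
  expect_equal(classify_modality(estimate_density(two)), "bimodal")
  expect_equal(classify_modality(estimate_density(three)), "other")

  # affine intensity rescaling does not change the class
  for (s in list(one, two, three)) {
    scaled <- s * 0.5 + 40
    expect_equal(classify_modality(estimate_density(scaled)),
                 classify_modality(estimate_density(s)))
  }
})

test_that("the blurred-circle phantom behaves as the calibration requires", {
  sharp <- make_blurred_circle(40, c(128, 128))
  expect_length(unique(as.vector(sharp$image)), 2L)
  expect_identical(sharp$mask, disc_mask(128, 128, r = 40))

  # blur moves the image but never the defined boundary
  blurred <- make_blurred_circle(40, c(128, 128),
                                 blur = blur_config("gaussian", 8))
  expect_identical(blurred$mask, sharp$mask)
  band <- sample_boundary_band(blurred$image, extract_contour(blurred$mask),
                               10, mask = blurred$mask)
  expect_gt(length(unique(round(band, 3))), 2L)

  # protrusions alter the image, not the mask
  spiky <- make_blurred_circle(40, c(128, 128),
                               blur = blur_config("box", 3, protrusions = TRUE))
  expect_identical(spiky$mask, sharp$mask)
  expect_gt(sum(spiky$image < 128), sum(blurred$image < 128) - 1)

  expect_error(make_blurred_circle(60, c(100, 100)), "does not fit")
})

test_that("dispersion study composes the pipeline and classifies the phantom", {
  sharp <- make_blurred_circle(40, c(128, 128))
  prof <- dispersion_study(sharp$image, sharp$mask)
  expect_s3_class(prof, "boundary_band_profile")
  expect_equal(prof$modality, "bimodal")
  expect_length(prof$peaks, 2L)

  hazy <- make_blurred_circle(100, c(290, 290),
                              blur = blur_config("gaussian", 100 / 3))
  expect_equal(dispersion_study(hazy$image, hazy$mask)$modality, "unimodal")

  flat <- dispersion_study(matrix(9, 60, 60), disc_mask(60, 60, r = 15))
  expect_equal(flat$modality, "unimodal")
})

test_that("band sampling is symmetric on the circle phantom", {
  ph <- make_blurred_circle(30, c(100, 100))
  s <- sample_boundary_band(ph$image, extract_contour(ph$mask), 10,
                            mask = ph$mask)
  pp <- attr(s, "per_point")
  expect_true(all(abs(pp$inward - pp$outward) <= 1L))
})
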