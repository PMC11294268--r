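test_that("reference lesions are deterministic, star-convex and sized as specified", {
  spec <- synthetic_spec(seed = 7)
  ref1 <- make_reference_lesion(spec)
  ref2 <- make_reference_lesion(spec)
  expect_identical(ref1, ref2)
  expect_false(identical(ref1, make_reference_lesion(spec, seed = 8)))

  # zero lobes -> smooth ellipse; pixel area within 10% of the analytic area
  smooth_spec <- synthetic_spec(lobe_amplitude = 0, radius = 35, seed = 2)
  ell <- make_reference_lesion(smooth_spec)
  a <- 35 * sqrt(smooth_spec$ellipticity); b <- 35 / sqrt(smooth_spec$ellipticity)
  expect_equal(sum(ell), pi * a * b, tolerance = 0.1)

  # lobed outline: the stored radial function gives the continuous area
  theta <- attr(ref1, "theta"); radii <- attr(ref1, "radii")
  analytic <- sum(radii^2) * (2 * pi / length(theta)) / 2
  expect_equal(sum(ref1), analytic, tolerance = 0.1)

  expect_error(synthetic_spec(radius = 90, image_size = c(100, 100)),
               "does not fit")
})

test_that("annotator jitter behaves as a boundary-disagreement model", {
  spec <- synthetic_spec(seed = 12)
  ref <- make_reference_lesion(spec)

  expect_identical(simulate_annotator(ref, 0, 25, seed = 1), ref)

  a1 <- simulate_annotator(ref, 3, 25, seed = 100)
  a2 <- simulate_annotator(ref, 3, 25, seed = 101)
  expect_false(identical(a1, a2))
  expect_identical(a1, simulate_annotator(ref, 3, 25, seed = 100))

  # smaller jitter -> masks closer to the reference (Monte-Carlo ordering)
  mean_iou <- function(sig, reps = 20)
    mean(vapply(seq_len(reps), function(k)
      iou(ref, simulate_annotator(ref, sig, 25, seed = 1000 * sig + k)),
      numeric(1)))
  expect_gt(mean_iou(2), mean_iou(8))

  expect_error(simulate_annotator(ref, 60, 40, seed = 5), "degenerate|exits")
})

test_that("ray-cast fallback recovers the outline of a plain mask", {
  # a disc with no outline attributes: jitter still works on it
  plain <- disc_mask(120, 120, r = 30)
  sim <- simulate_annotator(plain, 2, 20, seed = 9)
  expect_gt(iou(plain, sim), 0.8)
  expect_lt(iou(plain, sim), 1)
})

test_that("textures honour contrast, speckle and blur settings", {
  spec0 <- synthetic_spec(speckle_sigma = 0, blur_sigma = 0,
                          inside = 200, outside = 50, seed = 3)
  ref <- make_reference_lesion(spec0)
  img <- render_us_texture(ref, spec0)
  expect_setequal(unique(as.vector(img)), c(50, 200))

  # sharp full-contrast texture reduces to the sharp phantom: bimodal band
  spec_sharp <- synthetic_spec(speckle_sigma = 0, blur_sigma = 0,
                               inside = 255, outside = 0, seed = 3)
  img_sharp <- render_us_texture(ref, spec_sharp)
  expect_equal(dispersion_study(img_sharp, ref)$modality, "bimodal")

  # heavy blur relative to the lesion radius: indistinct, unimodal band
  spec_hazy <- synthetic_spec(image_size = c(200, 200), radius = 60,
                              lobe_amplitude = 0, ellipticity = 1,
                              speckle_sigma = 0, blur_sigma = 20,
                              inside = 255, outside = 0, seed = 3)
  ref_hazy <- make_reference_lesion(spec_hazy)
  img_hazy <- render_us_texture(ref_hazy, spec_hazy)
  expect_equal(dispersion_study(img_hazy, ref_hazy)$modality, "unimodal")

  expect_identical(render_us_texture(ref, synthetic_spec(seed = 3)),
                   render_us_texture(ref, synthetic_spec(seed = 3)))
})

test_that("cohorts are reproducible and sized by the design", {
  spec <- synthetic_spec(image_size = c(128, 128), radius = 26, seed = 77)
  cohort <- generate_cohort(spec, n_images = 30)
  expect_length(cohort, 30L)
  expect_true(all(vapply(cohort, function(x) length(x$annotators), integer(1)) == 3L))
  expect_true(all(vapply(cohort, function(x) any(x$reference), logical(1))))

  small1 <- generate_cohort(spec, n_images = 4)
  small2 <- generate_cohort(spec, n_images = 4)
  expect_identical(small1, small2)

  # mean pairwise annotator IoU decreases as jitter grows
  mean_pair_iou <- function(sig) {
    sp <- synthetic_spec(image_size = c(144, 144), radius = 26,
                         jitter_sigma = sig, seed = 501)
    co <- generate_cohort(sp, n_images = 8)
    mean(vapply(co, function(img)
      mean(pairwise_agreement(img$annotators)$iou), numeric(1)))
  }
  m <- vapply(c(1, 4, 8), mean_pair_iou, numeric(1))
  expect_true(all(diff(m) < 0))
})
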