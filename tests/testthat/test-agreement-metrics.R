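shifted_blocks <- function() {
  a <- matrix(FALSE, 6, 6); a[1:2, 1:2] <- TRUE
  b <- matrix(FALSE, 6, 6); b[1:2, 2:3] <- TRUE
  list(a = a, b = b)
}

test_that("overlap metrics match hand-counted examples and error on bad input", {
  p <- shifted_blocks()
  expect_equal(iou(p$a, p$b), 2 / 6)    # intersection 2, union 6
  expect_equal(dsc(p$a, p$b), 0.5)      # 2*2 / (4+4)

  m <- rand_blob_mask()
  expect_equal(iou(m, m), 1)
  expect_equal(dsc(m, m), 1)

  d1 <- matrix(FALSE, 5, 5); d1[1, 1] <- TRUE
  d2 <- matrix(FALSE, 5, 5); d2[5, 5] <- TRUE
  expect_equal(iou(d1, d2), 0)

  empty <- matrix(FALSE, 5, 5)
  expect_error(iou(empty, empty), "undefined")
  expect_error(dsc(empty, empty), "undefined")
  expect_error(iou(matrix(TRUE, 2, 2), matrix(TRUE, 3, 3)), "shapes differ")
})

test_that("metrics are symmetric, translation-equivariant and tied by the Dice-Jaccard identity", {
  set.seed(42)
  for (i in 1:50) {
    a <- rand_blob_mask(40, 40)
    b <- rand_blob_mask(40, 40)
    i_ab <- iou(a, b); d_ab <- dsc(a, b)
    expect_identical(i_ab, iou(b, a))
    expect_identical(d_ab, dsc(b, a))
    expect_equal(d_ab, 2 * i_ab / (1 + i_ab), tolerance = 1e-15)

    at <- translate_mask(a, 3, -2); bt <- translate_mask(b, 3, -2)
    # translating both masks identically leaves every metric unchanged
    # (blobs sit away from the border, so nothing is clipped)
    expect_equal(iou(at, bt), i_ab)
    expect_equal(hausdorff(extract_contour(at), extract_contour(bt)),
                 hausdorff(extract_contour(a), extract_contour(b)))
  }
})

test_that("contours are the 8-connectivity boundary-pixel sets", {
  single <- matrix(FALSE, 5, 5); single[3, 4] <- TRUE
  expect_equal(extract_contour(single),
               matrix(c(3L, 4L), 1, dimnames = list(NULL, c("row", "col"))))

  block <- matrix(FALSE, 7, 7); block[3:5, 3:5] <- TRUE
  ct <- extract_contour(block)
  expect_equal(nrow(ct), 8L)            # centre pixel is interior
  expect_false(any(ct[, 1L] == 4 & ct[, 2L] == 4))

  # every contour point of a disc is foreground and 8-adjacent to background
  disc <- disc_mask(50, 50, r = 20)
  ct <- extract_contour(disc)
  expect_true(all(disc[ct]))
  padded <- matrix(FALSE, 52, 52); padded[2:51, 2:51] <- disc
  touches_bg <- vapply(seq_len(nrow(ct)), function(i) {
    r <- ct[i, 1L] + 1L; c <- ct[i, 2L] + 1L
    any(!padded[(r - 1):(r + 1), (c - 1):(c + 1)][-5])
  }, logical(1))
  expect_true(all(touches_bg))

  # a mask filling the whole image still has a contour: its border pixels
  full <- matrix(TRUE, 4, 6)
  expect_equal(nrow(extract_contour(full)), 2 * 4 + 2 * 6 - 4)

  expect_error(extract_contour(matrix(FALSE, 3, 3)), "empty")
})

test_that("hausdorff matches hand examples and the exhaustive oracle", {
  expect_equal(hausdorff(rbind(c(1, 1)), rbind(c(4, 5))), 5)  # 3-4-5 triangle
  ct <- extract_contour(disc_mask(30, 30, r = 9))
  expect_equal(hausdorff(ct, ct), 0)

  p <- shifted_blocks()
  expect_equal(hausdorff(extract_contour(p$a), extract_contour(p$b)), 1)

  set.seed(99)
  for (i in 1:20) {
    a <- rand_contour(sample(2:200, 1))
    b <- rand_contour(sample(2:200, 1))
    h <- hausdorff(a, b)
    expect_equal(h, hd_oracle(a, b), tolerance = 1e-12)
    expect_equal(h, hausdorff(b, a))
  }

  expect_error(hausdorff(matrix(numeric(), 0, 2), rbind(c(1, 1))), "empty")
})

test_that("translating a disc degrades agreement monotonically", {
  disc <- disc_mask(60, 60, centre = c(30, 20), r = 12)
  ious <- hds <- numeric(11)
  for (t in 0:10) {
    shifted <- translate_mask(disc, 0, t)
    ious[t + 1] <- iou(disc, shifted)
    hds[t + 1] <- hausdorff(extract_contour(disc), extract_contour(shifted))
  }
  expect_true(all(diff(ious) <= 0))
  expect_true(all(diff(hds) >= 0))
  expect_equal(ious[1], 1)
  expect_equal(hds[1], 0)
})

test_that("agreement bundles the three metrics coherently", {
  p <- shifted_blocks()
  expect_equal(agreement(p$a, p$b), c(iou = 1 / 3, dsc = 0.5, hd = 1))
  m <- rand_blob_mask()
  expect_equal(agreement(m, m), c(iou = 1, dsc = 1, hd = 0))
  set.seed(5)
  for (i in 1:10) {
    rec <- agreement(rand_blob_mask(), rand_blob_mask())
    expect_equal(rec[["dsc"]], 2 * rec[["iou"]] / (1 + rec[["iou"]]),
                 tolerance = 1e-15)
  }
})
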