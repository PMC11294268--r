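#' Intersection over union (Jaccard index) of two masks
#'
#' `IoU = |A intersect B| / |A union B|` by pixel counting. Both masks
#' must have the same shape; comparing two empty masks is an error rather
#' than a conventional value, since the metric is undefined there.
#'
#' @param a,b Logical or 0/1 numeric matrices of identical shape.
#' @return A number in `[0, 1]`.
#' @export
iou <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  inter <- sum(a & b)
  union <- sum(a | b)
  if (union == 0L)
    stop("IoU is undefined for two empty masks")
  inter / union
}

#' Sorensen-Dice similarity coefficient of two masks
#'
#' `DSC = 2 |A intersect B| / (|A| + |B|)`. Algebraically tied to the
#' Jaccard index by `DSC = 2 IoU / (1 + IoU)`; the package's test-suite
#' checks that identity on every computed pair.
#'
#' @inheritParams iou
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L)
    stop("DSC is undefined for two empty masks")
  2 * sum(a & b) / (na + nb)
}

#' Extract the boundary-pixel contour of a mask
#'
#' The contour is the set of foreground pixels that touch the background:
#' pixels that are 1 and have at least one 0 among their 8 neighbours, or
#' lie on the image border. Coordinates are 1-based `(row, col)` pixel
#' centres; all distances derived from them are in pixel units.
#'
#' @param mask Nonempty logical or 0/1 numeric matrix.
#' @return Integer matrix with columns `row`, `col`, one boundary pixel
#'   per row.
#' @export
extract_contour <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("cannot extract the contour of an empty mask")
  nr <- nrow(mask); nc <- ncol(mask)
  # pad with background so border pixels count as boundary
  p <- matrix(FALSE, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- mask
  interior <- mask
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    interior <- interior & p[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  pts <- which(mask & !interior, arr.ind = TRUE)
  colnames(pts) <- c("row", "col")
  pts
}

#' Symmetric Hausdorff distance between two contours
#'
#' The classical (100th-percentile) Hausdorff distance between two point
#' sets: the larger of the two directed distances
#' `max_a min_b ||a - b||`, in Euclidean pixel units. This is the
#' worst-case boundary disagreement -- a single outlying contour point
#' dominates it, which is exactly what makes it informative about margin
#' uncertainty.
#'
#' @param a_c,b_c Contours as returned by [extract_contour()]: two-column
#'   matrices of `(row, col)` coordinates. Must be nonempty.
#' @return Distance in pixels (`>= 0`).
#' @export
hausdorff <- function(a_c, b_c) {
  a_c <- as_contour(a_c); b_c <- as_contour(b_c)
  sqrt(max(directed_hd2(a_c, b_c), directed_hd2(b_c, a_c)))
}

as_contour <- function(x, arg = deparse(substitute(x))) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || ncol(x) != 2L)
    stop(sprintf("'%s' must be a two-column (row, col) matrix", arg))
  if (nrow(x) == 0L)
    stop(sprintf("'%s' is an empty contour", arg))
  storage.mode(x) <- "double"
  x
}

# max over a of the squared distance to the nearest b, computed from the
# expansion ||a-b||^2 = |a|^2 - 2 a.b + |b|^2 in row chunks to bound the
# size of the cross-product matrix.
directed_hd2 <- function(a, b, chunk = 1024L) {
  bb <- rowSums(b * b)
  worst <- 0
  for (start in seq(1L, nrow(a), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(a))
    ach <- a[idx, , drop = FALSE]
    d2 <- rowSums(ach * ach) - 2 * tcrossprod(ach, b) +
      rep(bb, each = length(idx))
    nearest <- d2[cbind(seq_along(idx), max.col(-d2, ties.method = "first"))]
    worst <- max(worst, max(nearest))
  }
  max(worst, 0)  # guard tiny negatives from cancellation
}

#' Full agreement record for a mask pair
#'
#' Bundles the three similarity metrics used throughout the analysis:
#' IoU and DSC on the masks themselves, and the symmetric Hausdorff
#' distance on their boundary-pixel contours.
#'
#' @inheritParams iou
#' @return Named numeric vector `c(iou, dsc, hd)`.
#' @examples
#' a <- matrix(0, 8, 8); a[3:4, 3:4] <- 1
#' b <- matrix(0, 8, 8); b[3:4, 4:5] <- 1
#' agreement(a, b)  # iou 1/3, dsc 1/2, hd 1
#' @export
agreement <- function(a, b) {
  c(iou = iou(a, b), dsc = dsc(a, b),
    hd = hausdorff(extract_contour(a), extract_contour(b)))
}
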