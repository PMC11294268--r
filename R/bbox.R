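#' Axis-aligned bounding box of a mask
#'
#' The box spanned by the extremal row and column coordinates of the
#' mask's foreground pixels, with inclusive 1-based integer bounds --
#' the "fit a box around the outer limits of the segment" construction
#' used to relax segmentations into localisations.
#'
#' @param mask Nonempty logical or 0/1 numeric matrix.
#' @return An object of class `"bbox"`: a list with integer fields
#'   `row_min`, `row_max`, `col_min`, `col_max`.
#' @export
mask_to_bbox <- function(mask) {
  mask <- as_mask(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) == 0L) stop("cannot take the bounding box of an empty mask")
  structure(
    list(row_min = min(pts[, 1L]), row_max = max(pts[, 1L]),
         col_min = min(pts[, 2L]), col_max = max(pts[, 2L])),
    class = "bbox")
}

#' @export
print.bbox <- function(x, ...) {
  cat(sprintf("<bbox> rows %d..%d, cols %d..%d (%d x %d px)\n",
              x$row_min, x$row_max, x$col_min, x$col_max,
              x$row_max - x$row_min + 1L, x$col_max - x$col_min + 1L))
  invisible(x)
}

#' Rasterise a bounding box as a filled mask
#'
#' @param box A `"bbox"` object, see [mask_to_bbox()].
#' @param shape Target image shape `c(rows, cols)`; the box must fit.
#' @return Logical matrix with the box region set to `TRUE`.
#' @export
bbox_to_mask <- function(box, shape) {
  check_bbox(box)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("'shape' must be c(rows, cols)")
  if (box$row_min < 1L || box$col_min < 1L ||
      box$row_max > shape[1L] || box$col_max > shape[2L])
    stop("bounding box exceeds the image shape")
  m <- matrix(FALSE, shape[1L], shape[2L])
  m[box$row_min:box$row_max, box$col_min:box$col_max] <- TRUE
  m
}

check_bbox <- function(box) {
  if (!inherits(box, "bbox")) stop("'box' must be a \"bbox\" object")
  if (box$row_min > box$row_max || box$col_min > box$col_max)
    stop("degenerate bbox: min bound exceeds max bound")
  invisible(TRUE)
}

#' Box-level agreement of two segmentations
#'
#' Converts both masks to their bounding boxes, rasterises the boxes on
#' the shared image shape and evaluates the same three metrics as
#' [agreement()]. The box contour used for the Hausdorff distance is the
#' perimeter pixel set of the rasterised box.
#'
#' @inheritParams iou
#' @return Named numeric vector `c(iou, dsc, hd)`.
#' @export
bbox_agreement <- function(a, b) {
  a <- as_mask(a); b <- as_mask(b)
  check_same_shape(a, b)
  agreement(bbox_to_mask(mask_to_bbox(a), dim(a)),
            bbox_to_mask(mask_to_bbox(b), dim(b)))
}

#' Fraction of a reference segmentation contained in a box
#'
#' `|reference intersect box| / |reference|` -- the quantity behind the
#' study's per-annotator containment percentages, measuring how much of
#' the reference-standard segmentation an annotator's bounding box
#' captures.
#'
#' @param reference Nonempty logical or 0/1 numeric matrix.
#' @param box A `"bbox"` object lying within the reference's shape.
#' @return A number in `[0, 1]`.
#' @export
containment_fraction <- function(reference, box) {
  reference <- as_mask(reference)
  check_bbox(box)
  n_ref <- sum(reference)
  if (n_ref == 0L) stop("'reference' mask is empty")
  if (box$row_min < 1L || box$col_min < 1L ||
      box$row_max > nrow(reference) || box$col_max > ncol(reference))
    stop("bounding box exceeds the reference's shape")
  inside <- sum(reference[box$row_min:box$row_max, box$col_min:box$col_max])
  inside / n_ref
}
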