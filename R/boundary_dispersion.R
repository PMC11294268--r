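# Tumour-border pixel-dispersion substudy: sample the grayscale image in a
# band perpendicular to a segmentation contour, estimate the intensity
# density, and classify its modality. A bimodal band indicates a cleanly
# separated boundary (two tissue populations); a unimodal band indicates an
# indistinct one.

#' Blur configuration for the circle phantom
#'
#' @param kind `"gaussian"` or `"box"`.
#' @param strength Nonnegative scalar: the Gaussian sigma in pixels, or
#'   the box-kernel half-width in pixels. `0` means no smoothing.
#' @param protrusions If `TRUE`, thin radial spurs are added to the shape
#'   before filtering (the defined boundary -- the returned mask -- stays
#'   that of the plain circle).
#' @return An object of class `"blur_config"`.
#' @export
blur_config <- function(kind = c("gaussian", "box"), strength = 0,
                        protrusions = FALSE) {
  kind <- match.arg(kind)
  if (length(strength) != 1L || !is.finite(strength) || strength < 0)
    stop("'strength' must be a single nonnegative number")
  structure(list(kind = kind, strength = strength,
                 protrusions = isTRUE(protrusions)),
            class = "blur_config")
}

#' Blurred-circle calibration phantom
#'
#' Builds the synthetic example used to calibrate the modality
#' classifier: a binary disc of the given contrast, optionally with thin
#' radial protrusions, smoothed by a Gaussian or box filter of increasing
#' strength. The returned mask is always the *unfiltered* disc -- the
#' defined boundary does not move when the image blurs, which is the
#' point of the calibration: with no blur the boundary band is perfectly
#' bimodal, and under severe blur it collapses to unimodal.
#'
#' @param radius Disc radius in pixels.
#' @param image_size `c(rows, cols)`; the disc plus a 10-pixel band
#'   margin must fit.
#' @param inside,outside Disc and background intensities (`[0, 255]`).
#' @param blur A [blur_config()].
#' @return List with elements `image` (numeric matrix, `[0, 255]`) and
#'   `mask` (logical disc).
#' @export
make_blurred_circle <- function(radius, image_size = c(160, 160),
                                inside = 0, outside = 255,
                                blur = blur_config("gaussian", 0)) {
  if (!inherits(blur, "blur_config")) stop("'blur' must be a blur_config()")
  image_size <- as.integer(image_size)
  centre <- (image_size + 1) / 2
  margin <- 10 + 1  # band halfwidth used downstream, plus interpolation slack
  if (radius <= 0) stop("'radius' must be positive")
  if (radius + margin > min(centre - 1, image_size - centre))
    stop("circle of radius ", radius, " plus band margin does not fit in ",
         image_size[1L], "x", image_size[2L])

  rr <- matrix(seq_len(image_size[1L]), image_size[1L], image_size[2L])
  cc <- matrix(seq_len(image_size[2L]), image_size[1L], image_size[2L],
               byrow = TRUE)
  dy <- rr - centre[1L]; dx <- cc - centre[2L]
  rho <- sqrt(dy^2 + dx^2)
  disc <- rho <= radius

  shape <- disc
  if (blur$protrusions) {
    # 4 thin radial spurs (width 3 px, length radius/2) beyond the disc
    theta <- atan2(dy, dx)
    for (ang in c(0, pi / 2, pi, -pi / 2)) {
      d <- abs(atan2(sin(theta - ang), cos(theta - ang)))
      spur <- rho <= radius + radius / 2 & rho * sin(pmin(d, pi / 2)) <= 1.5 &
        d < pi / 2
      shape <- shape | spur
    }
  }
  img <- outside + (inside - outside) * (shape + 0)
  img <- apply_blur(img, blur)
  list(image = img, mask = disc)
}

apply_blur <- function(img, blur) {
  if (blur$strength == 0) return(img)
  if (blur$kind == "gaussian") {
    r <- 2L * as.integer(ceiling(3 * blur$strength)) + 1L
    r <- min(r, 2L * (min(dim(img)) %/% 2L) - 1L)  # brush must fit the image
    EBImage::gblur(img, sigma = blur$strength, radius = r,
                   boundary = "replicate")
  } else {
    k <- as.integer(round(blur$strength))
    if (k == 0L) return(img)
    brush <- matrix(1 / (2 * k + 1)^2, 2L * k + 1L, 2L * k + 1L)
    EBImage::filter2(img, brush, boundary = "replicate")
  }
}

#' Sample image intensities in a perpendicular band around a contour
#'
#' For every contour point, intensities are sampled at unit steps along
#' the local inward and outward normal, up to `halfwidth` pixels on each
#' side plus the contour point itself (so at most `2 * halfwidth + 1`
#' samples per point). Normal directions are taken from the gradient of
#' the signed distance transform of the mask, which is robust on jagged
#' contours; off-lattice positions are read by bilinear interpolation and
#' samples falling outside the image are dropped.
#'
#' @param image Numeric intensity matrix.
#' @param contour Two-column `(row, col)` matrix, e.g. from
#'   [extract_contour()]; must lie inside the image.
#' @param halfwidth Band half-width in pixels (default 10, `>= 1`).
#' @param mask Optional mask bounded by `contour`, used for the normal
#'   directions. If omitted it is reconstructed by filling the contour.
#' @return Numeric vector of intensities, with attribute `per_point`, a
#'   data.frame of retained inward/outward sample counts per contour
#'   point.
#' @export
sample_boundary_band <- function(image, contour, halfwidth = 10, mask = NULL) {
  check_gray_image(image)
  contour <- as_contour(contour)
  if (length(halfwidth) != 1L || !is.finite(halfwidth) || halfwidth < 1)
    stop("'halfwidth' must be a single number >= 1")
  halfwidth <- as.integer(halfwidth)
  nr <- nrow(image); nc <- ncol(image)
  if (min(contour) < 1 || max(contour[, 1L]) > nr || max(contour[, 2L]) > nc)
    stop("contour lies outside the image")

  if (is.null(mask)) {
    raster <- matrix(0L, nr, nc)
    raster[contour] <- 1L
    mask <- EBImage::fillHull(raster) != 0
  } else {
    mask <- as_mask(mask)
    check_same_shape(mask, image)
  }

  normals <- contour_normals(mask, contour)
  steps <- seq.int(-halfwidth, halfwidth)
  n_pts <- nrow(contour)
  # positions: one row per contour point, one column per step along the normal
  Y <- outer(normals[, 1L], steps) + contour[, 1L]
  X <- outer(normals[, 2L], steps) + contour[, 2L]
  vals <- matrix(bilinear_at(image, as.vector(Y), as.vector(X)), n_pts)

  keep <- !is.na(vals)
  structure(vals[keep],
            per_point = data.frame(
              inward  = rowSums(keep[, steps < 0, drop = FALSE]),
              outward = rowSums(keep[, steps > 0, drop = FALSE])))
}

# Outward unit normals at contour points, from central differences of the
# signed distance transform (positive outside the mask). Degenerate points
# (zero gradient) get a zero normal and contribute only their own pixel.
contour_normals <- function(mask, contour) {
  phi <- EBImage::distmap(1 - (mask + 0)) - EBImage::distmap(mask + 0)
  phi[!is.finite(phi)] <- 0  # all-fg / all-bg images have no finite map
  nr <- nrow(phi); nc <- ncol(phi)
  r <- contour[, 1L]; co <- contour[, 2L]
  gy <- (phi[cbind(pmin(r + 1, nr), co)] - phi[cbind(pmax(r - 1, 1), co)]) /
    (pmin(r + 1, nr) - pmax(r - 1, 1))
  gx <- (phi[cbind(r, pmin(co + 1, nc))] - phi[cbind(r, pmax(co - 1, 1))]) /
    (pmin(co + 1, nc) - pmax(co - 1, 1))
  len <- sqrt(gy^2 + gx^2)
  ok <- len > 1e-12
  cbind(ifelse(ok, gy / len, 0), ifelse(ok, gx / len, 0))
}

bilinear_at <- function(image, y, x) {
  nr <- nrow(image); nc <- ncol(image)
  out <- rep(NA_real_, length(y))
  ok <- y >= 1 & y <= nr & x >= 1 & x <= nc
  if (!any(ok)) return(out)
  y <- y[ok]; x <- x[ok]
  y0 <- pmin(floor(y), nr - 1L); x0 <- pmin(floor(x), nc - 1L)
  y0 <- pmax(y0, 1L); x0 <- pmax(x0, 1L)
  fy <- y - y0; fx <- x - x0
  out[ok] <-
    image[cbind(y0,     x0)]     * (1 - fy) * (1 - fx) +
    image[cbind(y0 + 1, x0)]     * fy       * (1 - fx) +
    image[cbind(y0,     x0 + 1)] * (1 - fy) * fx +
    image[cbind(y0 + 1, x0 + 1)] * fy       * fx
  out
}

#' Kernel density estimate of boundary-band intensities
#'
#' Gaussian KDE on a fixed 256-point grid over `[0, 255]`, renormalised
#' by the trapezoid rule so that the gridded density integrates to 1.
#' The bandwidth follows Scott's normal-reference rule (`stats::bw.nrd`),
#' falling back to a pure-SD rule when the sample IQR is zero. Constant
#' samples yield a degenerate spike at the constant, flagged with
#' `degenerate = TRUE` and classified unimodal downstream.
#'
#' @param samples Numeric vector of intensities (at least 2 for a proper
#'   estimate).
#' @param n_grid Number of grid points (default 256).
#' @return Object of class `"intensity_density"`: list with `x`, `y`,
#'   `bw`, `n`, `degenerate`.
#' @export
estimate_density <- function(samples, n_grid = 256L) {
  samples <- as.numeric(samples)
  samples <- samples[is.finite(samples)]
  if (length(samples) < 1L) stop("no finite samples")
  grid <- seq(0, 255, length.out = n_grid)
  spread <- stats::sd(samples)
  if (length(samples) < 2L || spread == 0) {
    y <- rep(0, n_grid)
    y[which.min(abs(grid - samples[1L]))] <- 1
    y <- y / trapezoid(grid, y)
    return(structure(list(x = grid, y = y, bw = NA_real_,
                          n = length(samples), degenerate = TRUE),
                     class = "intensity_density"))
  }
  iqr <- stats::IQR(samples)
  bw <- if (iqr > 0) stats::bw.nrd(samples) else
    1.06 * spread * length(samples)^(-1 / 5)
  d <- stats::density(samples, bw = bw, from = 0, to = 255, n = n_grid)
  y <- d$y / trapezoid(d$x, d$y)
  structure(list(x = d$x, y = y, bw = bw, n = length(samples),
                 degenerate = FALSE),
            class = "intensity_density")
}

trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)

#' @export
print.intensity_density <- function(x, ...) {
  cat(sprintf("<intensity_density> n = %d, bw = %s%s\n", x$n,
              if (is.na(x$bw)) "NA" else formatC(x$bw, digits = 3),
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Classify the modality of an intensity density
#'
#' Counts local maxima whose topographic prominence is at least
#' `prominence_frac` of the global density maximum and maps the count to
#' a class: one peak is `"unimodal"`, two `"bimodal"`, three or more
#' `"other"`. Grid endpoints count as peak candidates, so mass piled at 0
#' or 255 is a mode. The relative threshold makes the classification
#' invariant to affine rescaling of the sampled intensities; without a
#' prominence floor, KDE ripple would inflate peak counts. Degenerate
#' (zero-spread) densities are unimodal by convention.
#'
#' @param density An `"intensity_density"` from [estimate_density()].
#' @param prominence_frac Prominence threshold as a fraction of the
#'   global maximum (default 0.05).
#' @return One of `"unimodal"`, `"bimodal"`, `"other"`.
#' @export
classify_modality <- function(density, prominence_frac = 0.05) {
  if (!inherits(density, "intensity_density"))
    stop("'density' must come from estimate_density()")
  if (density$degenerate) return("unimodal")
  pk <- find_peaks(density$y)
  n <- sum(pk$prominence >= prominence_frac * max(density$y))
  if (n <= 1L) "unimodal" else if (n == 2L) "bimodal" else "other"
}

# Local maxima (plateau-tolerant, endpoints included) with topographic
# prominence: height above the higher of the two saddle minima separating
# the peak from nearer-higher ground on each side.
find_peaks <- function(y) {
  n <- length(y)
  dy_left <- c(Inf, diff(y))
  dy_right <- c(-diff(y), Inf)
  cand <- which(dy_left > 0 & dy_right >= 0)
  if (length(cand) == 0L) return(data.frame(idx = integer(), prominence = numeric()))
  prom <- vapply(cand, function(i) {
    # Base on each side: the saddle minimum between the peak and the nearest
    # strictly higher ground. On a bounded support a side with no higher
    # ground does not constrain the peak (treated as falling off the edge),
    # so a mode sitting at or near an end of the intensity range keeps its
    # full prominence.
    left <- if (i > 1L && any(y[seq_len(i - 1)] > y[i])) {
      j <- max(which(y[seq_len(i - 1)] > y[i]))
      min(y[j:i])
    } else -Inf
    right <- if (i < n && any(y[(i + 1):n] > y[i])) {
      j <- i + min(which(y[(i + 1):n] > y[i]))
      min(y[i:j])
    } else -Inf
    y[i] - max(left, right)
  }, numeric(1))
  data.frame(idx = cand, prominence = prom)
}

#' Run the boundary-dispersion substudy on one image/mask pair
#'
#' Composes the pipeline: contour extraction, perpendicular band
#' sampling, kernel density estimation, modality classification.
#'
#' @param image Numeric intensity matrix (`[0, 255]` scale).
#' @param mask Nonempty segmentation mask inside the image.
#' @param halfwidth Band half-width in pixels (default 10).
#' @param prominence_frac Peak-prominence threshold, see
#'   [classify_modality()].
#' @return Object of class `"boundary_band_profile"`: list with
#'   `samples`, `band_halfwidth`, `density`, `peaks` (intensity locations
#'   of accepted peaks) and `modality`.
#' @examples
#' ph <- make_blurred_circle(30, c(100, 100))
#' dispersion_study(ph$image, ph$mask)$modality  # "bimodal"
#' @export
dispersion_study <- function(image, mask, halfwidth = 10,
                             prominence_frac = 0.05) {
  mask <- as_mask(mask)
  check_gray_image(image)
  check_same_shape(mask, image)
  contour <- extract_contour(mask)
  samples <- sample_boundary_band(image, contour, halfwidth, mask = mask)
  dens <- estimate_density(samples)
  modality <- classify_modality(dens, prominence_frac)
  peaks <- if (dens$degenerate) dens$x[which.max(dens$y)] else {
    pk <- find_peaks(dens$y)
    dens$x[pk$idx[pk$prominence >= prominence_frac * max(dens$y)]]
  }
  structure(list(samples = as.numeric(samples),
                 band_halfwidth = halfwidth,
                 density = dens, peaks = peaks, modality = modality),
            class = "boundary_band_profile")
}

#' @export
print.boundary_band_profile <- function(x, ...) {
  cat(sprintf(
    "<boundary_band_profile> %d samples in a +/-%d px band\n  modality: %s (%d peak%s at %s)\n",
    length(x$samples), x$band_halfwidth, x$modality, length(x$peaks),
    if (length(x$peaks) == 1L) "" else "s",
    paste(round(x$peaks, 1), collapse = ", ")))
  invisible(x)
}

#' @export
plot.boundary_band_profile <- function(x, ...) {
  graphics::hist(x$samples, breaks = 32, freq = FALSE,
                 xlab = "intensity", main = paste("boundary band:", x$modality),
                 col = "grey90", border = "grey60", ...)
  graphics::lines(x$density$x, x$density$y, lwd = 2)
  graphics::abline(v = x$peaks, lty = 2)
  invisible(x)
}
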