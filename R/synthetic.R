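# Synthetic stand-in for the study data: star-convex reference lesions,
# simulated annotators that perturb the reference outline with smooth
# angularly-correlated noise, and an ultrasound-like texture with
# controllable echogenicity contrast, speckle and boundary blur. No patient
# data ships with the package; every pipeline stage is exercised on these.

#' Specification of a synthetic annotation study
#'
#' Collects every knob of the synthetic generator in one validated
#' object. Defaults describe the conditions the package's own analyses
#' use: a 192x192 image (a scaled-down stand-in for a cropped B-mode
#' frame), a mildly irregular star-convex lesion of radius 40 px, three
#' simulated annotators whose outlines deviate from the reference with
#' 3 px radial jitter correlated over ~25 px of arc, and a speckled
#' texture with the lesion hyperechogenic (brighter) relative to
#' background, as tumours typically appear on B-mode.
#'
#' @param image_size `c(rows, cols)` of the generated images.
#' @param centre Lesion centre `c(row, col)`; defaults to the image centre.
#' @param radius Mean lesion radius in pixels.
#' @param ellipticity Axis ratio of the underlying ellipse (1 = circle).
#' @param lobe_amplitude Relative amplitude of the radial lobes that make
#'   the outline irregular (0 = smooth ellipse).
#' @param lobe_frequency Integer number of lobes around the outline.
#' @param n_annotators Number of simulated annotators (K, `>= 2`).
#' @param jitter_sigma Radial boundary-perturbation scale per annotator,
#'   in pixels; 0 reproduces the reference exactly.
#' @param jitter_corr_length Arc-length correlation of the perturbation,
#'   in pixels: larger values give smoother, more systematic deviations.
#' @param jitter_dispersion Log-scale SD of the per-image difficulty
#'   multiplier applied to `jitter_sigma` in [generate_cohort()]
#'   (mean-preserving log-normal). Real cohorts are strongly
#'   heteroscedastic -- most images elicit close agreement while a few
#'   ambiguous ones drive most of the disagreement -- and this spread, not
#'   the per-image jitter itself, is what the bounding-box conversion
#'   compresses. 0 makes every image equally hard.
#' @param inside,outside Mean echogenicity (intensity in `[0, 255]`)
#'   inside and outside the lesion.
#' @param speckle_sigma Log-scale SD of the multiplicative log-normal
#'   speckle (0 = none).
#' @param blur_sigma Gaussian boundary blur in pixels applied to the
#'   texture (0 = sharp).
#' @param seed Master integer seed; everything downstream derives from it.
#' @return Object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(image_size = c(192, 192), centre = NULL,
                           radius = 40, ellipticity = 1.2,
                           lobe_amplitude = 0.12, lobe_frequency = 4,
                           n_annotators = 3,
                           jitter_sigma = 3, jitter_corr_length = 25,
                           jitter_dispersion = 0.8,
                           inside = 160, outside = 70,
                           speckle_sigma = 0.25, blur_sigma = 2,
                           seed = 1L) {
  image_size <- as.integer(image_size)
  if (length(image_size) != 2L || any(image_size < 8L))
    stop("'image_size' must be c(rows, cols), each >= 8")
  if (is.null(centre)) centre <- (image_size + 1) / 2
  if (radius <= 2) stop("'radius' must exceed 2 pixels")
  if (ellipticity <= 0) stop("'ellipticity' must be positive")
  if (lobe_amplitude < 0 || lobe_amplitude >= 1)
    stop("'lobe_amplitude' must be in [0, 1)")
  if (n_annotators < 2L) stop("'n_annotators' must be >= 2 for agreement studies")
  scales <- c(jitter_sigma = jitter_sigma,
              jitter_corr_length = jitter_corr_length,
              jitter_dispersion = jitter_dispersion,
              speckle_sigma = speckle_sigma, blur_sigma = blur_sigma)
  if (any(!is.finite(scales)) || any(scales < 0))
    stop("jitter, speckle and blur scales must be finite and >= 0")
  # worst-case outline (lobes up) plus jitter headroom must stay inside
  reach <- radius * sqrt(max(ellipticity, 1 / ellipticity)) *
    (1 + lobe_amplitude) + 4 * jitter_sigma
  room <- min(centre - 1, image_size - centre)
  if (reach > room)
    stop("lesion outline (reach ", round(reach, 1),
         " px) does not fit the image with margin (", round(room, 1), " px)")
  structure(list(image_size = image_size, centre = centre, radius = radius,
                 ellipticity = ellipticity, lobe_amplitude = lobe_amplitude,
                 lobe_frequency = as.integer(lobe_frequency),
                 n_annotators = as.integer(n_annotators),
                 jitter_sigma = jitter_sigma,
                 jitter_corr_length = jitter_corr_length,
                 jitter_dispersion = jitter_dispersion,
                 inside = inside, outside = outside,
                 speckle_sigma = speckle_sigma, blur_sigma = blur_sigma,
                 seed = check_seed(seed)),
            class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(paste0(
    "<synthetic_spec> %dx%d image, lesion r = %g px (ellipticity %g, ",
    "%d lobes x %g)\n  K = %d annotators, jitter %g px (corr %g px), ",
    "contrast %g/%g, speckle %g, blur %g, seed %d\n"),
    x$image_size[1L], x$image_size[2L], x$radius, x$ellipticity,
    x$lobe_frequency, x$lobe_amplitude, x$n_annotators, x$jitter_sigma,
    x$jitter_corr_length, x$inside, x$outside, x$speckle_sigma,
    x$blur_sigma, x$seed))
  invisible(x)
}

# number of points on the angular grid used for outlines
N_THETA <- 720L

#' Generate a star-convex reference lesion mask
#'
#' The outline is a radial function of angle,
#' `r(theta) = r_ellipse(theta) * (1 + a * cos(k * theta + phase))`,
#' rasterised by marking every pixel whose polar radius about the centre
#' is within the outline. The lobe phase is drawn from `seed`, so each
#' seed gives a different lesion of the same character. The returned mask
#' carries the centre and the radial outline as attributes, which
#' [simulate_annotator()] perturbs.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed for the lobe phase; defaults to `spec$seed`.
#' @return Logical mask with attributes `centre`, `theta`, `radii`.
#' @export
make_reference_lesion <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed <- check_seed(seed)
  set.seed(seed)
  theta <- seq(-pi, pi, length.out = N_THETA + 1L)[-(N_THETA + 1L)]
  a <- spec$radius * sqrt(spec$ellipticity)
  b <- spec$radius / sqrt(spec$ellipticity)
  r_ell <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  phase <- stats::runif(1, 0, 2 * pi)
  radii <- r_ell * (1 + spec$lobe_amplitude *
                      cos(spec$lobe_frequency * theta + phase))
  rasterize_outline(spec$centre, theta, radii, spec$image_size)
}

rasterize_outline <- function(centre, theta, radii, image_size) {
  room <- min(centre - 1, image_size - centre)
  if (max(radii) > room)
    stop("outline exits the image (max radius ", round(max(radii), 1),
         " px, room ", round(room, 1), " px)")
  nr <- image_size[1L]; nc <- image_size[2L]
  dy <- matrix(seq_len(nr) - centre[1L], nr, nc)
  dx <- matrix(seq_len(nc) - centre[2L], nr, nc, byrow = TRUE)
  ang <- atan2(dy, dx)
  rho <- sqrt(dy^2 + dx^2)
  # periodic linear interpolation of the outline at each pixel's angle
  r_at <- stats::approx(x = c(theta, theta[1L] + 2 * pi),
                        y = c(radii, radii[1L]),
                        xout = as.vector(ang), rule = 2)$y
  mask <- rho <= matrix(r_at, nr, nc)
  structure(mask, centre = centre, theta = theta, radii = radii)
}

#' Simulate one annotator's segmentation of a reference lesion
#'
#' Models interobserver boundary disagreement by perturbing the
#' reference's radial outline with smooth, angularly correlated Gaussian
#' noise: white noise on the angular grid is circularly smoothed with a
#' Gaussian kernel whose angular width corresponds to
#' `jitter_corr_length` pixels of arc at the mean radius, then rescaled
#' to standard deviation `jitter_sigma` pixels and added to the radii.
#' `jitter_sigma = 0` returns the reference unchanged.
#'
#' @param reference A mask from [make_reference_lesion()] (or any
#'   star-convex mask; centre and outline are then estimated by ray
#'   casting from the centroid).
#' @param jitter_sigma Radial perturbation SD in pixels.
#' @param jitter_corr_length Arc-length correlation in pixels.
#' @param seed Integer seed.
#' @return A logical mask with the same attribute structure as the
#'   reference.
#' @export
simulate_annotator <- function(reference, jitter_sigma, jitter_corr_length,
                               seed) {
  seed <- check_seed(seed)
  if (jitter_sigma < 0 || jitter_corr_length < 0)
    stop("jitter scales must be >= 0")
  out <- outline_of(reference)
  if (jitter_sigma == 0) return(reference)
  set.seed(seed)
  z <- stats::rnorm(length(out$theta))
  sigma_ang <- jitter_corr_length / mean(out$radii)
  dtheta <- 2 * pi / length(out$theta)
  half <- min(length(out$theta) %/% 2L - 1L,
              max(1L, ceiling(4 * sigma_ang / dtheta)))
  w <- stats::dnorm(seq.int(-half, half) * dtheta, sd = max(sigma_ang, dtheta))
  zs <- as.numeric(stats::filter(z, w / sum(w), method = "convolution",
                                 sides = 2, circular = TRUE))
  zs <- zs - mean(zs)  # centred: jitter perturbs shape, not overall size
  s <- stats::sd(zs)
  if (s == 0) stop("degenerate jitter: smoothed noise has zero spread")
  radii <- out$radii + zs / s * jitter_sigma
  if (any(radii < 1))
    stop("degenerate simulation: perturbed outline collapsed (radius < 1 px)")
  rasterize_outline(out$centre, out$theta, radii, dim(reference))
}

# Recover centre/outline from a reference mask: from attributes when
# present, otherwise by ray casting from the centroid.
outline_of <- function(reference) {
  centre <- attr(reference, "centre")
  theta <- attr(reference, "theta")
  radii <- attr(reference, "radii")
  if (!is.null(centre) && !is.null(theta) && !is.null(radii))
    return(list(centre = centre, theta = theta, radii = radii))
  mask <- as_mask(reference)
  if (!any(mask)) stop("'reference' mask is empty")
  pts <- which(mask, arr.ind = TRUE)
  centre <- colMeans(pts)
  theta <- seq(-pi, pi, length.out = N_THETA + 1L)[-(N_THETA + 1L)]
  rmax <- min(centre - 1, dim(mask) - centre)
  steps <- seq(0, rmax, by = 0.5)
  radii <- vapply(theta, function(th) {
    y <- round(centre[1L] + steps * sin(th))
    x <- round(centre[2L] + steps * cos(th))
    inside <- mask[cbind(y, x)]
    if (!inside[1L]) return(1)
    off <- which(!inside)
    if (length(off) == 0L) steps[length(steps)] else steps[max(1L, off[1L] - 1L)]
  }, numeric(1))
  list(centre = centre, theta = theta, radii = radii)
}

#' Render an ultrasound-like texture for a lesion mask
#'
#' Inside/outside mean echogenicity, multiplicative log-normal speckle
#' (unit mean), then Gaussian boundary blur; intensities are clamped to
#' `[0, 255]`. With zero speckle and zero blur the image is two-valued;
#' with large blur relative to the lesion radius the boundary band
#' becomes indistinct, emulating the fuzzy-border images that drive
#' segmentation disagreement.
#'
#' @param reference Lesion mask.
#' @param spec A [synthetic_spec()] (supplies contrast, speckle, blur).
#' @param seed Integer seed for the speckle; defaults to `spec$seed`.
#' @return Numeric intensity matrix on the `[0, 255]` scale.
#' @export
render_us_texture <- function(reference, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  mask <- as_mask(reference)
  seed <- check_seed(seed)
  img <- spec$outside + (spec$inside - spec$outside) * (mask + 0)
  if (spec$speckle_sigma > 0) {
    set.seed(seed)
    s <- spec$speckle_sigma
    img <- img * exp(stats::rnorm(length(img), -s^2 / 2, s))
    dim(img) <- dim(mask)
  }
  img <- apply_blur(img, blur_config("gaussian", spec$blur_sigma))
  pmin(pmax(img, 0), 255)
}

#' Generate a reproducible synthetic annotation cohort
#'
#' Emulates the study design -- a set of images, one reference lesion
#' each, K annotator segmentations per image -- entirely synthetically.
#' Per-image and per-annotator seeds are derived from the master seed, so
#' a cohort is bit-reproducible from `spec` alone.
#'
#' @param spec A [synthetic_spec()].
#' @param n_images Number of images in the cohort (default 30, the size
#'   of the study the package reanalyses).
#' @return Object of class `"synthetic_cohort"`: a list of `n_images`
#'   elements, each a list with `image`, `reference` and `annotators`
#'   (list of K masks), plus the spec as attribute.
#' @export
generate_cohort <- function(spec, n_images = 30L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_images < 1L) stop("'n_images' must be >= 1")
  set.seed(spec$seed)
  seed_tab <- matrix(sample.int(.Machine$integer.max - 1L,
                                n_images * (spec$n_annotators + 2L)),
                     nrow = n_images)
  # per-image difficulty: mean-preserving log-normal multiplier on the
  # jitter scale (see synthetic_spec); a few ambiguous images dominate the
  # disagreement, as in real cohorts
  mult <- exp(stats::rnorm(n_images, -spec$jitter_dispersion^2 / 2,
                           spec$jitter_dispersion))
  cohort <- lapply(seq_len(n_images), function(i) {
    ref <- make_reference_lesion(spec, seed = seed_tab[i, 1L])
    radii <- attr(ref, "radii")
    room <- min(spec$centre - 1, spec$image_size - spec$centre)
    # cap so 3.5-sigma excursions cannot collapse the outline nor exit the
    # image
    sigma_cap <- max(0, min((min(radii) - 2) / 3.5, (room - max(radii)) / 3.5))
    sigma_i <- min(spec$jitter_sigma * mult[i], sigma_cap)
    anns <- lapply(seq_len(spec$n_annotators), function(k)
      simulate_annotator(ref, sigma_i, spec$jitter_corr_length,
                         seed = seed_tab[i, 2L + k]))
    names(anns) <- paste0("An", seq_len(spec$n_annotators))
    list(image = render_us_texture(ref, spec, seed = seed_tab[i, 2L]),
         reference = ref, annotators = anns)
  })
  structure(cohort, spec = spec, class = c("synthetic_cohort", "list"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("<synthetic_cohort> %d images x %d annotators (jitter %g px, seed %d)\n",
              length(x), spec$n_annotators, spec$jitter_sigma, spec$seed))
  invisible(x)
}
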