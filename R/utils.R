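# internal validation helpers shared across modules

# Coerce a mask argument to a logical matrix. Accepts logical or numeric
# matrices; any nonzero value counts as foreground.
as_mask <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x))
    stop(sprintf("'%s' must be a 2D matrix, got %s", arg, class(x)[1L]))
  if (any(dim(x) < 1L))
    stop(sprintf("'%s' must be at least 1x1", arg))
  if (is.logical(x)) {
    if (anyNA(x)) stop(sprintf("'%s' contains NA", arg))
    return(x)
  }
  if (!is.numeric(x))
    stop(sprintf("'%s' must be logical or numeric", arg))
  if (anyNA(x) || any(!is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", arg))
  m <- x != 0
  for (a in c("centre", "theta", "radii"))  # outline metadata, if any
    attr(m, a) <- attr(x, a)
  m
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop(sprintf("mask shapes differ: %s vs %s",
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

check_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("'%s' must be a numeric matrix", arg))
  if (any(!is.finite(image)))
    stop(sprintf("'%s' contains non-finite intensities", arg))
  invisible(TRUE)
}

# single integer seed check (R RNG seeds are 32-bit)
check_seed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    stop("'seed' must be a single integer")
  as.integer(seed)
}
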