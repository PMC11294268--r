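# In-code fixtures: every mask and image used by the tests is generated here.

disc_mask <- function(nr, nc, centre = c((nr + 1) / 2, (nc + 1) / 2), r = 10) {
  dy <- matrix(seq_len(nr) - centre[1L], nr, nc)
  dx <- matrix(seq_len(nc) - centre[2L], nr, nc, byrow = TRUE)
  sqrt(dy^2 + dx^2) <= r
}

# union of a few random discs, nonempty and >= 6 px clear of the border so
# that small translations never clip foreground
rand_blob_mask <- function(nr = 48, nc = 48, n_discs = 3, r_range = c(3, 8)) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_discs)) {
    r <- runif(1, r_range[1L], r_range[2L])
    cy <- runif(1, r + 7, nr - r - 6)
    cx <- runif(1, r + 7, nc - r - 6)
    m <- m | disc_mask(nr, nc, c(cy, cx), r)
  }
  m
}

# sparse Bernoulli mask, guaranteed nonempty
rand_sparse_mask <- function(nr = 32, nc = 32, p = 0.1) {
  m <- matrix(runif(nr * nc) < p, nr, nc)
  if (!any(m)) m[sample(nr, 1), sample(nc, 1)] <- TRUE
  m
}

translate_mask <- function(mask, dr, dc) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  src <- which(mask, arr.ind = TRUE)
  dst <- cbind(src[, 1L] + dr, src[, 2L] + dc)
  keep <- dst[, 1L] >= 1 & dst[, 1L] <= nr & dst[, 2L] >= 1 & dst[, 2L] <= nc
  out[dst[keep, , drop = FALSE]] <- TRUE
  out
}

# Exhaustive double-loop Hausdorff oracle: for every point of one set, the
# distance to every point of the other, min then max; symmetrised.
hd_oracle <- function(a, b) {
  directed <- function(p, q) {
    max(vapply(seq_len(nrow(p)), function(i)
      min(sqrt((p[i, 1L] - q[, 1L])^2 + (p[i, 2L] - q[, 2L])^2)),
      numeric(1)))
  }
  max(directed(a, b), directed(b, a))
}

rand_contour <- function(n_pts, nr = 400, nc = 400) {
  cbind(row = sample.int(nr, n_pts, replace = TRUE),
        col = sample.int(nc, n_pts, replace = TRUE))
}
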