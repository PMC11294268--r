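#' Read a binary segmentation mask
#'
#' Reads a 2D binary lesion mask from disk. Two on-disk formats are
#' supported: NRRD as exported by 3D Slicer for 2D segmentations (a plain
#' 2D array, or a 3D array with singleton axes which is squeezed), and
#' 8-bit PNG. Any nonzero on-disk label value is mapped to foreground, so
#' label maps using e.g. label 2 for the lesion load identically to 0/1
#' masks.
#'
#' @param path Path to the mask file.
#' @param format One of `"auto"` (default; decided by file extension),
#'   `"nrrd"` or `"png"`.
#' @return A logical matrix (rows x cols); `TRUE` is lesion.
#' @seealso [write_mask()], [read_gray_image()]
#' @export
read_mask <- function(path, format = c("auto", "nrrd", "png")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- guess_format(path)
  pix <- switch(format,
    nrrd = read_nrrd(path),
    png  = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3L) a <- a[, , 1L]
      a
    }
  )
  if (!is.matrix(pix)) stop("mask in ", path, " is not 2D")
  pix != 0
}

#' Write a binary segmentation mask
#'
#' Inverse of [read_mask()]: round-tripping a mask through
#' `write_mask()` / `read_mask()` reproduces it exactly, for both formats.
#'
#' @param mask Logical or 0/1 numeric matrix.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"nrrd"` or `"png"`.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path, format = c("auto", "nrrd", "png")) {
  format <- match.arg(format)
  mask <- as_mask(mask)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nrrd = write_nrrd(mask + 0L, path),
    png  = png::writePNG(mask + 0, path)
  )
  invisible(path)
}

#' Read a grayscale ultrasound image
#'
#' Loads an 8-bit grayscale image (PNG) as an intensity matrix on the
#' `[0, 255]` scale used throughout the boundary-dispersion substudy.
#' Multi-channel PNGs are converted by averaging the colour channels
#' (alpha, if present, is ignored).
#'
#' @param path Path to a PNG file.
#' @return Numeric matrix of intensities in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    nch <- min(dim(a)[3L], 3L)  # drop alpha
    a <- apply(a[, , seq_len(nch), drop = FALSE], c(1L, 2L), mean)
  }
  a * 255
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param image Numeric intensity matrix on the `[0, 255]` scale; values
#'   are clamped to that range before quantisation.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gray_image <- function(image, path) {
  check_gray_image(image)
  png::writePNG(pmin(pmax(image, 0), 255) / 255, path)
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("nrrd", "nhdr")) return("nrrd")
  if (ext == "png") return("png")
  stop("cannot guess mask format from extension '", ext,
       "'; pass format = \"nrrd\" or \"png\"")
}

# ---- minimal NRRD dialect -------------------------------------------------
#
# Reads the subset of NRRD produced by 3D Slicer segmentation exports for
# single-slice data: integer or float types, raw / gzip / ascii encodings,
# little or big endian, any number of singleton axes around the two image
# axes. Orientation metadata is ignored: this package works in raw pixel
# space. No installed R package parses NRRD, hence the hand-written reader.

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD000", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated NRRD header in ", path)
    if (line == "") break
    if (grepl("^#", line)) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1L]]
    if (length(m) != 3L) next  # key/value pairs only; skip 'key:=value' etc.
    fields[[tolower(trimws(m[2L]))]] <- trimws(m[3L])
  }
  for (req in c("type", "dimension", "sizes", "encoding"))
    if (is.null(fields[[req]])) stop("NRRD header missing '", req, "' in ", path)

  sizes <- as.integer(strsplit(fields$sizes, "[ \t]+")[[1L]])
  if (length(sizes) != as.integer(fields$dimension))
    stop("NRRD sizes/dimension mismatch in ", path)
  n <- prod(sizes)
  type <- nrrd_type(fields$type)
  endian <- if (identical(fields$endian, "big")) "big" else "little"

  enc <- fields$encoding
  if (enc %in% c("raw", "gzip", "gz")) {
    payload <- readBin(con, "raw", n = file.size(path))
    if (enc != "raw") payload <- memDecompress(payload, type = "gzip")
    vals <- readBin(payload, what = type$what, n = n, size = type$size,
                    signed = type$signed, endian = endian)
  } else if (enc %in% c("ascii", "text", "txt")) {
    txt <- rawToChar(readBin(con, "raw", n = file.size(path)))
    vals <- as.numeric(strsplit(trimws(txt), "[ \t\r\n]+")[[1L]])
  } else {
    stop("unsupported NRRD encoding '", enc, "' in ", path)
  }
  if (length(vals) < n) stop("NRRD payload shorter than sizes imply in ", path)
  vals <- vals[seq_len(n)]

  keep <- sizes > 1L
  if (sum(keep) > 2L)
    stop("NRRD in ", path, " has ", sum(keep),
         " non-singleton axes; this package is 2D-only")
  dims <- sizes[keep]
  if (length(dims) == 0L) dims <- c(1L, 1L)
  if (length(dims) == 1L) dims <- c(dims, 1L)
  # NRRD orders the fastest axis first (x = columns); R matrices are
  # column-major with rows fastest, so fill by row.
  matrix(vals, nrow = dims[2L], ncol = dims[1L], byrow = TRUE)
}

nrrd_type <- function(type) {
  t <- gsub("_t$", "", tolower(trimws(type)))
  tab <- list(
    "unsigned char"  = list(what = "integer", size = 1L, signed = FALSE),
    "uchar"          = list(what = "integer", size = 1L, signed = FALSE),
    "uint8"          = list(what = "integer", size = 1L, signed = FALSE),
    "signed char"    = list(what = "integer", size = 1L, signed = TRUE),
    "char"           = list(what = "integer", size = 1L, signed = TRUE),
    "int8"           = list(what = "integer", size = 1L, signed = TRUE),
    "short"          = list(what = "integer", size = 2L, signed = TRUE),
    "int16"          = list(what = "integer", size = 2L, signed = TRUE),
    "unsigned short" = list(what = "integer", size = 2L, signed = FALSE),
    "uint16"         = list(what = "integer", size = 2L, signed = FALSE),
    "int"            = list(what = "integer", size = 4L, signed = TRUE),
    "int32"          = list(what = "integer", size = 4L, signed = TRUE),
    "float"          = list(what = "double",  size = 4L, signed = TRUE),
    "double"         = list(what = "double",  size = 8L, signed = TRUE)
  )
  out <- tab[[t]]
  if (is.null(out)) stop("unsupported NRRD type '", type, "'")
  out
}

write_nrrd <- function(pixels, path, type = "unsigned char") {
  stopifnot(is.matrix(pixels))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c(
    "NRRD0004",
    paste0("type: ", type),
    "dimension: 2",
    paste("sizes:", ncol(pixels), nrow(pixels)),
    "encoding: raw",
    "endian: little"
  )
  # blank line separates header from payload
  writeChar(paste0(paste(header, collapse = "\n"), "\n\n"), con, eos = NULL)
  # x (columns) fastest, matching the sizes line
  writeBin(as.integer(t(pixels)), con, size = 1L, endian = "little")
  invisible(path)
}

# ---- packaged agreement table ---------------------------------------------

#' Load the packaged per-image agreement table
#'
#' The package ships, as a CSV fixture, the per-image agreement values of a
#' published interobserver study of intraoperative ultrasound brain-tumour
#' segmentation: 30 images, three annotators (`An1`-`An3`) each compared
#' against a neuroradiologist's reference standard, in two variants --
#' the raw segmentations (`Seg`) and their axis-aligned bounding boxes
#' (`BBox`) -- with IoU, DSC and Hausdorff distance (pixels) per row.
#' All aggregation utilities ([reproduce_tables()], [iqr_reduction()],
#' [cross_annotator_mean()]) operate on this table.
#'
#' On load the table is integrity-checked: 180 rows, each
#' annotator-variant cell covering images 1-30 exactly once, metric
#' ranges, and row-wise consistency of DSC with IoU through the identity
#' `dsc = 2 iou / (1 + iou)`. The identity tolerance defaults to 0.0016,
#' the worst-case bound for values independently rounded to 3 decimals
#' (the derivative of the identity approaches 2 as IoU approaches 0, so
#' printed rounding can displace the pair by slightly more than 0.001).
#'
#' @param path Path to the CSV; defaults to the packaged fixture.
#' @param identity_tol Tolerance for the row-wise Dice-Jaccard
#'   consistency check.
#' @return A `data.frame` with columns `image_id`, `annotator`,
#'   `variant`, `iou`, `dsc`, `hd`.
#' @export
load_agreement_fixture <- function(path = NULL, identity_tol = 0.0016) {
  if (is.null(path))
    path <- system.file("extdata", "agreement_tables.csv", package = "segvar",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "annotator", "variant", "iou", "dsc", "hd")
  if (!all(need %in% names(tab)))
    stop("fixture is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab <- tab[need]

  problems <- character()
  if (nrow(tab) != 180L)
    problems <- c(problems, sprintf("expected 180 rows, found %d", nrow(tab)))
  for (ann in c("An1", "An2", "An3")) for (var in c("Seg", "BBox")) {
    ids <- sort(tab$image_id[tab$annotator == ann & tab$variant == var])
    if (!identical(ids, 1:30))
      problems <- c(problems, sprintf("%s/%s does not cover images 1..30", ann, var))
  }
  bad_range <- which(tab$iou < 0 | tab$iou > 1 | tab$dsc < 0 | tab$dsc > 1 |
                     tab$hd < 0 | tab$iou > tab$dsc)
  if (length(bad_range))
    problems <- c(problems, paste("metric range violated in rows:",
                                  paste(bad_range, collapse = ", ")))
  resid <- abs(tab$dsc - 2 * tab$iou / (1 + tab$iou))
  bad_id <- which(resid > identity_tol)
  if (length(bad_id))
    problems <- c(problems,
      paste("Dice-Jaccard identity violated beyond", identity_tol, "in rows:",
            paste(sprintf("%d (image %d %s %s, residual %.4f)", bad_id,
                          tab$image_id[bad_id], tab$annotator[bad_id],
                          tab$variant[bad_id], resid[bad_id]), collapse = "; ")))
  if (length(problems))
    stop("agreement fixture failed integrity checks:\n  ",
         paste(problems, collapse = "\n  "))
  tab
}
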