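#' Binary and grayscale image containers
#'
#' A `binary_image` is an integer/logical matrix with the package-wide
#' convention solid = 1, pore = 0, carrying its physical resolution in
#' µm/pixel.  A `gray_image` holds intensities in `[0, 1]` (solid phase
#' bright, as fibers appear in SEM).
#'
#' @param m matrix of 0/1 (binary) or `[0,1]` intensities (gray).
#' @param resolution_um_per_px physical pixel size, µm (> 0).
#' @return the matrix with class and `resolution_um_per_px` attribute.
#' @export
binary_image <- function(m, resolution_um_per_px = 1) {
  if (!is.matrix(m) || length(m) == 0) stop("image must be a non-empty matrix")
  check_num(resolution_um_per_px, "resolution_um_per_px", lower = 1e-12)
  v <- as.integer(m != 0)
  out <- matrix(v, nrow(m), ncol(m))
  attr(out, "resolution_um_per_px") <- resolution_um_per_px
  class(out) <- c("binary_image", "matrix", "array")
  out
}

#' @rdname binary_image
#' @export
gray_image <- function(m, resolution_um_per_px = 1) {
  if (!is.matrix(m) || length(m) == 0) stop("image must be a non-empty matrix")
  check_num(resolution_um_per_px, "resolution_um_per_px", lower = 1e-12)
  if (anyNA(m) || min(m) < 0 || max(m) > 1)
    stop("gray image intensities must lie in [0, 1]")
  out <- matrix(as.double(m), nrow(m), ncol(m))
  attr(out, "resolution_um_per_px") <- resolution_um_per_px
  class(out) <- c("gray_image", "matrix", "array")
  out
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("<binary_image> %d x %d px @ %g um/px, solid fraction %.3f\n",
              nrow(x), ncol(x), img_res(x), mean(x == 1)))
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px @ %g um/px, intensity [%.3f, %.3f]\n",
              nrow(x), ncol(x), img_res(x), min(x), max(x)))
  invisible(x)
}

img_res <- function(img) {
  r <- attr(img, "resolution_um_per_px")
  if (is.null(r)) 1 else r
}

is_binary <- function(img) inherits(img, "binary_image") ||
  (is.matrix(img) && all(img %in% c(0L, 1L, TRUE, FALSE)))

#' Read and write images
#'
#' Images are exchanged as single-channel PNG (via the `png` package) or as
#' plain-text ASCII PGM (P2), which needs no binary dependency and is the
#' fixture format used in the test-suite.  Binary images are stored with
#' solid = max gray.
#'
#' @param img a `binary_image` or `gray_image`.
#' @param path file path; format chosen by extension (`.png` or `.pgm`).
#' @param resolution_um_per_px resolution to attach on read.
#' @return `write_image()` returns `path` invisibly; `read_image()` returns a
#'   `gray_image` (rescale/binarize downstream as needed).
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  m <- unclass(img)
  attr(m, "resolution_um_per_px") <- NULL
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to write PNG")
    png::writePNG(t(m) * 1.0, path)  # writePNG expects rows = image rows
  } else if (ext == "pgm") {
    maxv <- 255L
    q <- round(m * maxv)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), as.character(maxv)), con)
    # PGM is row-major top-to-bottom; our rows are the first index
    apply(q, 1, function(r) writeLines(paste(r, collapse = " "), con))
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path, resolution_um_per_px = 1) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("the png package is required to read PNG")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) a <- a[, , 1]
    m <- t(a)
  } else if (ext == "pgm") {
    txt <- readLines(path)
    txt <- txt[!grepl("^#", txt)]
    if (txt[1] != "P2") stop("only ASCII PGM (P2) supported")
    vals <- scan(text = paste(txt[-1], collapse = " "), quiet = TRUE)
    w <- vals[1]; h <- vals[2]; maxv <- vals[3]
    m <- matrix(vals[-(1:3)] / maxv, nrow = h, ncol = w, byrow = TRUE)
  } else stop("unsupported image format: ", ext)
  gray_image(m, resolution_um_per_px)
}
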