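#' Otsu global threshold
#'
#' Maximizes the between-class variance of a 256-bin intensity histogram;
#' the returned threshold lies strictly between the two classes (pixels
#' `> threshold` are foreground).
#'
#' @param gray numeric matrix/vector of intensities in `[0, 1]`.
#' @param nbins histogram bins.
#' @return scalar threshold in `(0, 1)`.
#' @export
otsu_threshold <- function(gray, nbins = 256L) {
  x <- as.numeric(gray)
  if (anyNA(x)) stop("NA intensities")
  if (max(x) - min(x) < 1e-12)
    stop("constant image: Otsu threshold does not exist", call. = FALSE)
  brk <- seq(0, 1, length.out = nbins + 1)
  h <- tabulate(pmin(pmax(findInterval(x, brk, rightmost.closed = TRUE), 1L),
                     nbins), nbins)
  w <- h / sum(h)
  mids <- (brk[-1] + brk[-(nbins + 1)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[nbins]
  sb <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sb[!is.finite(sb)] <- -Inf
  k <- which.max(sb)
  brk[k + 1]
}

#' Segmentation configuration
#'
#' @param method `"global-otsu"` (default; between-class-variance threshold)
#'   or `"fixed-threshold"`.
#' @param threshold required for fixed mode, in `(0, 1)`.
#' @param despeckle_min_px components of either phase smaller than this are
#'   merged into the surrounding phase (default 4 px, suppressing
#'   salt-and-pepper noise).
#' @param invert set `TRUE` if the solid phase is dark in the input; output
#'   always uses solid = 1.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(method = c("global-otsu", "fixed-threshold"),
                                threshold = NULL, despeckle_min_px = 4L,
                                invert = FALSE) {
  method <- match.arg(method)
  if (method == "fixed-threshold") {
    if (is.null(threshold)) stop_field("threshold", "required for fixed-threshold")
    check_num(threshold, "threshold", lower = 1e-12, upper = 1 - 1e-12)
  }
  check_num(despeckle_min_px, "despeckle_min_px", lower = 0, integer = TRUE)
  structure(list(method = method, threshold = threshold,
                 despeckle_min_px = as.integer(despeckle_min_px),
                 invert = isTRUE(invert)),
            class = "segmentation_config")
}

despeckle <- function(solid, min_px) {
  if (min_px <= 0) return(solid)
  flip_small <- function(mask, conn) {
    lab <- cpp_label(mask, conn)
    if (max(lab) == 0) return(mask)
    small <- which(tabulate(lab[lab > 0]) < min_px)
    if (length(small)) mask[lab %in% small] <- FALSE
    mask
  }
  # small solid specks become pore (solid 4-connected), then small pore
  # specks become solid (pore 8-connected)
  solid <- flip_small(solid, 4L)
  pore <- flip_small(!solid, 8L)
  !pore
}

#' Segment a grayscale image into a binary image
#'
#' Global thresholding (Otsu by default) followed by small-component
#' despeckling; the output uses the package convention solid = 1 (bright
#' phase, unless `invert`).  Binarizing an already binary image with
#' despeckle 0 is the identity, and the operation is idempotent for a fixed
#' configuration.
#'
#' @param gray a `gray_image` (a `binary_image` is passed through threshold
#'   0.5).
#' @param cfg a [segmentation_config()].
#' @return a `binary_image`.
#' @export
binarize <- function(gray, cfg = segmentation_config()) {
  res <- img_res(gray)
  m <- matrix(as.numeric(gray), nrow(gray), ncol(gray))
  if (min(m) < 0 || max(m) > 1) stop("intensities must lie in [0, 1]")
  thr <- if (cfg$method == "fixed-threshold") cfg$threshold
         else if (all(m %in% c(0, 1))) 0.5
         else otsu_threshold(m)
  solid <- m > thr
  if (cfg$invert) solid <- !solid
  solid <- despeckle(solid, cfg$despeckle_min_px)
  binary_image(solid * 1L, res)
}

#' Full image-analysis pathway: micrograph to structure metrics
#'
#' Segments a grayscale image (or accepts a binary one), then measures
#' surface porosity, pore areas and fiber widths.  A stabilization report —
#' running means of pore area and fiber width over increasing sample
#' fractions — accompanies the statistics so the user can check that the
#' averages have stabilized at the image size analysed.
#'
#' @param img a `gray_image` or `binary_image`.
#' @param resolution_um_per_px overrides the image's resolution if given.
#' @param cfg a [segmentation_config()].
#' @param checkpoints number of stabilization checkpoints.
#' @return an `image_analysis` list: `metrics` (a `structure_metrics`),
#'   `binary`, `config`, and `stabilization` (data.frame of running means).
#' @export
analyze_image <- function(img, resolution_um_per_px = NULL,
                          cfg = segmentation_config(), checkpoints = 10L) {
  if (!is.null(resolution_um_per_px))
    attr(img, "resolution_um_per_px") <- resolution_um_per_px
  bin <- if (is_binary(img)) binary_image(unclass(img) * 1L, img_res(img))
         else binarize(img, cfg)
  met <- structure_metrics(bin)
  running <- function(x) {
    if (is.null(x) || length(x) == 0) return(rep(NA_real_, checkpoints))
    mns <- cumsum(x) / seq_along(x)
    mns[pmax(1L, round(seq_len(checkpoints) / checkpoints * length(x)))]
  }
  stab <- data.frame(fraction = seq_len(checkpoints) / checkpoints,
                     mean_pore_area_um2 = running(met$pore_areas_um2),
                     mean_fiber_width_um = running(met$fiber_widths_um))
  out <- list(metrics = met, binary = bin, config = cfg, stabilization = stab)
  class(out) <- "image_analysis"
  out
}

#' @export
print.image_analysis <- function(x, ...) {
  cat("<image_analysis>\n")
  print(x$metrics)
  invisible(x)
}
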