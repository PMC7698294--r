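#' Specify a fiber population
#'
#' Describes the morphology distribution of a fiber furnish: the width range
#' and sampling law, the length/width aspect ratio, wall thickness, lumen and
#' an integer flexibility.  Widths of micro/nanofibrillated cellulose span
#' roughly 0.07–10 µm; the default law is log-uniform over the supplied range
#' (only a range is known for such furnishes, and widths spread over two
#' decades), with a two-mode option representing an MFC/NFC mixture.
#'
#' @param width_range_um length-2 numeric, min/max fiber width in µm
#'   (0 < min <= max).
#' @param width_law one of `"log-uniform"`, `"log-normal"`,
#'   `"two-mode"`.
#' @param aspect_ratio fiber length / width, >= 1.
#' @param wall_thickness_um fiber wall thickness, µm (> 0); the deposited
#'   vertical solid thickness is `2 * wall + lumen` (collapsed lumen
#'   contributes 0, see [sim_config()]).
#' @param lumen_um lumen diameter, µm (0 = collapsed).
#' @param flexibility non-negative integer: maximum vertical deflection in
#'   voxels per lateral voxel step when the fiber drapes over the structure.
#' @param mixture_weight fraction of nano-mode fibers when
#'   `width_law = "two-mode"`; the mode boundary is the geometric midpoint
#'   of `width_range_um`.
#' @param sdlog log-sd for `"log-normal"` (defaults to a quarter of the
#'   log-range; samples are truncated to the range).
#' @return a `fiber_population_spec` list.
#' @seealso [sample_fiber_population()]
#' @export
#' @examples
#' fiber_population_spec(c(0.0685, 9.8))
fiber_population_spec <- function(width_range_um = c(0.0685, 9.8),
                                  width_law = c("log-uniform", "log-normal", "two-mode"),
                                  aspect_ratio = 20,
                                  wall_thickness_um = 0.5,
                                  lumen_um = 0,
                                  flexibility = 1,
                                  mixture_weight = 0.5,
                                  sdlog = NULL) {
  width_law <- match.arg(width_law)
  check_num(width_range_um, "width_range_um", len = 2L)
  if (width_range_um[1] <= 0 || width_range_um[1] > width_range_um[2])
    stop_field("width_range_um", "need 0 < min <= max")
  check_num(aspect_ratio, "aspect_ratio", lower = 1)
  check_num(wall_thickness_um, "wall_thickness_um", lower = 1e-12)
  check_num(lumen_um, "lumen_um", lower = 0)
  check_num(flexibility, "flexibility", lower = 0, integer = TRUE)
  check_num(mixture_weight, "mixture_weight", lower = 0, upper = 1)
  if (is.null(sdlog)) sdlog <- diff(log(width_range_um)) / 4
  structure(list(width_range_um = as.double(width_range_um),
                 width_law = width_law,
                 aspect_ratio = as.double(aspect_ratio),
                 wall_thickness_um = as.double(wall_thickness_um),
                 lumen_um = as.double(lumen_um),
                 flexibility = as.integer(flexibility),
                 mixture_weight = as.double(mixture_weight),
                 sdlog = as.double(sdlog)),
            class = "fiber_population_spec")
}

#' @export
print.fiber_population_spec <- function(x, ...) {
  cat(sprintf(paste0("<fiber_population_spec> widths %s [%g, %g] um, aspect %g, ",
                     "wall %g um, lumen %g um, flexibility %d\n"),
              x$width_law, x$width_range_um[1], x$width_range_um[2],
              x$aspect_ratio, x$wall_thickness_um, x$lumen_um, x$flexibility))
  invisible(x)
}

sample_widths <- function(spec, n) {
  rng <- spec$width_range_um
  if (rng[1] == rng[2]) return(rep(rng[1], n))
  lo <- log(rng[1]); hi <- log(rng[2])
  switch(spec$width_law,
    "log-uniform" = exp(runif(n, lo, hi)),
    "log-normal" = {
      mu <- (lo + hi) / 2
      x <- rnorm(n, mu, spec$sdlog)
      pmin(pmax(exp(x), rng[1]), rng[2])
    },
    "two-mode" = {
      mid <- (lo + hi) / 2
      nano <- runif(n) < spec$mixture_weight
      x <- ifelse(nano, runif(n, lo, mid), runif(n, mid, hi))
      exp(x)
    })
}

#' Sample a fiber population
#'
#' Draws `n` fiber morphology records from a population spec.  Deterministic
#' for a fixed seed; every width lies inside the spec's range and length is
#' `aspect_ratio * width`.
#'
#' @param spec a [fiber_population_spec()].
#' @param n number of fibers (>= 1).
#' @param seed integer seed.
#' @return a `data.frame` (class `fiber_population`) with columns
#'   `width_um`, `length_um`, `wall_thickness_um`, `lumen_um`, `flexibility`.
#' @export
#' @examples
#' pop <- sample_fiber_population(fiber_population_spec(), 5, seed = 1)
sample_fiber_population <- function(spec, n, seed = 1L) {
  if (!inherits(spec, "fiber_population_spec"))
    spec <- do.call(fiber_population_spec, spec)
  check_num(n, "n", lower = 1, integer = TRUE)
  set.seed(seed)
  w <- sample_widths(spec, n)
  out <- data.frame(width_um = w,
                    length_um = spec$aspect_ratio * w,
                    wall_thickness_um = rep(spec$wall_thickness_um, n),
                    lumen_um = rep(spec$lumen_um, n),
                    flexibility = rep(spec$flexibility, n))
  class(out) <- c("fiber_population", "data.frame")
  out
}

#' Specify a phantom image
#'
#' A phantom is a constructed binary image with exactly known porosity and
#' pore geometry, used as ground truth for segmentation and morphometry.
#' Pores (void) are carved out of a solid or fibrous-texture background.
#'
#' @param image_shape_px length-2 integer `(H, W)` in pixels.
#' @param resolution_um_per_px pixel size, µm (> 0).
#' @param pores `data.frame` with columns `shape` ("disc" or "rectangle"),
#'   `x_um`, `y_um` (centre), `size1_um` (disc radius / rectangle height),
#'   `size2_um` (rectangle width; ignored for discs).  May be empty.
#' @param background `"solid"` or `"fibrous-texture"` (random solid ribbons;
#'   its own inter-fiber voids mean analytic per-pore truth is only kept for
#'   solid backgrounds).
#' @param allow_overlap if `FALSE` (default), overlapping requested pores are
#'   an error so that each pore stays a distinct connected component.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_shape_px = c(100L, 100L),
                         resolution_um_per_px = 1,
                         pores = data.frame(),
                         background = c("solid", "fibrous-texture"),
                         allow_overlap = FALSE) {
  background <- match.arg(background)
  check_num(image_shape_px, "image_shape_px", lower = 1, len = 2L, integer = TRUE)
  check_num(resolution_um_per_px, "resolution_um_per_px", lower = 1e-12)
  if (nrow(pores) > 0) {
    need <- c("shape", "x_um", "y_um", "size1_um")
    if (!all(need %in% names(pores)))
      stop_field("pores", paste("needs columns", paste(need, collapse = ", ")))
    ext_um <- image_shape_px * resolution_um_per_px
    s2 <- if ("size2_um" %in% names(pores)) pores$size2_um else pores$size1_um
    half_x <- ifelse(pores$shape == "rectangle", pores$size1_um / 2, pores$size1_um)
    half_y <- ifelse(pores$shape == "rectangle", s2 / 2, pores$size1_um)
    if (any(pores$x_um - half_x < 0) || any(pores$x_um + half_x > ext_um[1]) ||
        any(pores$y_um - half_y < 0) || any(pores$y_um + half_y > ext_um[2]))
      stop_field("pores", "every pore must lie inside the image")
  }
  structure(list(image_shape_px = as.integer(image_shape_px),
                 resolution_um_per_px = as.double(resolution_um_per_px),
                 pores = pores, background = background,
                 allow_overlap = isTRUE(allow_overlap)),
            class = "phantom_spec")
}

#' Random non-overlapping disc pores
#'
#' Convenience constructor: scatter `n` disc pores with radii uniform in
#' `r_range_um`, rejecting overlaps (and border clipping) so ground truth
#' stays analytic.
#'
#' @inheritParams phantom_spec
#' @param n number of discs.
#' @param r_range_um radius range, µm.
#' @param seed integer seed.
#' @param max_tries rejection-sampling cap per disc.
#' @return a `phantom_spec`.
#' @export
random_disc_phantom <- function(image_shape_px = c(128L, 128L),
                                resolution_um_per_px = 1,
                                n = 20, r_range_um = c(2, 6), seed = 1L,
                                max_tries = 2000) {
  set.seed(seed)
  ext <- image_shape_px * resolution_um_per_px
  xs <- ys <- rs <- numeric(0)
  for (k in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      r <- runif(1, r_range_um[1], r_range_um[2])
      x <- runif(1, r + resolution_um_per_px, ext[1] - r - resolution_um_per_px)
      y <- runif(1, r + resolution_um_per_px, ext[2] - r - resolution_um_per_px)
      # one-pixel margin keeps discretized discs disjoint components
      if (all(sqrt((xs - x)^2 + (ys - y)^2) > rs + r + 2 * resolution_um_per_px)) {
        xs <- c(xs, x); ys <- c(ys, y); rs <- c(rs, r); ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place ", n, " non-overlapping discs; reduce n or radii")
  }
  phantom_spec(image_shape_px, resolution_um_per_px,
               pores = data.frame(shape = "disc", x_um = xs, y_um = ys,
                                  size1_um = rs),
               background = "solid")
}

rasterize_pore <- function(spec, p) {
  H <- spec$image_shape_px[1]; W <- spec$image_shape_px[2]
  res <- spec$resolution_um_per_px
  # pixel centres at (i - 0.5) * res
  xc <- (seq_len(H) - 0.5) * res
  yc <- (seq_len(W) - 0.5) * res
  if (p$shape == "disc") {
    outer(xc, yc, function(x, y) (x - p$x_um)^2 + (y - p$y_um)^2 <= p$size1_um^2)
  } else if (p$shape == "rectangle") {
    h <- p$size1_um
    w <- if (!is.null(p$size2_um) && !is.na(p$size2_um)) p$size2_um else p$size1_um
    outer(xc, yc, function(x, y)
      x > p$x_um - h / 2 & x <= p$x_um + h / 2 &
      y > p$y_um - w / 2 & y <= p$y_um + w / 2)
  } else stop_field("pores$shape", paste("unknown shape", p$shape))
}

fibrous_background <- function(H, W, res) {
  # random solid ribbons over a void canvas until ~75% solid coverage
  m <- matrix(FALSE, H, W)
  n_target <- 0.75
  guard <- 0
  while (mean(m) < n_target && guard < 10000) {
    guard <- guard + 1
    len <- runif(1, 0.3, 0.8) * max(H, W)
    wid <- max(1, round(runif(1, 1, 6)))
    cx <- runif(1, 1, H); cy <- runif(1, 1, W); a <- runif(1, 0, pi)
    co <- cos(a); si <- sin(a)
    ii <- row(m) - cx; jj <- col(m) - cy
    u <- ii * co + jj * si; v <- -ii * si + jj * co
    m <- m | (abs(u) <= len / 2 & abs(v) <= wid / 2)
  }
  m
}

#' Build a phantom binary image with exact ground truth
#'
#' Renders the phantom spec to a `binary_image` (solid = 1, pore = 0) and
#' computes ground truth by direct pixel counting, which is exact by
#' construction.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed (only used by the fibrous-texture background).
#' @return list with elements `image` (a `binary_image`) and `truth`, a
#'   `ground_truth` list: `true_porosity`, `true_pore_areas_um2` (per
#'   requested pore, solid background only), `void_px`.
#' @export
#' @examples
#' ph <- make_phantom_binary(phantom_spec(c(100, 100), 1,
#'   pores = data.frame(shape = "rectangle", x_um = 50, y_um = 50,
#'                      size1_um = 5, size2_um = 5)))
#' ph$truth$true_porosity   # 0.0025
make_phantom_binary <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(seed)
  H <- spec$image_shape_px[1]; W <- spec$image_shape_px[2]
  res <- spec$resolution_um_per_px
  solid <- if (spec$background == "solid") matrix(TRUE, H, W)
           else fibrous_background(H, W, res)
  areas <- numeric(0)
  if (nrow(spec$pores) > 0) {
    masks <- lapply(seq_len(nrow(spec$pores)), function(i)
      rasterize_pore(spec, as.list(spec$pores[i, , drop = FALSE])))
    if (!spec$allow_overlap && length(masks) > 1) {
      tot <- Reduce(`+`, lapply(masks, function(m) m * 1L))
      if (any(tot > 1L))
        stop("pores overlap but `allow_overlap` is FALSE", call. = FALSE)
    }
    for (m in masks) solid[m] <- FALSE
    areas <- vapply(masks, function(m) sum(m) * res^2, numeric(1))
  }
  img <- binary_image(solid * 1L, res)
  truth <- list(
    true_porosity = sum(img == 0L) / length(img),
    true_pore_areas_um2 = if (spec$background == "solid") sort(areas, decreasing = TRUE) else NULL,
    void_px = sum(img == 0L))
  class(truth) <- "ground_truth"
  list(image = img, truth = truth)
}

#' Write a phantom image with its ground-truth JSON sidecar
#'
#' @param phantom result of [make_phantom_binary()].
#' @param path image path (`.png` or `.pgm`); the sidecar is written next to
#'   it as `<path>.truth.json`.
#' @return the sidecar path, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  write_image(phantom$image, path)
  sidecar <- paste0(path, ".truth.json")
  jsonlite::write_json(
    list(true_porosity = phantom$truth$true_porosity,
         pore_areas_um2 = phantom$truth$true_pore_areas_um2,
         resolution_um_per_px = img_res(phantom$image)),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(sidecar)
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(x) {
    # replicate-pad each column vector, convolve, crop
    n <- length(x)
    xp <- c(rep(x[1], r), x, rep(x[n], r))
    as.numeric(stats::filter(xp, k, sides = 2))[(r + 1):(r + n)]
  }
  m <- apply(m, 2, pad_conv)
  t(apply(m, 1, pad_conv))
}

#' Render an SEM-like grayscale image from a binary structure image
#'
#' Emulates the contrast of a secondary-electron micrograph of a fibrous mat:
#' solid (fiber) bright, pores dark, optional Gaussian blur (beam/detector
#' point spread) and additive Gaussian noise.  With zero blur and noise the
#' output equals the binary image cast to `{0, 1}`.
#'
#' @param binary a `binary_image`.
#' @param blur_sigma_px Gaussian blur sd in pixels (>= 0).
#' @param noise_sd additive Gaussian noise sd (>= 0); intensities are clipped
#'   back to `[0, 1]`.
#' @param seed integer seed for the noise stream.
#' @return a `gray_image` at the same resolution.
#' @export
render_sem_like <- function(binary, blur_sigma_px = 1.5, noise_sd = 0.05,
                            seed = 1L) {
  check_num(blur_sigma_px, "blur_sigma_px", lower = 0)
  check_num(noise_sd, "noise_sd", lower = 0)
  res <- img_res(binary)
  g <- matrix(as.double(unclass(binary)), nrow(binary), ncol(binary))
  g <- gaussian_blur(g, blur_sigma_px)
  if (noise_sd > 0) {
    set.seed(seed)
    g <- g + rnorm(length(g), 0, noise_sd)
  }
  g <- pmin(pmax(g, 0), 1)
  gray_image(matrix(g, nrow(binary), ncol(binary)), res)
}
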