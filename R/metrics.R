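#' Surface porosity of a binary image
#'
#' Void-pixel fraction (pore = 0, solid = 1) of a 2D top-view or micrograph
#' binary image.
#'
#' @param binary a `binary_image` (or 0/1 matrix).
#' @return fraction in `[0, 1]`.
#' @export
surface_porosity <- function(binary) {
  if (length(binary) == 0) stop("empty image")
  if (!is_binary(binary)) stop("surface_porosity() needs a binary image")
  sum(binary == 0) / length(binary)
}

#' Top-view binary image of a simulated structure
#'
#' Emulates what a top-down micrograph of the mat sees: a pixel is solid iff
#' its column holds any solid voxel within `depth_voxels` of the structure's
#' maximum height.  The default depth, twice the median fiber vertical
#' thickness of the placed fibers, is an SEM visibility-depth surrogate and
#' is the knob calibrated against measured surface porosities.
#'
#' @param structure a `structure3d`.
#' @param depth_voxels visibility depth d >= 1 (`Inf` = full depth: a pixel
#'   is solid iff its column holds any solid voxel); `NULL` for the default.
#' @return a `binary_image` at the structure's lateral resolution.
#' @export
render_top_view <- function(structure, depth_voxels = NULL) {
  if (is.null(depth_voxels)) {
    tv <- structure$fiber_log$t_vox[structure$fiber_log$placed]
    depth_voxels <- if (length(tv)) 2 * median(tv) else 1
  }
  check_num(depth_voxels, "depth_voxels", lower = 1)
  h <- structure$height_map
  zmax <- max(h)
  if (zmax == 0)
    return(binary_image(matrix(0L, nrow(h), ncol(h)),
                        structure$resolution_um_per_voxel))
  # column top voxel is solid, so "any voxel with z >= zmax - d" == height > zmax - d;
  # empty columns (height 0) are always void, whatever the depth
  solid <- h > 0 & h > (zmax - depth_voxels)
  binary_image(solid * 1L, structure$resolution_um_per_voxel)
}

#' Pore areas from a binary image
#'
#' Connected components of the void phase under 8-connectivity (the
#' complementary solid phase is treated 4-connected), including components
#' touching the border; areas in µm², sorted descending.
#'
#' @param binary a `binary_image`.
#' @return numeric vector of areas (µm²); empty if there is no void.
#' @export
pore_areas <- function(binary) {
  if (!is_binary(binary)) stop("pore_areas() needs a binary image")
  res <- img_res(binary)
  void <- matrix(binary == 0, nrow(binary), ncol(binary))
  if (!any(void)) return(numeric(0))
  lab <- cpp_label(void, 8L)
  counts <- tabulate(lab[lab > 0])
  sort(counts * res^2, decreasing = TRUE)
}

#' Fiber widths by skeleton + distance transform
#'
#' Thins the solid phase to a one-pixel skeleton (Zhang–Suen) and reads the
#' local fiber width at each skeleton pixel as twice the Euclidean distance
#' to the nearest void pixel.  This is the standard micrograph fiber-diameter
#' morphometry; widths are per-skeleton-pixel samples, so long fibers weigh
#' proportionally to their length.
#'
#' @param binary a `binary_image` with a non-empty solid phase.
#' @return list with `widths_um` (per-skeleton-pixel sample) and `stats`
#'   (min, max, mean, P5, P95 in µm).
#' @export
fiber_widths <- function(binary) {
  if (!is_binary(binary)) stop("fiber_widths() needs a binary image")
  res <- img_res(binary)
  solid <- matrix(binary == 1, nrow(binary), ncol(binary))
  if (!any(solid)) stop("no solid phase: fiber widths undefined")
  if (all(solid)) stop("image is all solid: fiber width undefined without void")
  skel <- cpp_thin(solid)
  d <- cpp_edt(solid)
  w <- 2 * d[skel] * res
  w <- w[is.finite(w)]
  list(widths_um = w,
       stats = c(min = min(w), max = max(w), mean = mean(w),
                 P5 = pquant(w, 0.05), P95 = pquant(w, 0.95)))
}

#' Bulk (volumetric) porosity of a simulated structure
#'
#' Void fraction of the mat inside its mean-thickness envelope.  The default
#' `"covered"` convention averages column height and counts area over covered
#' (non-empty) columns only, so a uniform slab has porosity 0 regardless of
#' lateral coverage; the `"full"` convention uses the whole domain area with
#' the same mean height, counting never-covered columns as void.
#'
#' @param structure a non-empty `structure3d`.
#' @param convention `"covered"` (default) or `"full"`.
#' @return fraction in `[0, 1]`.
#' @export
bulk_porosity <- function(structure, convention = c("covered", "full")) {
  convention <- match.arg(convention)
  h <- structure$height_map
  if (all(h == 0)) stop("empty structure: bulk porosity undefined")
  solid <- sum(structure$occupancy)
  zbar <- mean(h[h > 0])
  ncols <- if (convention == "covered") sum(h > 0) else length(h)
  p <- 1 - solid / (ncols * zbar)
  max(0, min(1, p))
}

pore_stats <- function(areas) {
  if (length(areas) == 0)
    return(c(count = 0, min = NA_real_, max = NA_real_, P5 = NA_real_,
             P95 = NA_real_, mean = NA_real_, cv = NA_real_))
  c(count = length(areas), min = min(areas), max = max(areas),
    P5 = pquant(areas, 0.05), P95 = pquant(areas, 0.95),
    mean = mean(areas), cv = if (length(areas) > 1) sd(areas) / mean(areas) else 0)
}

#' Structure metrics for an image or simulated structure
#'
#' Bundles the morphometric quantities used throughout the package: surface
#' porosity, pore-area distribution statistics (count, min, max, P5, P95,
#' mean, CV) and fiber-width statistics; for a `structure3d`, additionally
#' bulk porosity, measured on the [render_top_view()] image.
#'
#' @param x a `binary_image` or a `structure3d`.
#' @param depth_voxels top-view depth for structures (`NULL` = default).
#' @param fiber_widths compute the (more expensive) skeleton widths?
#' @return a `structure_metrics` list.
#' @export
structure_metrics <- function(x, depth_voxels = NULL, fiber_widths = TRUE) {
  if (inherits(x, "structure3d")) {
    img <- render_top_view(x, depth_voxels)
    bp <- bulk_porosity(x)
  } else {
    img <- x
    bp <- NA_real_
  }
  areas <- pore_areas(img)
  fw <- if (fiber_widths && any(img == 1) && any(img == 0))
    fiber_widths(img) else NULL
  out <- list(surface_porosity = surface_porosity(img),
              bulk_porosity = bp,
              pore_areas_um2 = areas,
              pore_stats = pore_stats(areas),
              fiber_width_stats = if (!is.null(fw)) fw$stats else NULL,
              fiber_widths_um = if (!is.null(fw)) fw$widths_um else NULL,
              resolution_um_per_px = img_res(img))
  class(out) <- "structure_metrics"
  out
}

#' @export
print.structure_metrics <- function(x, ...) {
  cat(sprintf("<structure_metrics> surface porosity %.3f", x$surface_porosity))
  if (!is.na(x$bulk_porosity)) cat(sprintf(", bulk porosity %.3f", x$bulk_porosity))
  cat(sprintf("\n  pores: n=%d, P5=%.3g, P95=%.3g um^2, CV=%.2f\n",
              x$pore_stats["count"], x$pore_stats["P5"], x$pore_stats["P95"],
              x$pore_stats["cv"]))
  if (!is.null(x$fiber_width_stats))
    cat(sprintf("  fiber widths: %.3g-%.3g um, mean %.3g um\n",
                x$fiber_width_stats["min"], x$fiber_width_stats["max"],
                x$fiber_width_stats["mean"]))
  invisible(x)
}
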