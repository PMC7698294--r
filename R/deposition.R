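#' Single-fiber morphology
#'
#' One fiber's geometry for deposition.  The deposited vertical solid
#' thickness is `2 * wall_thickness_um` for a collapsed lumen plus
#' `lumen_um` when the lumen is kept open.
#'
#' @param width_um,length_um lateral fiber dimensions, µm (> 0); by
#'   convention `length_um = aspect_ratio * width_um`.
#' @param wall_thickness_um wall thickness, µm (> 0).
#' @param lumen_um lumen, µm (>= 0).
#' @param flexibility non-negative integer F: maximum vertical drop in voxels
#'   per lateral voxel step while draping.
#' @return a `fiber_morphology` list.
#' @export
fiber_morphology <- function(width_um, length_um, wall_thickness_um = 0.5,
                             lumen_um = 0, flexibility = 1) {
  check_num(width_um, "width_um", lower = 1e-12)
  check_num(length_um, "length_um", lower = 1e-12)
  check_num(wall_thickness_um, "wall_thickness_um", lower = 1e-12)
  check_num(lumen_um, "lumen_um", lower = 0)
  check_num(flexibility, "flexibility", lower = 0, integer = TRUE)
  structure(list(width_um = width_um, length_um = length_um,
                 wall_thickness_um = wall_thickness_um, lumen_um = lumen_um,
                 flexibility = as.integer(flexibility)),
            class = "fiber_morphology")
}

#' Deposition simulation configuration
#'
#' @param domain_px lateral grid size `(Nx, Ny)` in voxels (>= 16 each).
#' @param resolution_um_per_voxel voxel edge, µm.  0.5 suits micro-scale
#'   furnishes; nano-scale populations need a finer grid (sub-voxel widths
#'   are clamped to one voxel).
#' @param target_layers deposition stops once mean areal coverage (sum of
#'   fiber footprint areas / domain area) reaches this "number of layers in
#'   the thickness direction".
#' @param population a [fiber_population_spec()].
#' @param seed integer seed.
#' @param boundary `"periodic"` (default; no edge artifacts) or `"clipped"`.
#' @param lumen `"collapsed"` (default; lumen adds no thickness, typical for
#'   refined/homogenized cellulose) or `"open"` (lumen kept as interior
#'   thickness — counted as pore space in bulk porosity).
#' @param max_fibers guard against non-convergence.
#' @return a `sim_config` list.
#' @export
sim_config <- function(domain_px = c(256L, 256L),
                       resolution_um_per_voxel = 0.5,
                       target_layers = 4,
                       population = fiber_population_spec(),
                       seed = 1L,
                       boundary = c("periodic", "clipped"),
                       lumen = c("collapsed", "open"),
                       max_fibers = 50000L) {
  boundary <- match.arg(boundary)
  lumen <- match.arg(lumen)
  check_num(domain_px, "domain_px", lower = 16, len = 2L, integer = TRUE)
  check_num(resolution_um_per_voxel, "resolution_um_per_voxel", lower = 1e-12)
  check_num(target_layers, "target_layers", lower = 1e-12)
  if (!inherits(population, "fiber_population_spec"))
    population <- do.call(fiber_population_spec, population)
  structure(list(domain_px = as.integer(domain_px),
                 resolution_um_per_voxel = resolution_um_per_voxel,
                 target_layers = target_layers, population = population,
                 seed = as.integer(seed), boundary = boundary, lumen = lumen,
                 max_fibers = as.integer(max_fibers)),
            class = "sim_config")
}

# voxelize fiber dimensions; lengths capped so a periodic fiber cannot wrap
# onto itself (self-overlap would break the no-overwrite invariant)
fiber_voxels <- function(width_um, length_um, wall_um, lumen_um, res,
                         nx, ny, lumen_mode) {
  w <- pmax(1, round(width_um / res))
  l <- pmax(1, round(length_um / res))
  lcap <- pmax(1, min(nx, ny) - w - 2)
  l <- pmin(l, lcap)
  t_um <- 2 * wall_um + if (lumen_mode == "open") lumen_um else 0
  t <- pmax(1, round(t_um / res))
  cbind(w_vox = w, l_vox = l, t_vox = t)
}

new_structure3d <- function(nx, ny, res, boundary = "periodic", config = NULL) {
  structure(list(
    occupancy = array(FALSE, dim = c(nx, ny, 1L)),
    height_map = matrix(0L, nx, ny),
    fiber_log = empty_fiber_log(),
    resolution_um_per_voxel = res,
    boundary = boundary,
    config = config), class = "structure3d")
}

empty_fiber_log <- function() {
  data.frame(width_um = numeric(0), length_um = numeric(0),
             w_vox = integer(0), l_vox = integer(0), t_vox = integer(0),
             flexibility = integer(0), cx = numeric(0), cy = numeric(0),
             angle = numeric(0), placed = logical(0), voxels = integer(0),
             footprint_area = integer(0), b_min = integer(0),
             b_max = integer(0), reason = character(0))
}

deposit_batch <- function(structure, fib_mat, meta, target_cov, cov0) {
  nx <- dim(structure$occupancy)[1]; ny <- dim(structure$occupancy)[2]
  nz <- dim(structure$occupancy)[3]
  has_solid <- any(structure$height_map > 0)
  res <- cpp_deposit(nx, ny,
                     as.integer(structure$height_map),
                     if (has_solid) as.raw(structure$occupancy) else raw(0),
                     if (has_solid) nz else 0L,
                     fib_mat,
                     structure$boundary == "periodic",
                     target_cov, cov0)
  na <- res$n_attempted
  occ <- array(as.logical(res$occ), dim = c(nx, ny, res$nz))
  structure$occupancy <- occ
  structure$height_map <- matrix(res$height, nx, ny)
  if (na > 0) {
    log_new <- data.frame(meta[seq_len(na), , drop = FALSE],
                          placed = res$placed[seq_len(na)],
                          voxels = res$voxels[seq_len(na)],
                          footprint_area = res$footprint[seq_len(na)],
                          b_min = res$b_min[seq_len(na)],
                          b_max = res$b_max[seq_len(na)],
                          reason = res$reason[seq_len(na)])
    structure$fiber_log <- rbind(structure$fiber_log, log_new)
  }
  attr(structure, "coverage") <- res$coverage
  structure
}

#' Place one fiber onto a structure
#'
#' Rasterizes the fiber as a straight ribbon of voxels at the given in-plane
#' angle, then drapes it onto the current surface: the bottom surface is the
#' minimal surface that (a) rests on or above the present height map and
#' (b) changes by at most `flexibility` voxels between lateral neighbours
#' inside the footprint.  `flexibility = 0` bridges rigidly across gaps;
#' large values conform fully and create no new voids.
#'
#' @param structure a `structure3d` (see [simulate_structure()]), or `NULL`
#'   to start from an empty grid of `domain_px` voxels.
#' @param fiber a [fiber_morphology()].
#' @param center length-2 numeric, lateral centre in voxel units.
#' @param angle in-plane angle, radians.
#' @param domain_px,resolution_um_per_voxel,boundary grid parameters used
#'   when `structure` is `NULL`.
#' @param lumen `"collapsed"` or `"open"`.
#' @return the updated `structure3d`; the placement record (including
#'   rejections, with a reason) is appended to `$fiber_log`.
#' @export
place_fiber <- function(structure, fiber, center, angle,
                        domain_px = c(64L, 64L), resolution_um_per_voxel = 0.5,
                        boundary = "periodic", lumen = "collapsed") {
  stopifnot(inherits(fiber, "fiber_morphology"))
  if (is.null(structure))
    structure <- new_structure3d(domain_px[1], domain_px[2],
                                 resolution_um_per_voxel, boundary)
  nx <- dim(structure$occupancy)[1]; ny <- dim(structure$occupancy)[2]
  res <- structure$resolution_um_per_voxel
  vox <- fiber_voxels(fiber$width_um, fiber$length_um, fiber$wall_thickness_um,
                      fiber$lumen_um, res, nx, ny, lumen)
  fib_mat <- cbind(vox[, "w_vox"], vox[, "l_vox"], vox[, "t_vox"],
                   fiber$flexibility, center[1], center[2], angle)
  meta <- data.frame(width_um = fiber$width_um, length_um = fiber$length_um,
                     w_vox = vox[, "w_vox"], l_vox = vox[, "l_vox"],
                     t_vox = vox[, "t_vox"], flexibility = fiber$flexibility,
                     cx = center[1], cy = center[2], angle = angle)
  out <- deposit_batch(structure, fib_mat, meta, Inf, 0)
  last <- out$fiber_log[nrow(out$fiber_log), ]
  if (!last$placed)
    warning("fiber placement rejected: ", last$reason, call. = FALSE)
  out
}

#' Simulate a fiber mat by sequential deposition
#'
#' Samples fibers from the configured population, drops them at uniform
#' random positions and orientations, and drapes each onto the growing
#' structure until mean areal coverage reaches `target_layers`.
#' Deterministic for a fixed config seed.
#'
#' @param config a [sim_config()].
#' @return a `structure3d`: logical `occupancy` array `(Nx, Ny, Nz)` with
#'   `z = 1` the substrate, integer `height_map` (`1 + top voxel index`, 0
#'   for empty columns), per-fiber `fiber_log`, and the config echo.
#' @export
#' @examples
#' cfg <- sim_config(domain_px = c(32, 32), target_layers = 1, seed = 7,
#'   population = fiber_population_spec(c(2, 4), aspect_ratio = 5))
#' st <- simulate_structure(cfg)
#' sum(st$occupancy) == sum(st$fiber_log$voxels)
simulate_structure <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  nx <- config$domain_px[1]; ny <- config$domain_px[2]
  res <- config$resolution_um_per_voxel
  st <- new_structure3d(nx, ny, res, config$boundary, config)
  set.seed(config$seed)
  cov <- 0
  batch <- 512L
  total <- 0L
  while (cov < config$target_layers) {
    if (total >= config$max_fibers)
      stop(sprintf(paste0("deposition did not reach target_layers = %g after %d ",
                          "fibers (coverage %.3f); check population/domain scale"),
                   config$target_layers, total, cov), call. = FALSE)
    n <- min(batch, config$max_fibers - total)
    w <- sample_widths(config$population, n)
    fib <- data.frame(width_um = w,
                      length_um = config$population$aspect_ratio * w)
    cx <- runif(n, 0, nx); cy <- runif(n, 0, ny); ang <- runif(n, 0, pi)
    vox <- fiber_voxels(fib$width_um, fib$length_um,
                        config$population$wall_thickness_um,
                        config$population$lumen_um, res, nx, ny, config$lumen)
    fib_mat <- cbind(vox[, "w_vox"], vox[, "l_vox"], vox[, "t_vox"],
                     config$population$flexibility, cx, cy, ang)
    meta <- data.frame(width_um = fib$width_um, length_um = fib$length_um,
                       w_vox = vox[, "w_vox"], l_vox = vox[, "l_vox"],
                       t_vox = vox[, "t_vox"],
                       flexibility = config$population$flexibility,
                       cx = cx, cy = cy, angle = ang)
    st <- deposit_batch(st, fib_mat, meta, config$target_layers, cov)
    total <- nrow(st$fiber_log)
    cov <- attr(st, "coverage")
  }
  attr(st, "coverage") <- cov
  st
}

#' Recompute the top height map from occupancy
#'
#' Scans the occupancy grid and returns, per lateral column, `1 +` the top
#' solid voxel index (0 for empty columns).  Must equal the incrementally
#' maintained `$height_map` exactly.
#'
#' @param structure a `structure3d`.
#' @return integer matrix `(Nx, Ny)`.
#' @export
top_height_map <- function(structure) {
  occ <- structure$occupancy
  nz <- dim(occ)[3]
  h <- matrix(0L, dim(occ)[1], dim(occ)[2])
  for (z in seq_len(nz)) {
    sl <- occ[, , z]
    h[sl] <- z
  }
  h
}

#' @export
print.structure3d <- function(x, ...) {
  d <- dim(x$occupancy)
  cat(sprintf(paste0("<structure3d> %d x %d x %d voxels @ %g um, %d fibers ",
                     "placed, mean height %.1f\n"),
              d[1], d[2], d[3], x$resolution_um_per_voxel,
              sum(x$fiber_log$placed), mean(x$height_map)))
  invisible(x)
}
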