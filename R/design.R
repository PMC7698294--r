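#' Design space for simulation sweeps
#'
#' Each parameter is either a numeric range `c(lo, hi)` (continuous) or a
#' `list(levels = ...)` of explicit levels (required for the full-factorial
#' scheme).  Parameters named in `integer_params` are rounded to whole
#' numbers after sampling.
#'
#' @param params named list of ranges / level sets over fiber-population and
#'   deposition parameters (`aspect_ratio`, `wall_thickness_um`,
#'   `flexibility`, `target_layers`, `mixture_weight`, ...).
#' @param scheme `"latin-hypercube"` (default), `"full-factorial"`, or
#'   `"uniform-random"`.
#' @param n_designs number of parameter combinations (ignored by
#'   full-factorial).
#' @param seeds_per_design replicate simulations per design.
#' @param integer_params names of integer-valued parameters.
#' @return a `design_space` list.
#' @seealso [default_design_space()], [generate_design()]
#' @export
design_space <- function(params, scheme = c("latin-hypercube", "full-factorial",
                                            "uniform-random"),
                         n_designs = 200L, seeds_per_design = 5L,
                         integer_params = "flexibility") {
  scheme <- match.arg(scheme)
  stopifnot(is.list(params), length(params) >= 1, !is.null(names(params)))
  check_num(n_designs, "n_designs", lower = 1, integer = TRUE)
  check_num(seeds_per_design, "seeds_per_design", lower = 1, integer = TRUE)
  for (nm in names(params)) {
    p <- params[[nm]]
    if (is.list(p)) {
      if (is.null(p$levels) || length(p$levels) < 1)
        stop_field(nm, "list parameters need a non-empty `levels`")
    } else {
      check_num(p, nm, len = 2L)
      if (p[1] > p[2]) stop_field(nm, "range must have lo <= hi")
    }
  }
  structure(list(params = params, scheme = scheme,
                 n_designs = as.integer(n_designs),
                 seeds_per_design = as.integer(seeds_per_design),
                 integer_params = integer_params),
            class = "design_space")
}

#' Default design space and base configuration for the porosity sweep
#'
#' The committed desk-scale exploration space: a two-mode MFC/NFC width
#' mixture spanning 0.0685–9.8 µm with the nano-mode fraction, fiber aspect
#' ratio, wall thickness, flexibility and deposited coverage varied over
#' ranges bracketing the calibrated validation point — thin mats below one
#' full fiber layer, where surface pores are inter-fiber gaps at the fiber
#' scale (see the methods vignette for the calibration).
#'
#' @param n_designs,seeds_per_design sweep size (defaults 200 x 5, the
#'   desk-scale stand-in for a 1000-structure sweep).
#' @return a `design_space`.
#' @export
default_design_space <- function(n_designs = 200L, seeds_per_design = 5L) {
  design_space(
    params = list(aspect_ratio = c(10, 30),
                  wall_thickness_um = c(0.3, 0.8),
                  flexibility = c(0, 2),
                  target_layers = c(0.6, 0.8),
                  mixture_weight = c(0.5, 0.9)),
    scheme = "latin-hypercube",
    n_designs = n_designs, seeds_per_design = seeds_per_design)
}

#' @rdname default_design_space
#' @export
default_sweep_base <- function() {
  sim_config(domain_px = c(256L, 256L), resolution_um_per_voxel = 0.1,
             population = fiber_population_spec(c(0.0685, 9.8),
                                                width_law = "two-mode"))
}

#' Generate a design table from a design space
#'
#' Latin-hypercube sampling stratifies every parameter's marginal (one draw
#' per equal-probability stratum, strata independently permuted);
#' full-factorial crosses explicit levels; uniform-random draws i.i.d.
#' Deterministic for a fixed seed.
#'
#' @param space a [design_space()].
#' @param seed integer seed.
#' @return a `data.frame` (class `design_table`) with `design_id` and one
#'   column per parameter; parameter columns recorded in attribute
#'   `param_cols`.
#' @export
generate_design <- function(space, seed = 1L) {
  stopifnot(inherits(space, "design_space"))
  set.seed(seed)
  pn <- names(space$params)
  if (space$scheme == "full-factorial") {
    lv <- lapply(pn, function(nm) {
      p <- space$params[[nm]]
      if (!is.list(p))
        stop_field(nm, "full-factorial needs explicit `levels` for every parameter")
      p$levels
    })
    ncell <- prod(vapply(lv, length, numeric(1)))
    if (ncell > 1e5)
      stop("full factorial would need ", format(ncell, big.mark = ","),
           " cells; use latin-hypercube or uniform-random sampling",
           call. = FALSE)
    tab <- do.call(expand.grid, stats::setNames(lv, pn))
  } else {
    n <- space$n_designs
    cols <- lapply(pn, function(nm) {
      p <- space$params[[nm]]
      u <- if (space$scheme == "latin-hypercube")
        (sample.int(n) - runif(n)) / n
      else runif(n)
      if (is.list(p)) {
        lev <- p$levels
        lev[pmin(length(lev), floor(u * length(lev)) + 1L)]
      } else {
        p[1] + u * (p[2] - p[1])
      }
    })
    tab <- as.data.frame(stats::setNames(cols, pn))
  }
  for (nm in intersect(space$integer_params, pn))
    tab[[nm]] <- round(tab[[nm]])
  out <- cbind(design_id = seq_len(nrow(tab)), tab)
  attr(out, "param_cols") <- pn
  attr(out, "seeds_per_design") <- space$seeds_per_design
  attr(out, "scheme") <- space$scheme
  class(out) <- c("design_table", "data.frame")
  out
}

apply_design_row <- function(base, row) {
  pop <- base$population
  for (nm in c("aspect_ratio", "wall_thickness_um", "lumen_um", "flexibility",
               "mixture_weight"))
    if (nm %in% names(row)) pop[[nm]] <- if (nm == "flexibility")
      as.integer(row[[nm]]) else as.numeric(row[[nm]])
  cfg <- base
  cfg$population <- pop
  if ("target_layers" %in% names(row))
    cfg$target_layers <- as.numeric(row[["target_layers"]])
  cfg
}

measure_one <- function(cfg, depth_voxels) {
  st <- simulate_structure(cfg)
  met <- structure_metrics(st, depth_voxels = depth_voxels)
  ps <- met$pore_stats
  fw <- met$fiber_width_stats
  data.frame(surface_porosity = met$surface_porosity,
             bulk_porosity = met$bulk_porosity,
             pore_count = unname(ps["count"]), pore_mean = unname(ps["mean"]),
             pore_p5 = unname(ps["P5"]), pore_p95 = unname(ps["P95"]),
             pore_cv = unname(ps["cv"]),
             fw_min = if (is.null(fw)) NA_real_ else unname(fw["min"]),
             fw_max = if (is.null(fw)) NA_real_ else unname(fw["max"]),
             fw_mean = if (is.null(fw)) NA_real_ else unname(fw["mean"]))
}

#' Run a batch of simulations over a design table
#'
#' For every design row and replicate, derives a deterministic seed from the
#' master seed, simulates the structure, renders the top view and measures
#' the structure metrics.  Failures are logged and excluded rather than
#' fatal.  With an output directory the batch is resumable: completed
#' (design, replicate) rows found in `results.csv` are skipped on re-run.
#'
#' @param design a `design_table` from [generate_design()].
#' @param base a [sim_config()] supplying everything the design does not vary.
#' @param master_seed integer master seed.
#' @param reps replicates per design (default: the design's
#'   `seeds_per_design`).
#' @param out_dir optional directory for incremental `results.csv`.
#' @param depth_voxels top-view depth passed to [structure_metrics()].
#' @param quiet suppress progress messages.
#' @return a `data.frame` (class `results_table`): design parameters plus the
#'   measured metrics, one row per (design, replicate); failures in
#'   attribute `failures`.
#' @export
run_batch <- function(design, base = sim_config(), master_seed = 1L,
                      reps = NULL, out_dir = NULL, depth_voxels = NULL,
                      quiet = TRUE) {
  stopifnot(is.data.frame(design))
  if (is.null(reps)) reps <- attr(design, "seeds_per_design")
  if (is.null(reps)) reps <- 1L
  param_cols <- attr(design, "param_cols")
  if (is.null(param_cols)) param_cols <- setdiff(names(design), "design_id")
  csv <- NULL
  done <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (file.access(out_dir, 2) != 0)
      stop("output location not writable: ", out_dir, call. = FALSE)
    csv <- file.path(out_dir, "results.csv")
    if (file.exists(csv)) done <- read.csv(csv)
    schema <- c(design_id = "integer", replicate = "integer", seed = "integer",
                stats::setNames(rep("numeric", length(param_cols)), param_cols),
                surface_porosity = "numeric", bulk_porosity = "numeric",
                pore_count = "numeric", pore_mean = "numeric",
                pore_p5 = "numeric", pore_p95 = "numeric", pore_cv = "numeric",
                fw_min = "numeric", fw_max = "numeric", fw_mean = "numeric")
    jsonlite::write_json(as.list(schema),
                         file.path(out_dir, "results_schema.json"),
                         auto_unbox = TRUE)
  }
  rows <- list()
  failures <- list()
  for (i in seq_len(nrow(design))) {
    for (r in seq_len(reps)) {
      if (!is.null(done) &&
          any(done$design_id == design$design_id[i] & done$replicate == r)) next
      seed <- derive_seed(master_seed, "sim", i, r)
      cfg <- apply_design_row(base, design[i, , drop = FALSE])
      cfg$seed <- seed
      met <- tryCatch(measure_one(cfg, depth_voxels), error = function(e) e)
      if (inherits(met, "error")) {
        failures[[length(failures) + 1]] <-
          data.frame(design_id = design$design_id[i], replicate = r,
                     message = conditionMessage(met))
        next
      }
      row <- cbind(design_id = design$design_id[i], replicate = r, seed = seed,
                   design[i, param_cols, drop = FALSE], met)
      rownames(row) <- NULL
      rows[[length(rows) + 1]] <- row
      if (!is.null(csv))
        write.table(row, csv, sep = ",", col.names = !file.exists(csv),
                    row.names = FALSE, append = file.exists(csv))
      if (!quiet && (length(rows) %% 50 == 0))
        message(sprintf("run_batch: %d rows done", length(rows)))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    stop("no batch row succeeded", call. = FALSE)
  if (!is.null(done) && nrow(done) > 0) {
    done <- done[, names(out), drop = FALSE]
    out <- rbind(done, out[!(paste(out$design_id, out$replicate) %in%
                               paste(done$design_id, done$replicate)), ])
  }
  out <- out[order(out$design_id, out$replicate), ]
  rownames(out) <- NULL
  attr(out, "param_cols") <- param_cols
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures) else NULL
  class(out) <- c("results_table", "data.frame")
  out
}

#' Suitability criteria for pore structure
#'
#' A design is suitable when its pore-area distribution sits inside the
#' target window — P5 at or above the lower edge, P95 at or below the upper
#' edge (percentiles rather than absolute extremes, which are unstable at
#' small pore counts) — and, optionally, when its surface porosity lies in a
#' band.  Among suitable designs, lower pore-area CV means a more uniform
#' pore structure.
#'
#' @param pore_window_um2 `(lo, hi)` window in µm²; default `c(0.02, 120)`,
#'   the delivery-matrix target window.
#' @param porosity_band optional `(lo, hi)` surface-porosity fractions.
#' @return a `suitability_criteria` list.
#' @export
suitability_criteria <- function(pore_window_um2 = c(0.02, 120),
                                 porosity_band = NULL) {
  check_num(pore_window_um2, "pore_window_um2", len = 2L)
  if (pore_window_um2[1] >= pore_window_um2[2])
    stop_field("pore_window_um2", "need lo < hi")
  if (!is.null(porosity_band)) {
    check_num(porosity_band, "porosity_band", len = 2L, lower = 0, upper = 1)
    if (porosity_band[1] >= porosity_band[2])
      stop_field("porosity_band", "need lo < hi")
  }
  structure(list(pore_window_um2 = pore_window_um2,
                 porosity_band = porosity_band),
            class = "suitability_criteria")
}

#' Label result rows with the suitability rule
#'
#' @param results a `results_table`.
#' @param criteria a [suitability_criteria()].
#' @return `results` with a logical `suitable` column appended.
#' @export
label_suitability <- function(results, criteria = suitability_criteria()) {
  w <- criteria$pore_window_um2
  ok <- !is.na(results$pore_p5) & !is.na(results$pore_p95) &
    results$pore_p5 >= w[1] & results$pore_p95 <= w[2]
  if (!is.null(criteria$porosity_band))
    ok <- ok & results$surface_porosity >= criteria$porosity_band[1] &
      results$surface_porosity <= criteria$porosity_band[2]
  out <- results
  out$suitable <- ok
  attr(out, "param_cols") <- attr(results, "param_cols")
  class(out) <- class(results)
  out
}

aggregate_designs <- function(results) {
  param_cols <- attr(results, "param_cols")
  metric_cols <- c("surface_porosity", "bulk_porosity", "pore_count",
                   "pore_mean", "pore_p5", "pore_p95")
  sp <- split(results, results$design_id)
  agg <- do.call(rbind, lapply(sp, function(d) {
    out <- d[1, c("design_id", param_cols), drop = FALSE]
    for (mc in metric_cols) out[[mc]] <- mean(d[[mc]], na.rm = TRUE)
    # design-level CV pools pore areas across replicates (via per-replicate
    # moments), a lower-variance uniformity estimate than averaging CVs
    ok <- !is.na(d$pore_cv) & d$pore_count > 0
    out$pore_cv <- if (!any(ok)) NA_real_ else {
      n <- d$pore_count[ok]; m <- d$pore_mean[ok]
      s <- d$pore_cv[ok] * m
      N <- sum(n); M <- sum(n * m) / N
      ss <- sum(pmax(n - 1, 0) * s^2 + n * m^2)
      if (N < 2) 0 else sqrt(max(0, (ss - N * M^2) / (N - 1))) / M
    }
    out$sd_surface_porosity <- if (nrow(d) > 1) sd(d$surface_porosity) else 0
    out$n_reps <- nrow(d)
    out
  }))
  rownames(agg) <- NULL
  attr(agg, "param_cols") <- param_cols
  agg
}

#' Select the optimum design from a labelled sweep
#'
#' Averages replicates per design, keeps designs whose aggregated pore P5/P95
#' fall inside the suitability window (and porosity band, if set), and picks
#' the one with minimal pore-area CV — the most uniform pore structure.
#' Ties are broken by surface porosity closest to the suitable-set median,
#' then by lowest design index, so the selection is reproducible and
#' invariant to row order.
#'
#' @param results a `results_table` (labelled or not).
#' @param criteria a [suitability_criteria()].
#' @return an `optimum_report` list: `design_id`, `params`,
#'   `mean_surface_porosity`, `sd_surface_porosity`, `pore_p5`, `pore_p95`,
#'   `pore_cv`, `n_suitable`, `n_designs`, and the aggregated table.
#' @export
select_optimum <- function(results, criteria = suitability_criteria()) {
  agg <- aggregate_designs(results)
  w <- criteria$pore_window_um2
  ok <- !is.na(agg$pore_p5) & !is.na(agg$pore_p95) &
    agg$pore_p5 >= w[1] & agg$pore_p95 <= w[2]
  if (!is.null(criteria$porosity_band))
    ok <- ok & agg$surface_porosity >= criteria$porosity_band[1] &
      agg$surface_porosity <= criteria$porosity_band[2]
  if (!any(ok))
    stop("no design satisfies the suitability window; widen the design space",
         call. = FALSE)
  suit <- agg[ok, , drop = FALSE]
  med <- median(suit$surface_porosity)
  o <- order(suit$pore_cv, abs(suit$surface_porosity - med), suit$design_id)
  best <- suit[o[1], , drop = FALSE]
  param_cols <- attr(agg, "param_cols")
  out <- list(design_id = best$design_id,
              params = as.list(best[1, param_cols, drop = FALSE]),
              mean_surface_porosity = best$surface_porosity,
              sd_surface_porosity = best$sd_surface_porosity,
              pore_p5 = best$pore_p5, pore_p95 = best$pore_p95,
              pore_cv = best$pore_cv,
              n_suitable = nrow(suit), n_designs = nrow(agg),
              criteria = criteria, aggregated = agg)
  class(out) <- "optimum_report"
  out
}

#' @export
print.optimum_report <- function(x, ...) {
  cat(sprintf(paste0("<optimum_report> design %d: surface porosity %.1f%% ",
                     "(sd %.1f pp), pore P5 %.3g / P95 %.3g um^2, CV %.2f\n"),
              x$design_id, 100 * x$mean_surface_porosity,
              100 * x$sd_surface_porosity, x$pore_p5, x$pore_p95, x$pore_cv))
  cat(sprintf("  suitable designs: %d of %d\n", x$n_suitable, x$n_designs))
  for (nm in names(x$params))
    cat(sprintf("  %s = %.4g\n", nm, as.numeric(x$params[[nm]])))
  invisible(x)
}
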