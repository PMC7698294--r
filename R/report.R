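#' Run a full design-space exploration
#'
#' Wires the sweep stages: design generation, batch simulation and
#' measurement, regression/classification trees, and optimum selection.
#' All artifacts (results CSV, optimum JSON, tree JSON/DOT, manifest) are
#' written under `out_dir` when given.
#'
#' @param space a [design_space()].
#' @param base a [sim_config()].
#' @param master_seed integer master seed.
#' @param criteria a [suitability_criteria()].
#' @param out_dir optional output directory.
#' @param depth_voxels top-view depth (NULL = default).
#' @param quiet suppress progress.
#' @return list: `design`, `results`, `labeled`, `reg_tree`, `cls`,
#'   `optimum` (or `NULL` with `optimum_error` when no design is suitable).
#' @export
explore <- function(space = default_design_space(), base = sim_config(),
                    master_seed = 1L, criteria = suitability_criteria(),
                    out_dir = NULL, depth_voxels = NULL, quiet = TRUE) {
  design <- generate_design(space, seed = derive_seed(master_seed, "design"))
  results <- run_batch(design, base, master_seed = master_seed,
                       out_dir = out_dir, depth_voxels = depth_voxels,
                       quiet = quiet)
  min_leaf <- max(2L, min(5L, nrow(results) %/% 4L))
  reg_tree <- tryCatch(
    fit_regression_tree(results, "surface_porosity", min_leaf = min_leaf),
    error = function(e) NULL)
  cls <- tryCatch(
    suppressWarnings(label_and_fit_decision_tree(results, criteria,
                                                 min_leaf = min_leaf)),
    error = function(e) NULL)
  labeled <- if (!is.null(cls)) cls$labeled else label_suitability(results, criteria)
  optimum <- tryCatch(select_optimum(labeled, criteria),
                      error = function(e) e)
  optimum_error <- NULL
  if (inherits(optimum, "error")) {
    optimum_error <- conditionMessage(optimum)
    optimum <- NULL
  }
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(reg_tree)) {
      export_tree(reg_tree, file.path(out_dir, "regression_tree.json"))
      export_tree(reg_tree, file.path(out_dir, "regression_tree.dot"))
    }
    if (!is.null(cls)) {
      export_tree(cls$tree, file.path(out_dir, "decision_tree.json"))
      export_tree(cls$tree, file.path(out_dir, "decision_tree.dot"))
    }
    opt_json <- if (!is.null(optimum)) {
      o <- optimum[c("design_id", "params", "mean_surface_porosity",
                     "sd_surface_porosity", "pore_p5", "pore_p95", "pore_cv",
                     "n_suitable", "n_designs")]
      o$params <- lapply(o$params, as.numeric)
      o
    } else list(error = optimum_error)
    jsonlite::write_json(opt_json, file.path(out_dir, "optimum.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(out_dir, stage = "explore", seed = master_seed,
                   config = list(n_designs = space$n_designs,
                                 seeds_per_design = space$seeds_per_design,
                                 scheme = space$scheme))
  }
  list(design = design, results = results, labeled = labeled,
       reg_tree = reg_tree, cls = cls, optimum = optimum,
       optimum_error = optimum_error)
}

#' Write a run manifest
#'
#' Records tool version, config echo, master seed, timestamps and an md5
#' content hash of every file in the output directory — the provenance
#' record for a pipeline stage.
#'
#' @param out_dir directory whose contents are hashed.
#' @param stage stage name.
#' @param seed master seed used.
#' @param config config echo (any list).
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(out_dir, stage, seed, config = list()) {
  files <- setdiff(list.files(out_dir, recursive = TRUE), "manifest.json")
  hashes <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(hashes) <- files
  manifest <- list(tool = "fibermat",
                   version = as.character(utils::packageVersion("fibermat")),
                   stage = stage, master_seed = seed, config = config,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   files = hashes)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

open_device <- function(path, width = 800, height = 500) {
  if (capabilities("png")) {
    grDevices::png(path, width = width, height = height)
    path
  } else {
    # headless fallback: keep the figure, switch container format
    pdf_path <- sub("\\.png$", ".pdf", path)
    grDevices::pdf(pdf_path, width = width / 100, height = height / 100)
    pdf_path
  }
}

#' Render a report bundle for a finished sweep
#'
#' Reads `results.csv` and `optimum.json` from a sweep directory and writes
#' a Markdown report with a porosity histogram, the pore-area distribution
#' (log scale), tree renderings and the optimum summary; figures as PNG.
#' An empty suitable set is reported explicitly rather than failing.
#'
#' @param sweep_dir directory produced by [explore()] / [run_batch()].
#' @param out_dir report destination (default: the sweep directory).
#' @return path of the written `report.md`, invisibly.
#' @export
report <- function(sweep_dir, out_dir = sweep_dir) {
  csv <- file.path(sweep_dir, "results.csv")
  opt <- file.path(sweep_dir, "optimum.json")
  for (f in c(csv, opt))
    if (!file.exists(f))
      stop("missing sweep artifact: ", f, call. = FALSE)
  results <- read.csv(csv)
  optimum <- jsonlite::read_json(opt, simplifyVector = TRUE)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  fig1 <- open_device(file.path(out_dir, "porosity_hist.png"))
  graphics::hist(100 * results$surface_porosity, breaks = 30,
                 main = "Surface porosity across the sweep",
                 xlab = "surface porosity (%)", col = "grey80")
  grDevices::dev.off()
  fig2 <- open_device(file.path(out_dir, "pore_area_hist.png"))
  pa <- results$pore_mean[is.finite(results$pore_mean) & results$pore_mean > 0]
  if (length(pa)) {
    graphics::hist(log10(pa), breaks = 30,
                   main = "Mean pore area per structure",
                   xlab = "log10 pore area (um^2)", col = "grey80")
  } else graphics::plot.new()
  grDevices::dev.off()

  tree_txt <- character(0)
  for (tf in c("regression_tree.dot", "decision_tree.dot")) {
    p <- file.path(sweep_dir, tf)
    if (file.exists(p))
      tree_txt <- c(tree_txt, sprintf("### %s", tf), "```dot",
                    readLines(p), "```", "")
  }
  opt_txt <- if (!is.null(optimum$error)) {
    c("**No suitable design was found.**",
      sprintf("Reason: %s", optimum$error))
  } else {
    c(sprintf("Selected design %s:", optimum$design_id),
      sprintf("- mean surface porosity: %.1f%%",
              100 * optimum$mean_surface_porosity),
      sprintf("- pore P5 / P95: %.3g / %.3g um^2", optimum$pore_p5,
              optimum$pore_p95),
      sprintf("- pore-area CV: %.2f", optimum$pore_cv),
      sprintf("- suitable designs: %s of %s", optimum$n_suitable,
              optimum$n_designs),
      "",
      "Parameters:",
      vapply(names(optimum$params), function(nm)
        sprintf("- %s = %.4g", nm, as.numeric(optimum$params[[nm]])),
        character(1)))
  }
  md <- c("# Fiber-matrix design sweep report", "",
          sprintf("Rows: %d structures over %d designs.", nrow(results),
                  length(unique(results$design_id))), "",
          "## Porosity distribution", "",
          sprintf("![porosity](%s)", basename(fig1)), "",
          "## Pore-area distribution (log scale)", "",
          sprintf("![pore areas](%s)", basename(fig2)), "",
          "## Optimum", "", opt_txt, "",
          "## Trees", "", tree_txt)
  out <- file.path(out_dir, "report.md")
  writeLines(md, out)
  write_manifest(out_dir, stage = "report", seed = NA,
                 config = list(sweep_dir = sweep_dir))
  invisible(out)
}
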