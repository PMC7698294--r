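#' Read a configuration file
#'
#' YAML (`.yaml`/`.yml`, via the yaml package) or JSON configs whose keys
#' mirror the constructor arguments of [sim_config()],
#' [fiber_population_spec()] and [design_space()].
#'
#' @param path config file path.
#' @return a named list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required for YAML configs")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: ", ext, call. = FALSE)
}

#' @keywords internal
sim_config_from_list <- function(lst) {
  pop_lst <- lst$population
  pop <- if (is.null(pop_lst)) fiber_population_spec() else {
    pop_lst$width_range_um <- as.numeric(unlist(pop_lst$width_range_um))
    do.call(fiber_population_spec, pop_lst)
  }
  args <- lst[setdiff(names(lst), c("population", "depth_voxels", "n_seeds"))]
  args$population <- pop
  if (!is.null(args$domain_px)) args$domain_px <- as.integer(unlist(args$domain_px))
  do.call(sim_config, args)
}

design_space_from_list <- function(lst) {
  params <- lapply(lst$params, function(p) {
    if (is.list(p) && !is.null(p$levels)) list(levels = unlist(p$levels))
    else as.numeric(unlist(p))
  })
  args <- list(params = params)
  for (nm in c("scheme", "n_designs", "seeds_per_design", "integer_params"))
    if (!is.null(lst[[nm]])) args[[nm]] <- lst[[nm]]
  do.call(design_space, args)
}

#' The committed calibration configuration
#'
#' Loads the repository's calibration config: the fiber population matched
#' to the measured micro/nano width range (log-uniform over 0.0685–9.8 µm)
#' and the layer / flexibility / top-view-depth settings calibrated once so
#' that simulated top-view surface porosity reproduces the measured
#' computational porosity (see the methods vignette).  Used by the
#' acceptance script and available to users as a validated starting point.
#'
#' @param path config path; default the copy installed with the package.
#' @return list with `config` (a [sim_config()]), `depth_voxels`, `n_seeds`.
#' @export
calibration_config <- function(path = system.file("extdata",
                                                  "calibration_micro.yaml",
                                                  package = "fibermat")) {
  lst <- load_config(path)
  list(config = sim_config_from_list(lst),
       depth_voxels = if (is.null(lst$depth_voxels)) NULL else lst$depth_voxels,
       n_seeds = if (is.null(lst$n_seeds)) 20L else as.integer(lst$n_seeds))
}

#' Mean calibrated surface porosity over replicate seeds
#'
#' Runs the committed calibration config for `n_seeds` seeds derived from a
#' master seed, measures top-view surface porosity per run, and returns the
#' replicate values and their mean.  This is the quantity compared against
#' measured computational porosities.
#'
#' @param master_seed integer master seed.
#' @param n_seeds number of replicate structures (default from the config).
#' @param calib result of [calibration_config()].
#' @return list with `porosities` (per-seed fractions) and `mean_porosity`.
#' @export
calibrated_porosity <- function(master_seed = 1L, n_seeds = NULL,
                                calib = calibration_config()) {
  if (is.null(n_seeds)) n_seeds <- calib$n_seeds
  p <- vapply(seq_len(n_seeds), function(k) {
    cfg <- calib$config
    cfg$seed <- derive_seed(master_seed, "calibration", k)
    st <- simulate_structure(cfg)
    surface_porosity(render_top_view(st, calib$depth_voxels))
  }, numeric(1))
  list(porosities = p, mean_porosity = mean(p))
}
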