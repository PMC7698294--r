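tiny_space <- function(n = 20, reps = 1) design_space(
  params = list(aspect_ratio = c(5, 10), target_layers = c(1, 2)),
  n_designs = n, seeds_per_design = reps)

tiny_base <- sim_config(domain_px = c(32, 32), target_layers = 1,
                        population = fiber_population_spec(c(1, 3),
                                                           aspect_ratio = 6))

test_that("generate_design: factorial combinatorics and determinism", {
  sp <- design_space(params = list(a = list(levels = c(1, 2, 3)),
                                   b = list(levels = c(10, 20, 30))),
                     scheme = "full-factorial")
  d <- generate_design(sp, seed = 1)
  expect_equal(nrow(d), 9)
  expect_equal(sort(unique(d$a)), c(1, 2, 3))
  d2 <- generate_design(tiny_space(), seed = 5)
  d3 <- generate_design(tiny_space(), seed = 5)
  expect_identical(d2, d3)
  big <- design_space(params = list(a = list(levels = 1:400),
                                    b = list(levels = 1:400)),
                      scheme = "full-factorial")
  expect_error(generate_design(big, 1), "latin-hypercube")
})

test_that("latin hypercube stratifies every marginal", {
  sp <- design_space(params = list(x = c(0, 1)), n_designs = 50,
                     integer_params = character(0))
  d <- generate_design(sp, seed = 3)
  expect_equal(nrow(d), 50)
  strata <- floor(d$x * 50)
  expect_equal(sort(strata), 0:49)   # exactly one sample per stratum
})

test_that("run_batch produces one row per design x replicate and is deterministic", {
  des <- generate_design(tiny_space(5, 2), seed = 2)
  r1 <- run_batch(des, tiny_base, master_seed = 9, reps = 2)
  expect_equal(nrow(r1), 10)
  expect_false(any(is.na(r1$surface_porosity)))
  r2 <- run_batch(des, tiny_base, master_seed = 9, reps = 2)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
})

test_that("run_batch is resumable from its results.csv", {
  des <- generate_design(tiny_space(4, 1), seed = 2)
  out <- tempfile("sweep")
  r1 <- run_batch(des[1:2, ], tiny_base, master_seed = 9, reps = 1,
                  out_dir = out)
  r2 <- run_batch(des, tiny_base, master_seed = 9, reps = 1, out_dir = out)
  expect_equal(nrow(r2), 4)
  # previously computed rows identical to a fresh full run
  full <- run_batch(des, tiny_base, master_seed = 9, reps = 1)
  expect_equal(r2$surface_porosity, full$surface_porosity)
  unlink(out, recursive = TRUE)
})

test_that("doubling layers raises mean bulk porosity (paired designs)", {
  # bridging-dominated regime: more coverage traps more voids (see the
  # deposition monotonicity tests)
  des <- data.frame(design_id = 1:2, target_layers = c(1, 2))
  attr(des, "param_cols") <- "target_layers"
  res <- run_batch(des, tiny_base, master_seed = 4, reps = 10)
  agg <- tapply(res$bulk_porosity, res$design_id, mean)
  expect_lte(agg[["1"]], agg[["2"]])
})

test_that("suitability labelling applies the pore window", {
  res <- data.frame(design_id = 1:3, replicate = 1,
                    surface_porosity = c(0.3, 0.4, 0.5),
                    pore_p5 = c(0.03, 0.01, 0.05),
                    pore_p95 = c(100, 50, 494))
  lab <- label_suitability(res, suitability_criteria(c(0.02, 120)))
  # row 1 inside window; row 2 fails P5; row 3 has the unoptimized matrix's
  # 494 um^2 upper extreme, outside the optimum window
  expect_equal(lab$suitable, c(TRUE, FALSE, FALSE))
  band <- suitability_criteria(c(0.02, 120), porosity_band = c(0.35, 0.45))
  expect_equal(label_suitability(res, band)$suitable, c(FALSE, FALSE, FALSE))
  expect_error(suitability_criteria(c(5, 2)), "pore_window")
})

test_that("select_optimum picks minimal CV with documented tie-breaks", {
  mk <- function(id, cv, porosity) data.frame(
    design_id = id, replicate = 1:2, x = id,
    surface_porosity = porosity, bulk_porosity = 0.5,
    pore_count = 10, pore_mean = 10, pore_p5 = 1, pore_p95 = 50,
    pore_cv = cv, fw_min = 1, fw_max = 2, fw_mean = 1.5)
  res <- rbind(mk(1, 0.9, 0.40), mk(2, 0.4, 0.30), mk(3, 0.4, 0.35))
  attr(res, "param_cols") <- "x"
  opt <- select_optimum(res)
  # designs 2 and 3 tie on CV; 3 is closer to the suitable-set median porosity
  expect_equal(opt$design_id, 3)
  expect_equal(opt$n_suitable, 3)
  # permutation invariance
  perm <- res[sample(nrow(res)), ]
  attr(perm, "param_cols") <- "x"
  expect_equal(select_optimum(perm)$design_id, 3)
  # single suitable design is returned
  one <- mk(7, 1.2, 0.2)
  attr(one, "param_cols") <- "x"
  expect_equal(select_optimum(one)$design_id, 7)
  # empty suitable set errors
  bad <- mk(1, 0.5, 0.4); bad$pore_p95 <- 500
  attr(bad, "param_cols") <- "x"
  expect_error(select_optimum(bad), "widen")
})

test_that("scaled sweep produces a non-degenerate suitable set", {
  # desk-scale smoke: a reduced sweep over the default space still yields
  # some suitable and some unsuitable designs
  sp <- default_design_space(n_designs = 24, seeds_per_design = 1)
  des <- generate_design(sp, seed = 8)
  base <- sim_config(domain_px = c(128, 128), resolution_um_per_voxel = 0.1,
                     population = fiber_population_spec(c(0.0685, 9.8),
                                                        width_law = "two-mode"))
  res <- run_batch(des, base, master_seed = 8, depth_voxels = 512)
  lab <- label_suitability(res)
  expect_gt(sum(lab$suitable), 0)
  expect_lt(sum(lab$suitable), nrow(lab))
})
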