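test_that("sample_fiber_population respects range, determinism and length law", {
  spec <- fiber_population_spec(c(0.0685, 9.8), aspect_ratio = 20)
  pop <- sample_fiber_population(spec, 1000, seed = 42)
  expect_equal(nrow(pop), 1000)
  expect_true(all(pop$width_um >= 0.0685 & pop$width_um <= 9.8))
  expect_equal(pop$length_um, 20 * pop$width_um)
  pop2 <- sample_fiber_population(spec, 1000, seed = 42)
  expect_identical(pop, pop2)
  # degenerate range
  mono <- sample_fiber_population(fiber_population_spec(c(2, 2)), 5, seed = 1)
  expect_equal(mono$width_um, rep(2, 5))
})

test_that("log-uniform width law has the closed-form median", {
  # median of exp(U[log a, log b]) is sqrt(a b) = 1.0 for (0.1, 10)
  spec <- fiber_population_spec(c(0.1, 10))
  w <- sample_fiber_population(spec, 1e4, seed = 7)$width_um
  # se of the sample median ~ 1/(2 f(m) sqrt(n)); f(m) = 1/(m log(b/a))
  se <- median(w) * log(10 / 0.1) / (2 * sqrt(1e4))
  expect_lt(abs(median(w) - 1.0), 3 * se)
})

test_that("width laws stay in range and the two-mode mixture spans both modes", {
  for (law in c("log-normal", "two-mode")) {
    spec <- fiber_population_spec(c(0.0685, 9.8), width_law = law)
    w <- sample_fiber_population(spec, 2000, seed = 3)$width_um
    expect_true(all(w >= 0.0685 & w <= 9.8), info = law)
  }
  spec <- fiber_population_spec(c(0.0685, 9.8), width_law = "two-mode",
                                mixture_weight = 0.5)
  w <- sample_fiber_population(spec, 2000, seed = 3)$width_um
  mid <- sqrt(0.0685 * 9.8)
  expect_gt(mean(w < mid), 0.4)
  expect_lt(mean(w < mid), 0.6)
})

test_that("invalid population specs name the offending field", {
  expect_error(fiber_population_spec(c(-1, 2)), "width_range_um")
  expect_error(fiber_population_spec(c(3, 2)), "width_range_um")
  expect_error(fiber_population_spec(aspect_ratio = 0.5), "aspect_ratio")
  expect_error(fiber_population_spec(wall_thickness_um = 0), "wall_thickness_um")
  expect_error(fiber_population_spec(flexibility = 1.5), "flexibility")
  expect_error(fiber_population_spec(mixture_weight = 2), "mixture_weight")
})

test_that("make_phantom_binary counts ground truth exactly", {
  sq <- phantom_spec(c(100, 100), 1,
                     pores = data.frame(shape = "rectangle", x_um = 50,
                                        y_um = 50, size1_um = 5, size2_um = 5))
  ph <- make_phantom_binary(sq)
  expect_equal(ph$truth$true_porosity, 0.0025)
  expect_equal(ph$truth$true_pore_areas_um2, 25)
  expect_equal(sum(ph$image == 0), 25)

  # all-void: one pore covering the whole frame
  allv <- make_phantom_binary(phantom_spec(c(20, 30), 0.5,
    pores = data.frame(shape = "rectangle", x_um = 5, y_um = 7.5,
                       size1_um = 10, size2_um = 15)))
  expect_equal(allv$truth$true_porosity, 1.0)
  expect_equal(allv$truth$true_pore_areas_um2, 20 * 30 * 0.25)
})

test_that("random disc phantoms match the brute-force pixel count", {
  spec <- random_disc_phantom(c(128, 128), 1, n = 20, r_range_um = c(2, 5),
                              seed = 9)
  ph <- make_phantom_binary(spec)
  void <- sum(unclass(ph$image) == 0)
  expect_equal(ph$truth$true_porosity, void / (128 * 128))
  expect_equal(sum(ph$truth$true_pore_areas_um2), void)
  # pores are distinct components: count with the independent flood fill
  comp <- oracle_flood_areas(matrix(ph$image == 0, 128, 128), 8)
  expect_equal(length(comp), 20)
  expect_equal(sort(comp), sort(ph$truth$true_pore_areas_um2))
})

test_that("overlapping pores error unless allowed", {
  pores <- data.frame(shape = "disc", x_um = c(50, 52), y_um = c(50, 52),
                      size1_um = c(5, 5))
  spec <- phantom_spec(c(100, 100), 1, pores = pores)
  expect_error(make_phantom_binary(spec), "overlap")
  spec2 <- phantom_spec(c(100, 100), 1, pores = pores, allow_overlap = TRUE)
  expect_silent(make_phantom_binary(spec2))
  expect_error(phantom_spec(c(100, 100), 1,
    pores = data.frame(shape = "disc", x_um = 2, y_um = 50, size1_um = 5)),
    "inside the image")
})

test_that("render_sem_like: identity, determinism and mean preservation", {
  ph <- make_phantom_binary(random_disc_phantom(c(64, 64), 1, n = 5,
                                                r_range_um = c(3, 6), seed = 2))
  # blur 0, noise 0 -> exact cast
  g0 <- render_sem_like(ph$image, 0, 0)
  expect_equal(matrix(as.numeric(g0), 64, 64),
               matrix(as.numeric(unclass(ph$image)), 64, 64))
  # fixed seed -> identical bytes
  g1 <- render_sem_like(ph$image, 1.5, 0.05, seed = 11)
  g2 <- render_sem_like(ph$image, 1.5, 0.05, seed = 11)
  expect_identical(g1, g2)
  # blur only: mean intensity = solid fraction within edge effects
  g3 <- render_sem_like(ph$image, 2, 0)
  expect_lt(abs(mean(g3) - (1 - ph$truth$true_porosity)), 0.02)
  # solid brighter than pores on average
  expect_gt(mean(g1[unclass(ph$image) == 1]), mean(g1[unclass(ph$image) == 0]))
})

test_that("binarize(render_sem_like(b, 0, 0)) round-trips exactly", {
  for (seed in 1:5) {
    b <- binary_image(random_binary(32, 32, 0.6, seed), 0.5)
    g <- render_sem_like(b, 0, 0)
    back <- binarize(g, segmentation_config(despeckle_min_px = 0))
    expect_equal(matrix(as.integer(back), 32, 32), matrix(as.integer(b), 32, 32))
  }
})

test_that("image round trip through PGM and PNG preserves binary content", {
  b <- binary_image(random_binary(24, 31, 0.5, 4), 0.25)
  for (ext in c("pgm", "png")) {
    if (ext == "png") skip_if_not_installed("png")
    f <- tempfile(fileext = paste0(".", ext))
    write_image(b, f)
    back <- read_image(f, 0.25)
    expect_equal(dim(back), dim(b))
    expect_equal(matrix(as.integer(back > 0.5), 24, 31),
                 matrix(as.integer(b), 24, 31), info = ext)
    unlink(f)
  }
})
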