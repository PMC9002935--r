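test_that("an un-noised synthetic seed reproduces its model", {
  s <- generate_seed("DM3", eps = 0, rot_deg = c(0, 0),
                     scale_range = c(1, 1), shift_px = c(0, 0),
                     rng_seed = 1)
  j <- suppressWarnings(jfit(s, models = "DM3"))$fits$J
  expect_gte(j, 99)
})

test_that("generation is bit-reproducible and order-independent", {
  a <- generate_seed("DM7", eps = 0.02, rng_seed = 99)
  b <- generate_seed("DM7", eps = 0.02, rng_seed = 99)
  expect_identical(unclass(a), unclass(b))
  p3 <- generate_population("DM7", 3, eps = 0.02, rng_seed = 7,
                            height_px = 80)
  p5 <- generate_population("DM7", 5, eps = 0.02, rng_seed = 7,
                            height_px = 80)
  expect_identical(p3$masks[[2]], p5$masks[[2]])
})

test_that("population ground truth matches the masks produced", {
  p <- generate_population("DM9", 1, eps = 0.02, rng_seed = 4)
  expect_identical(nrow(p$truth), 1L)
  expect_identical(p$truth$model_id, "DM9")
  tr <- attr(p$masks[[1]], "truth")
  expect_identical(tr$rotation, p$truth$rotation)
})

test_that("generated populations inherit the model's convexity class", {
  pc <- generate_population("DM1", 20, eps = 0.02, rng_seed = 31,
                            height_px = 120)
  labc <- vapply(pc$masks, function(m) classify_convexity(m)$label, "")
  expect_true(all(labc == "convex"))
  pn <- generate_population("DM9", 20, eps = 0.02, rng_seed = 32,
                            height_px = 120)
  labn <- vapply(pn$masks, function(m) classify_convexity(m)$label, "")
  expect_true(all(labn == "nonconvex"))
})

test_that("mean J against the generator decays with noise amplitude", {
  eps_levels <- c(0, 0.01, 0.02, 0.05)
  mj <- vapply(eps_levels, function(e) {
    p <- generate_population("DM7", 12, eps = e, rng_seed = 55,
                             height_px = 90)
    mean(vapply(p$masks, function(m)
      suppressWarnings(jfit(m, models = "DM7"))$fits$J, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mj) < 0))
})

test_that("colliculae bumps lower circularity but spare roundness", {
  smooth <- generate_seed("DM2", eps = 0, rot_deg = c(0, 0),
                          scale_range = c(1, 1), shift_px = c(0, 0),
                          height_px = 200, rng_seed = 8)
  bumpy <- generate_seed("DM2", eps = 0, rot_deg = c(0, 0),
                         scale_range = c(1, 1), shift_px = c(0, 0),
                         colliculae = 10, colliculae_amp = 0.02,
                         height_px = 200, rng_seed = 8)
  a <- measure_mask(smooth, 0.01)
  b <- measure_mask(bumpy, 0.01)
  expect_lt(b$C, a$C)
  expect_lt(abs(b$R - a$R) / a$R, 0.02)
})

test_that("an overly violent perturbation is damped, not fatal", {
  expect_message(
    s <- generate_seed("DM8", eps = 0.9, height_px = 80, rng_seed = 2),
    "damping")
  expect_identical(seedshape:::n_components(s), 1L)
  expect_lt(attr(s, "truth")$eps, 0.9)
})

test_that("plates compose and segment back to the input seeds", {
  p <- generate_population("DM5", 20, eps = 0.02, rng_seed = 77,
                           height_px = 70)
  img <- generate_plate(p$masks, ncol_grid = 5, rng_seed = 78)
  bin <- read_and_binarize(img, mode = "otsu", polarity = "dark_seeds")
  seg <- segment_plate(bin$mask, min_area_px = 200)
  expect_identical(length(seg$masks), 20L)
  # with the ruler artifact, border exclusion still recovers exactly 20
  img2 <- generate_plate(p$masks, ncol_grid = 5, ruler = TRUE, rng_seed = 79)
  bin2 <- read_and_binarize(img2, mode = "otsu", polarity = "dark_seeds")
  seg2 <- segment_plate(bin2$mask, min_area_px = 200, exclude_border = TRUE)
  expect_identical(length(seg2$masks), 20L)
  expect_error(generate_plate(list()), "at least one")
})
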