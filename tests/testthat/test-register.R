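test_that("jaccard_percent implements S/T x 100 with its edge contract", {
  a <- disk_mask(30)
  expect_identical(jaccard_percent(a, a), 100)
  b <- matrix(FALSE, nrow(a), ncol(a)); b[1:3, 1:3] <- TRUE
  expect_identical(jaccard_percent(a, b), 0)
  expect_error(jaccard_percent(a, matrix(FALSE, 5, 5)), "grid")
  z <- matrix(FALSE, 10, 10)
  expect_error(jaccard_percent(z, z), "empty")
  # symmetry over assorted mask pairs
  set.seed(42)
  for (k in 1:5) {
    a <- disk_mask(20, center_off = sample(-5:5, 2))
    b <- disk_mask(20, center_off = sample(-5:5, 2))
    expect_identical(jaccard_percent(a, b), jaccard_percent(b, a))
  }
})

test_that("the warp kernel matches analytic transforms of simple shapes", {
  # scale + translate a disk -> disk with scaled radius at the target
  d <- disk_mask(40, pad = 60)
  mo <- seedshape:::mask_moments(d)
  w <- seedshape:::warp_mask_cpp(d * 1, nrow(d), ncol(d), mo$cx, mo$cy,
                                 mo$cx + 15, mo$cy - 10, 1.5, 0, FALSE)
  ref <- disk_mask(60, pad = 40, center_off = c(-10, 15))
  expect_lt(sum(xor(w, ref)) / sum(ref), 0.02)
  # 90-degree rotation of a rectangle is exact up to the 1-px rim
  r <- matrix(FALSE, 121, 121); r[46:76, 21:101] <- TRUE
  mo <- seedshape:::mask_moments(r)
  w <- seedshape:::warp_mask_cpp(r * 1, 121, 121, mo$cx, mo$cy,
                                 mo$cx, mo$cy, 1, pi / 2, FALSE)
  expect_lt(sum(xor(w, t(r))) / sum(r), 0.02)
})

test_that("initial_alignment recovers known ground-truth transforms", {
  m <- rasterize_model("DM6", 100, margin_px = 40)
  mo <- seedshape:::mask_moments(m)
  tr <- initial_alignment(m, m)
  expect_lt(abs(tr$tx - mo$cx), 0.5)
  expect_lt(abs(tr$ty - mo$cy), 0.5)
  expect_lt(abs(tr$s - 1), 0.005)
  expect_lt(abs(tr$phi) %% pi, pi / 180)
  # pure translation
  sh <- shift_mask(m, -12, 30)
  tr <- initial_alignment(sh, m)
  expect_lt(abs(tr$tx - (mo$cx + 30)), 0.5)
  expect_lt(abs(tr$ty - (mo$cy - 12)), 0.5)
  # scale by 1.5 (reference raster at 1.5x the height)
  big <- rasterize_model("DM6", 150, margin_px = 20)
  tr <- initial_alignment(big, m)
  expect_lt(abs(tr$s - 1.5), 0.015)
})

test_that("refinement never falls below the initializer", {
  for (id in c("DM2", "DM8")) {
    s <- generate_seed(id, eps = 0.03, height_px = 90, rng_seed = 11)
    j0 <- suppressWarnings(jfit(s, models = id, refine = FALSE))$fits$J
    j1 <- suppressWarnings(jfit(s, models = id))$fits$J
    expect_gte(j1, j0)
  }
})

test_that("fitting is invariant under a rigid motion of the seed", {
  s <- generate_seed("DM6", eps = 0.02, height_px = 120, rng_seed = 3,
                     margin_px = 25)
  j0 <- suppressWarnings(jfit(s, models = "DM6"))$fits$J
  moved <- shift_mask(s, 7, -9)
  j1 <- suppressWarnings(jfit(moved, models = "DM6"))$fits$J
  expect_lt(abs(j1 - j0), 0.5)
  rot <- warp_on_canvas(s, phi = 33 * pi / 180)
  j2 <- suppressWarnings(jfit(rot, models = "DM6"))$fits$J
  expect_lt(abs(j2 - j0), 0.5)
})

test_that("the fit table is ordered, subsettable and order-independent", {
  s <- rasterize_model("DM5", 70, margin_px = 6)
  f1 <- suppressWarnings(jfit(s, models = c("DM7", "DM5")))
  expect_identical(f1$fits$model, c("DM5", "DM7"))
  f2 <- suppressWarnings(jfit(s, models = c("DM5", "DM7")))
  expect_equal(f1$fits, f2$fits)
  f3 <- suppressWarnings(jfit(s, models = "DM5"))
  expect_identical(nrow(f3$fits), 1L)
  expect_identical(f3$best_model, "DM5")
  expect_error(jfit(s, models = character(0)))
})

test_that("coef, summary and warped_model expose the fitted transform", {
  s <- rasterize_model("DM3", 80, margin_px = 8)
  f <- suppressWarnings(jfit(s, models = c("DM1", "DM3")))
  expect_identical(f$best_model, "DM3")
  co <- coef(f)
  expect_named(co, c("tx", "ty", "s", "phi", "flip"))
  sm <- summary(f)
  expect_true(sm$good)
  w <- warped_model(f)
  expect_identical(dim(w), dim(s))
  expect_equal(jaccard_percent(w, s), f$fits$J[f$fits$model == "DM3"],
               tolerance = 1e-9)
})
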