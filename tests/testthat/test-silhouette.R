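test_that("pose standardization is stable and rotation-invariant", {
  e <- ellipse_mask(40, 80)  # major axis already vertical
  a <- align_mask(e)
  ja <- jaccard_percent(seedshape:::pad_mask(seedshape:::crop_mask(e), 201, 201),
                        seedshape:::pad_mask(a, 201, 201))
  expect_gt(ja, 97)
  rot <- warp_on_canvas(e, phi = 37 * pi / 180)
  b <- align_mask(rot)
  nr <- max(nrow(a), nrow(b)); ncl <- max(ncol(a), ncol(b))
  d <- sum(xor(seedshape:::pad_mask(a, nr, ncl),
               seedshape:::pad_mask(b, nr, ncl)))
  expect_lt(d / sum(a), 0.02)
})

test_that("mirror-image seeds align to one canonical pose", {
  s <- generate_seed("DM4", eps = 0.03, height_px = 90, rng_seed = 5)
  mir <- s[, ncol(s):1]
  a <- align_mask(s); b <- align_mask(mir)
  nr <- max(nrow(a), nrow(b)); ncl <- max(ncol(a), ncol(b))
  d <- sum(xor(seedshape:::pad_mask(a, nr, ncl),
               seedshape:::pad_mask(b, nr, ncl)))
  expect_lt(d / sum(a), 0.02)
})

test_that("identical masks average to themselves for any tau", {
  m <- rasterize_model("DM2", 80, margin_px = 6)
  for (tau in c(0.2, 0.5, 1)) {
    s <- average_silhouette(rep(list(m), 5), tau = tau, n_min = 2,
                            align = FALSE)
    nr <- max(nrow(m), nrow(s)); ncl <- max(ncol(m), ncol(s))
    expect_identical(sum(xor(seedshape:::pad_mask(m, nr, ncl),
                             seedshape:::pad_mask(s, nr, ncl))), 0L)
  }
})

test_that("tau = 1 on two offset disks reproduces the analytic lens", {
  r <- 100; off <- 50
  a <- disk_mask(r, pad = 40, center_off = c(0, -off / 2))
  b <- disk_mask(r, pad = 40, center_off = c(0, off / 2))
  s <- average_silhouette(list(a, b), tau = 1, n_min = 2, align = FALSE)
  lens <- 2 * r^2 * acos(off / (2 * r)) - (off / 2) * sqrt(4 * r^2 - off^2)
  expect_lt(abs(sum(s) - lens) / lens, 0.02)
  # tau -> 1/N gives the union
  u <- average_silhouette(list(a, b), tau = 0.5, n_min = 2, align = FALSE)
  expect_identical(sum(u), sum(a | b))
})

test_that("silhouette area is non-increasing in tau", {
  pop <- generate_population("DM5", 8, eps = 0.03, height_px = 80,
                             rng_seed = 9)
  areas <- vapply(c(0.124, 0.25, 0.5, 0.75, 1),
                  function(tau) sum(average_silhouette(pop$masks, tau = tau,
                                                       n_min = 2)),
                  numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("duplicating one mask pulls the silhouette toward it", {
  base <- generate_seed("DM3", eps = 0.05, height_px = 70, rng_seed = 21)
  other <- generate_seed("DM3", eps = 0.05, height_px = 70, rng_seed = 22)
  stack <- c(rep(list(base), 18), list(other, other))
  s <- average_silhouette(stack, tau = 0.5, n_min = 2, align = FALSE)
  nr <- max(nrow(s), nrow(base)); ncl <- max(ncol(s), ncol(base))
  j <- jaccard_percent(seedshape:::pad_mask(s, nr, ncl),
                       seedshape:::pad_mask(base, nr, ncl))
  expect_gt(j, 98)
})

test_that("the population silhouette fits its model like the average seed", {
  pop <- generate_population("DM6", 12, eps = 0.02, height_px = 100,
                             rng_seed = 14)
  js <- vapply(pop$masks, function(m)
    suppressWarnings(jfit(m, models = "DM6"))$fits$J, numeric(1))
  sil <- average_silhouette(pop$masks, tau = 0.5, n_min = 2)
  jsil <- suppressWarnings(jfit(sil, models = "DM6"))$fits$J
  expect_lt(abs(jsil - mean(js)), 2)
})

test_that("degenerate silhouette inputs are rejected", {
  m <- disk_mask(20)
  expect_error(average_silhouette(list(m)), "at least 2")
  expect_error(average_silhouette(list(m, m), tau = 0), "tau")
  expect_error(average_silhouette(list(m, m), tau = 0.5, n_min = 20),
               "n_min")
})
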