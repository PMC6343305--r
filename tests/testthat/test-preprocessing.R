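test_that("sharpen matches a direct convolution oracle and clips", {
  kernel <- matrix(-1, 3, 3); kernel[2, 2] <- 12; kernel <- kernel / 4
  # [DERIVED] random 8-bit slices vs direct R convolution with clipping
  for (seed in 1:3) {
    sl <- rand_slice8(7, 9, seed)
    vol <- gray_volume(array(sl, c(1, 7, 9)), 1)
    out <- sharpen(vol)
    expect_equal(out$data[1, , ], pmin(pmax(conv3x3_r(sl, kernel), 0), 255))
  }
  # [TRIVIAL] kernel weights sum to 1: uniform slice unchanged
  u <- gray_volume(array(100, c(2, 6, 6)), 1)
  expect_equal(sharpen(u)$data, u$data)
  # [DERIVED] single pixel 100 on 0, 8-bit: centre 1200/4 = 300, clipped to 255
  px <- array(0, c(1, 5, 5)); px[1, 3, 3] <- 100
  sp <- sharpen(gray_volume(px, 1))
  expect_equal(sp$data[1, 3, 3], 255)
  # [DERIVED] checkerboard: contrast strictly increases
  cb <- array(0, c(1, 4, 4))
  cb[1, , ] <- 100 * ((outer(1:4, 1:4, "+") %% 2))
  out_cb <- sharpen(gray_volume(cb, 1))
  expect_gt(var(as.vector(out_cb$data)), var(as.vector(cb)))
})

test_that("despeckle is the 3x3 per-slice median with edge replication", {
  for (seed in 4:6) {
    sl <- rand_slice8(8, 6, seed)
    vol <- gray_volume(array(sl, c(1, 8, 6)), 1)
    expect_equal(despeckle(vol)$data[1, , ], med3x3_r(sl))
  }
  # [TRIVIAL] isolated spike removed; uniform unchanged
  sp <- array(0, c(1, 7, 7)); sp[1, 4, 4] <- 255
  expect_equal(despeckle(gray_volume(sp, 1))$data[1, 4, 4], 0)
  u <- gray_volume(array(42, c(3, 5, 5)), 1)
  expect_equal(despeckle(u)$data, u$data)
  # [DERIVED] 3x3 slice 1..9: centre is the median 5
  m <- array(matrix(1:9, 3, 3, byrow = TRUE), c(1, 3, 3))
  expect_equal(despeckle(gray_volume(m, 1))$data[1, 2, 2], 5)
})

test_that("isodata reproduces the hand examples and verifies its fixed point", {
  # [DERIVED] half 0 / half 100: T = 50 after one step
  r1 <- isodata_threshold(c(rep(0, 50), rep(100, 50)))
  expect_equal(r1$value, 50)
  expect_gte(r1$iterations, 1L)
  # [DERIVED] {0,0,0,9,9,9,90,90,90}: T0 = 33 -> means 4.5 / 90 -> T = 47.25
  r2 <- isodata_threshold(c(0, 0, 0, 9, 9, 9, 90, 90, 90))
  expect_equal(r2$value, 47.25)
  # [TRIVIAL] constant input has no threshold
  expect_error(isodata_threshold(rep(7, 10)), "constant")
  # fixed point verified post hoc on random data, plus range invariant
  for (seed in 1:5) {
    set.seed(seed)
    v <- c(rnorm(300, 40, 12), rnorm(200, 120, 20))
    r <- isodata_threshold(v)
    expect_gte(r$value, min(v)); expect_lte(r$value, max(v))
    mid <- (mean(v[v <= r$value]) + mean(v[v > r$value])) / 2
    expect_lt(abs(r$value - mid), 1e-6 * (max(v) - min(v)) + 1e-12)
  }
})

test_that("isodata is shift-equivariant and binarize_global inherits it", {
  set.seed(7)
  v <- c(rnorm(400, 50, 10), rnorm(150, 150, 15))
  t0 <- isodata_threshold(v)$value
  t1 <- isodata_threshold(v + 37.5)$value
  expect_equal(t1, t0 + 37.5, tolerance = 1e-6)
  vol <- gray_volume(array(sample(v, 6 * 8 * 8, TRUE), c(6, 8, 8)), 1)
  m0 <- binarize_global(vol)
  m1 <- binarize_global(gray_volume(vol$data + 25, 1))
  expect_identical(m0$mask, m1$mask)
  # [TRIVIAL] two-level volume: mask picks the upper level
  two <- gray_volume(array(c(0, 100)[1 + (rand_slice8(8, 8, 8) > 127)], c(1, 8, 8)), 1)
  expect_identical(binarize_global(two)$mask, two$data == 100)
})

test_that("global binarization recovers the phantom ground truth", {
  # [DERIVED] bone 180 / marrow 60, noise sigma 5: >= 99% voxel agreement
  ph <- tiny_phantom(seed = 12, texture = 5, air = 0)
  m <- binarize_global(ph$gray, "G0")
  agree <- mean(m$mask == ph$truth$mask)
  expect_gte(agree, 0.99)
})

test_that("per-slice thresholding is equivariant to per-slice affine maps", {
  # low-noise two-level volume with a wide margin makes the check exact
  set.seed(9)
  base <- array(c(60, 180)[1 + (runif(12 * 10 * 10) < 0.3)], c(12, 10, 10))
  vol <- gray_volume(base, 1)
  g_ref <- binarize_global(vol)
  gains <- seq(0.7, 1.3, length.out = 12)
  offs <- seq(-10, 25, length.out = 12)
  shaded <- base * gains + offs # recycles along z
  ps <- binarize_per_slice(gray_volume(pmax(shaded, 0), 1))
  # [DERIVED] per-slice masks equal the unshaded global mask
  expect_identical(ps$mask, g_ref$mask)
  # and per-slice agrees with global on the unshaded volume
  ps0 <- binarize_per_slice(vol)
  expect_gte(mean(ps0$mask == g_ref$mask), 0.99)
  # global binarization is NOT equivariant to the same per-slice shading:
  # this asymmetry is the mechanism behind the per-slice group's advantage
  g_shaded <- binarize_global(gray_volume(pmax(shaded, 0), 1))
  expect_false(identical(g_shaded$mask, g_ref$mask))
})

test_that("constant slices inherit the nearest non-constant threshold", {
  set.seed(10)
  base <- array(c(60, 180)[1 + (runif(5 * 8 * 8) < 0.4)], c(5, 8, 8))
  base[3, , ] <- 60 # an all-marrow slice
  ps <- binarize_per_slice(gray_volume(base, 1))
  thr <- attr(ps, "thresholds")
  expect_equal(thr[3], thr[2])
  expect_false(any(ps$mask[3, , ]))
  expect_error(binarize_per_slice(gray_volume(array(5, c(3, 4, 4)), 1)),
               "all slices constant")
})

test_that("calibration OLS behaves as derived (perturbation shifts intercept)", {
  pairs <- data.frame(density_mg_cm3 = c(0, 400, 800),
                      mean_grayscale = c(50, 150, 250))
  f0 <- fit_calibration(pairs)
  # [TRIVIAL] two points: interpolating line
  f2 <- fit_calibration(pairs[c(1, 3), ])
  expect_equal(f2$slope, 0.25); expect_equal(f2$intercept, 50)
  # [DERIVED by OLS algebra] perturbing outer points by (+e, -e) shifts the
  # intercept by exactly +e while the fitted value at the mean density is
  # unchanged (the midpoint, not the intercept, is the invariant)
  e <- 4
  pert <- pairs; pert$mean_grayscale <- pert$mean_grayscale + c(e, 0, -e)
  fp <- fit_calibration(pert)
  expect_equal(fp$intercept, f0$intercept + e)
  xbar <- mean(pairs$density_mg_cm3)
  expect_equal(fp$intercept + fp$slope * xbar, f0$intercept + f0$slope * xbar)
  expect_error(fit_calibration(data.frame(density_mg_cm3 = c(1, 1),
                                          mean_grayscale = c(2, 3))),
               "distinct densities")
})

test_that("remove_air is the exact set rule and idempotent", {
  calib <- fit_calibration(data.frame(density_mg_cm3 = c(0, 400, 800),
                                      mean_grayscale = c(60, 140, 220)))
  expect_equal(calib$air_cutoff_gv, 60)
  set.seed(11)
  g <- array(runif(16^3, 0, 200), c(16, 16, 16))
  gv <- gray_volume(g, 1)
  mk <- binary_volume(array(runif(16^3) < 0.5, c(16, 16, 16)), 1, "G3")
  out <- remove_air(mk, gv, calib)
  # [DERIVED] removed set equals {mask & gray <= cutoff}, checked exhaustively
  expect_identical(mk$mask & !out$mask, mk$mask & (g <= 60))
  expect_identical(out$mask, mk$mask & (g > 60))
  # [TRIVIAL] all above cutoff: unchanged; all below: empty
  hi <- gray_volume(g + 300, 1)
  expect_identical(remove_air(mk, hi, calib)$mask, mk$mask)
  lo <- gray_volume(g * 0, 1)
  expect_false(any(remove_air(mk, lo, calib)$mask))
  # idempotent
  expect_identical(remove_air(out, gv, calib)$mask, out$mask)
  expect_error(remove_air(mk, gray_volume(g[1:8, , ], 1), calib), "differ")
})

test_that("run_group dispatches the ladder and G4 only deletes", {
  ph <- tiny_phantom(seed = 13)
  cb <- degrade_to_cbct(ph$gray, degradation_spec(seed = 14))
  calib <- fit_calibration(generate_calibration_scan())
  g1 <- run_group(cb, "G1")
  expect_identical(g1$mask, binarize_global(cb)$mask)
  expect_equal(g1$provenance, "G1")
  g3 <- run_group(cb, "G3", calib)
  g4 <- run_group(cb, "G4", calib)
  # [TRIVIAL] air removal only deletes: G4 subset of G3
  expect_true(all(g3$mask[g4$mask]))
  expect_equal(g4$provenance, "G4")
  expect_error(run_group(cb, "G4"), "calibration")
})
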