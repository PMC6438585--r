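# Shared phantoms, built once per file.
clean_sphere <- function(vol_ml, sbr = 20, seed = 1) {
  sp <- phantom_spec(tumor_radii_mm = radii_for_volume(vol_ml, c(1, 1, 1)),
                     heterogeneity_amp = 0, noise_sd = 0, target_sbr = sbr,
                     seed = seed)
  generate_phantom(sp)
}

test_that("fixed threshold applies the inclusive 40% SUVmax rule", {
  v <- vol_from(array(c(10, 5, 4, 3.9), c(4, 1, 1)), spacing = c(4, 4, 4))
  m <- segment_fixed_threshold(v, c(1, 1, 1))
  expect_identical(as.vector(m$mask), c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(m$method, "FIXED40")
})

test_that("fixed threshold keeps a constant-uptake unblurred sphere whole", {
  sp <- phantom_spec(heterogeneity_amp = 0, noise_sd = 0, blur_fwhm_mm = 0,
                     seed = 2)
  v <- generate_phantom(sp)
  m <- segment_fixed_threshold(v, round(sp$tumor_center))
  expect_identical(m$mask, attr(v, "true_mask"))
})

test_that("fixed-threshold masks are nested in the threshold fraction", {
  v <- clean_sphere(20)
  pt <- round(phantom_spec()$tumor_center)
  masks <- lapply(c(0.3, 0.45, 0.6), function(f) {
    segment_fixed_threshold(v, pt, segmentation_config(fixed_threshold_fraction = f))
  })
  expect_true(all(masks[[2]]$mask[masks[[3]]$mask]))
  expect_true(all(masks[[1]]$mask[masks[[2]]$mask]))
})

test_that("SBR estimation recovers the simulated signal-to-background ratio", {
  sp <- phantom_spec(heterogeneity_amp = 0, noise_sd = 0, blur_fwhm_mm = 0,
                     target_sbr = 23.5, seed = 2)
  v <- generate_phantom(sp)
  m <- voi_mask(attr(v, "true_mask"), v)
  est <- estimate_sbr(v, m)
  expect_equal(est$suv_max, 23.5)
  expect_equal(est$sbr, 23.5, tolerance = 1e-6)

  u <- pet_volume(array(5, c(12, 12, 12)), spacing = c(4, 4, 4))
  mu <- voi_mask(array(c(rep(TRUE, 8), rep(FALSE, 1720)), c(12, 12, 12)), u)
  expect_equal(estimate_sbr(u, mu)$sbr, 1)

  z <- pet_volume(array(0, c(12, 12, 12)), spacing = c(4, 4, 4))
  z$values[6, 6, 6] <- 3
  mz <- voi_mask(z$values > 0, z)
  expect_error(estimate_sbr(z, mz), "zero")
})

test_that("adaptive thresholding needs coefficients and clamps sensibly", {
  v <- clean_sphere(20)
  pt <- round(phantom_spec()$tumor_center)
  expect_error(segment_adaptive_sbr(v, pt, segmentation_config()), "calibrat")
  # a law stuck at the 0.8 clamp must produce a subset of the 40% mask
  cfg_hi <- segmentation_config(adaptive_coeffs = c(0, 2))
  m_hi <- segment_adaptive_sbr(v, pt, cfg_hi)
  m_40 <- segment_fixed_threshold(v, pt)
  expect_true(all(m_40$mask[m_hi$mask]))
  expect_lt(m_hi$volume_ml, m_40$volume_ml)
})

test_that("calibration fits the threshold law with small residuals", {
  co <- calibrate_adaptive_thresholds(sphere_volumes_ml = c(10, 25),
                                      sbr_values = c(6, 24))
  cal <- attr(co, "calibration")
  expect_equal(nrow(cal), 4)
  expect_true(all(abs(cal$residual) < 0.05))
  expect_gt(co["a"], 0)   # lower SBR demands a higher fraction
  expect_true(co["b"] > 0.2 && co["b"] < 0.8)
})

test_that("calibration degenerates gracefully for a single SBR level", {
  co <- calibrate_adaptive_thresholds(sphere_volumes_ml = c(8, 15, 25, 40),
                                      sbr_values = 20)
  expect_equal(unname(co["a"]), 0)
  cal <- attr(co, "calibration")
  expect_equal(unname(co["b"]), mean(cal$fraction))
})

test_that("gradient edges recover clean sphere boundaries within one voxel", {
  for (vol_ml in c(8, 40)) {
    v <- clean_sphere(vol_ml)
    m <- segment_gradient_edge(v, round(phantom_spec()$tumor_center))
    r_true <- (3 * vol_ml * 1000 / (4 * pi))^(1 / 3)
    r_rec <- (3 * m$volume_ml * 1000 / (4 * pi))^(1 / 3)
    expect_lt(abs(r_rec - r_true), max(v$spacing))
  }
})

test_that("gradient method fails on gradient-free volumes", {
  u <- pet_volume(array(7, c(16, 16, 16)), spacing = c(4, 4, 4))
  expect_error(segment_gradient_edge(u, c(8, 8, 8)), "gradient extremum")
})

test_that("threshold masks are smaller than adaptive and gradient masks on
          heterogeneous phantoms", {
  cfg <- segmentation_config(adaptive_coeffs = c(0.49, 0.59))
  ord_ok <- sapply(c(7, 12, 33), function(s) {
    sp <- phantom_spec(seed = s, noise_sd = 0)
    v <- generate_phantom(sp)
    pt <- round(sp$tumor_center)
    f <- segment_fixed_threshold(v, pt, cfg)$volume_ml
    a <- segment_adaptive_sbr(v, pt, cfg)$volume_ml
    g <- segment_gradient_edge(v, pt, cfg)$volume_ml
    f <= a && f <= g
  })
  expect_true(all(ord_ok))
})

test_that("cluster selection keeps the component holding the hottest voxel", {
  arr <- array(0, c(9, 3, 3))
  arr[1:2, 1, 1] <- c(8, 6)     # cool component
  arr[6:7, 1, 1] <- c(12, 7)    # hot component
  v <- vol_from(arr, spacing = c(4, 4, 4))
  mask <- arr > 0
  sel <- select_representative_cluster(voi_mask(mask, v), v)
  expect_identical(which(sel$mask), which(arr == 12 | arr == 7))

  single <- voi_mask(arr == 12, v)  # already one component
  sel2 <- select_representative_cluster(single, v)
  expect_identical(sel2$mask, single$mask)
})

test_that("cluster-selection ties go to the larger component", {
  arr <- array(0, c(20, 4, 4))
  arr[1:8, 1:4, 1:4] <- 5       # 128 voxels, max 5
  arr[15:19, 1:2, 1:2] <- 5     # 20 voxels, max 5 (tie)
  v <- vol_from(arr, spacing = c(4, 4, 4))
  sel <- select_representative_cluster(voi_mask(arr > 0, v), v)
  expect_equal(sel$n_voxels, 128L)
  expect_true(all(sel$mask[1:8, , ]))
})

test_that("every method's mask contains the regional maximum voxel", {
  cfg <- segmentation_config(adaptive_coeffs = c(0.49, 0.59))
  sp <- phantom_spec(seed = 17)
  v <- generate_phantom(sp)
  pt <- round(sp$tumor_center)
  suvs <- sapply(segmentation_methods(), function(m) {
    compute_suvmax(v, segment(v, pt, m, cfg))
  })
  expect_true(all(suvs == max(suvs)))
})

test_that("SUVmax and MTV follow their definitions", {
  arr <- array(0, c(3, 1, 1)); arr[] <- c(3, 7, 5)
  v <- vol_from(arr, spacing = c(4, 4, 4))
  m <- voi_mask(array(TRUE, c(3, 1, 1)), v)
  expect_equal(compute_suvmax(v, m), 7)
  single <- voi_mask(array(c(TRUE, FALSE, FALSE), c(3, 1, 1)), v)
  expect_equal(compute_suvmax(v, single), 3)
  expect_error(compute_suvmax(v, voi_mask(array(FALSE, c(3, 1, 1)), v)),
               "empty")

  v2 <- pet_volume(array(1, c(10, 10, 10)), spacing = c(4.07, 4.07, 2))
  arr64 <- array(FALSE, c(10, 10, 10)); arr64[1:64] <- TRUE
  expect_equal(round(compute_mtv(voi_mask(arr64, v2)), 2), 2.12)
  expect_equal(compute_mtv(voi_mask(array(FALSE, c(10, 10, 10)), v2)), 0)
  v3 <- pet_volume(array(1, c(10, 10, 10)), spacing = c(1, 1, 1))
  expect_equal(compute_mtv(voi_mask(array(TRUE, c(10, 10, 10)), v3)), 1)
})
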