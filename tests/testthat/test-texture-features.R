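# The [1, 1, 2] collinear fixture used by the hand-computed examples.
line_dvoi <- function() dvoi_from(array(c(1L, 1L, 2L), c(3, 1, 1)))

test_that("absolute resampling maps SUVs to the documented levels", {
  v <- vol_from(array(c(0, 30, 35, 15, 10, 29.9999), c(6, 1, 1)))
  m <- voi_mask(array(TRUE, c(6, 1, 1)), v)
  dv <- discretize_absolute(v, m)
  expect_equal(dv$levels[, 1, 1], c(1L, 64L, 64L, 33L, 22L, 64L))

  vc <- vol_from(array(10, c(4, 4, 4)))
  mc <- voi_mask(array(TRUE, c(4, 4, 4)), vc)
  expect_equal(unique(as.vector(discretize_absolute(vc, mc)$levels)), 22L)
})

test_that("co-occurrence counts and indices match the hand-built example", {
  g <- build_glcm(line_dvoi())
  expect_equal(g$counts[1, 1], 2)
  expect_equal(g$counts[1, 2], 1)
  expect_equal(g$counts[2, 1], 1)
  expect_equal(sum(g$counts), 4)
  idx <- glcm_indices(g)
  expect_equal(unname(idx["Homogeneity"]), 0.75)
  expect_equal(unname(idx["Energy"]), 0.375)
  expect_equal(unname(idx["Contrast_glcm"]), 0.5)
  expect_equal(unname(idx["Dissimilarity"]), 0.5)
  expect_equal(unname(idx["Entropy"]), 1.5)
  expect_equal(unname(idx["Correlation"]), -1 / 3)
})

test_that("constant VOIs give the degenerate single-cell matrices", {
  dv <- dvoi_from(array(22L, c(3, 3, 3)))
  g <- build_glcm(dv)
  expect_equal(g$p[22, 22], 1)
  idx <- glcm_indices(g)
  expect_equal(unname(idx[c("Homogeneity", "Energy")]), c(1, 1))
  expect_equal(unname(idx[c("Contrast_glcm", "Dissimilarity", "Entropy")]),
               c(0, 0, 0))
  expect_true(is.na(idx["Correlation"]))

  z <- build_glzlm(dv)
  expect_equal(sum(z), 1)          # a single zone...
  expect_equal(z[22, 27], 1)       # ...of all 27 voxels
  ng <- ngldm_indices(build_ngldm(dv))
  expect_true(is.na(ng["Busyness"]))
})

test_that("run decomposition matches the hand example and conserves mass", {
  mat <- build_glrlm(line_dvoi())
  # +x direction: one level-1 run of length 2, one level-2 run of length 1;
  # the 12 other directions fragment the VOI into 36 runs of length 1.
  expect_equal(mat[1, 2], 1)
  expect_equal(mat[1, 1], 24)
  expect_equal(mat[2, 1], 13)
  expect_equal(sum(sweep(mat, 2, seq_len(ncol(mat)), "*")), 13 * 3)
})

test_that("run/zone emphasis formulas reduce to their closed forms", {
  # single run of length L at level 1, one direction
  L <- 5
  mat <- matrix(0, 4, L); mat[1, L] <- 1
  idx <- glrlm_indices(mat, n_voxels = L, n_directions = 1)
  expect_equal(unname(idx["SRE"]), 1 / L^2)
  expect_equal(unname(idx["LRE"]), L^2)
  expect_equal(unname(idx["RP"]), 1 / L)

  # all runs of length 1: SRE = LRE = RP = 1
  m1 <- matrix(0, 4, 1); m1[, 1] <- c(3, 1, 0, 2)
  idx1 <- glrlm_indices(m1, n_voxels = 6, n_directions = 1)
  expect_equal(unname(idx1[c("SRE", "LRE", "RP")]), c(1, 1, 1))

  # single zone of size N at level 1
  N <- 7
  mz <- matrix(0, 4, N); mz[1, N] <- 1
  zidx <- glzlm_indices(mz, n_voxels = N)
  expect_equal(unname(zidx["LZLGE"]), N^2)
  expect_equal(unname(zidx["SZE"]), 1 / N^2)
  expect_equal(unname(zidx["ZP"]), 1 / N)
})

test_that("zone statistics match the hand-built example", {
  z <- build_glzlm(line_dvoi())
  expect_equal(z[1, 2], 1)
  expect_equal(z[2, 1], 1)
  expect_equal(sum(sweep(z, 2, seq_len(ncol(z)), "*")), 3)
  idx <- glzlm_indices(z, n_voxels = 3)
  expect_equal(unname(idx["SZE"]), 0.625)
  expect_equal(unname(idx["LZE"]), 2.5)
  expect_equal(unname(idx["LGZE"]), 0.625)
  expect_equal(unname(idx["HGZE"]), 2.5)
  expect_equal(unname(idx["ZP"]), 2 / 3)
})

test_that("neighborhood dependence handles uniform and alternating patterns", {
  dv <- dvoi_from(array(5L, c(3, 3, 3)))
  ng <- build_ngldm(dv)
  expect_equal(ng$Q[5, 27], 1)               # center voxel: 26 equal neighbors
  expect_equal(sum(ng$Q), 27)                # every voxel counted once

  strip <- dvoi_from(array(rep(c(1L, 2L), 3), c(6, 1, 1)))
  ngs <- build_ngldm(strip)
  expect_equal(sum(ngs$Q[, 1]), 6)           # all dependences zero
})

test_that("matrix builders agree with brute-force enumeration", {
  set.seed(42)
  for (k in 1:15) {
    dv <- random_dvoi(dims = c(5, 5, 5), n_levels = 4L)
    if (dv$n_voxels == 0) next
    expect_matrix_equal(build_glcm(dv)$counts[1:4, 1:4], oracle_glcm(dv))
    expect_matrix_equal(build_glrlm(dv)[1:4, , drop = FALSE], oracle_glrlm(dv))
    expect_matrix_equal(build_ngldm(dv)$Q[1:4, ], oracle_ngldm_Q(dv))
    expect_matrix_equal(build_glzlm(dv)[1:4, , drop = FALSE], oracle_glzlm(dv))
  }
})

test_that("matrix mass is conserved", {
  set.seed(7)
  for (k in 1:5) {
    dv <- random_dvoi(dims = c(4, 4, 4), n_levels = 3L)
    if (dv$n_voxels < 2) next
    g <- build_glcm(dv)
    if (!g$degenerate) expect_equal(sum(g$p), 1)
    z <- build_glzlm(dv)
    expect_equal(sum(sweep(z, 2, seq_len(ncol(z)), "*")), dv$n_voxels)
    r <- build_glrlm(dv)
    expect_equal(sum(sweep(r, 2, seq_len(ncol(r)), "*")), 13 * dv$n_voxels)
  }
})

test_that("coarser discretization never raises co-occurrence entropy", {
  set.seed(11)
  for (k in 1:8) {
    sp <- phantom_spec(seed = k, grid_shape = c(24, 24, 36),
                       tumor_radii_mm = radii_for_volume(10))
    v <- generate_phantom(sp)
    m <- voi_mask(attr(v, "true_mask"), v)
    e64 <- glcm_indices(build_glcm(discretize_absolute(
      v, m, discretization_config(n_levels = 64))))["Entropy"]
    e32 <- glcm_indices(build_glcm(discretize_absolute(
      v, m, discretization_config(n_levels = 32))))["Entropy"]
    expect_lte(unname(e32), unname(e64) + 1e-9)
  }
})

test_that("noise on a homogeneous phantom lowers homogeneity, raises entropy", {
  set.seed(5)
  res <- sapply(1:20, function(s) {
    sp0 <- phantom_spec(heterogeneity_amp = 0, blur_fwhm_mm = 0, noise_sd = 0,
                        grid_shape = c(20, 20, 30),
                        tumor_radii_mm = radii_for_volume(8), seed = s)
    spn <- sp0; spn$noise_sd <- 1.0
    extract_pair <- function(sp) {
      v <- generate_phantom(sp)
      m <- voi_mask(attr(v, "true_mask"), v)
      glcm_indices(build_glcm(discretize_absolute(v, m)))[c("Homogeneity", "Entropy")]
    }
    c(extract_pair(sp0), extract_pair(spn))
  })
  expect_lt(mean(res[3, ]), mean(res[1, ]))  # homogeneity drops with noise
  expect_gt(mean(res[4, ]), mean(res[2, ]))  # entropy rises with noise
})

test_that("feature extraction enforces eligibility and emits 31 indices", {
  v <- pet_volume(array(10, c(10, 10, 10)), spacing = c(4.07, 4.07, 2))
  arr63 <- array(FALSE, c(10, 10, 10)); arr63[1:63] <- TRUE
  expect_error(extract_features(v, voi_mask(arr63, v)), "neligible")

  sp <- phantom_spec(seed = 3, tumor_radii_mm = radii_for_volume(10))
  vp <- generate_phantom(sp)
  mk <- segment_fixed_threshold(vp, round(sp$tumor_center))
  f <- extract_features(vp, mk, patient = "P01")
  expect_true(all(texture_feature_names() %in% names(f)))
  expect_length(texture_feature_names(), 31)
  expect_true(all(is.finite(unlist(f[texture_feature_names()]))))
  expect_true(all(c("SUVmax", "MTV") %in% names(f)))

  arr64 <- array(FALSE, c(10, 10, 10)); arr64[1:4, 1:4, 1:4] <- TRUE
  fc <- extract_features(v, voi_mask(arr64, v))
  expect_equal(fc$Homogeneity, 1)
  expect_equal(fc$Entropy, 0)
  expect_true(is.na(fc$Correlation))
  expect_true(is.na(fc$Busyness))
})

test_that("multi-component masks are rejected by feature extraction", {
  v <- pet_volume(array(10, c(12, 12, 12)), spacing = c(4.07, 4.07, 2))
  arr <- array(FALSE, c(12, 12, 12))
  arr[1:4, 1:4, 1:4] <- TRUE
  arr[9:12, 9:12, 9:12] <- TRUE
  expect_error(extract_features(v, voi_mask(arr, v)), "single")
})
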