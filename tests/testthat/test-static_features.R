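test_that("fixed-bin-width discretization follows the floor rule", {
  expect_equal(discretize(c(0, 25, 49, 50), 25), c(1L, 2L, 2L, 3L))
  expect_equal(discretize(rep(7, 5), 25), rep(1L, 5))
  x <- c(3, 30, 61, 99)
  expect_identical(discretize(x + 1000, 25), discretize(x, 25))  # translation invariant
})

test_that("z-normalization centres the volume and the shift relocates it", {
  arr <- array(5, c(3, 3, 3)); arr[1, 1, 1] <- 6  # constant plus one voxel
  v <- image_volume(arr)
  m <- roi_mask(array(TRUE, c(3, 3, 3)), v)
  s <- extraction_settings(resample_spacing = NULL)
  pp <- preprocess(v, m, s)
  expect_equal(mean(pp$volume$voxels), 1000, tolerance = 1e-10)
  s0 <- extraction_settings(resample_spacing = NULL, voxel_array_shift = 0)
  expect_equal(mean(preprocess(v, m, s0)$volume$voxels), 0, tolerance = 1e-10)
  vc <- image_volume(array(5, c(3, 3, 3)))
  expect_error(preprocess(vc, m, s), "variance")
})

test_that("resampling a 2 mm grid to 1 mm doubles each axis; mask keeps volume", {
  set.seed(3)
  arr <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  v <- image_volume(arr, spacing = c(2, 2, 2))
  ph <- simulate_phantom_images(grid = c(24, 24, 24), radii = c(10, 10, 10),
                                noise_sd = 0, spacing = c(2, 2, 2))
  m <- ph$mask
  m$voxels <- m$voxels[1:6, 1:5, 1:4, drop = FALSE]  # any nonempty mask works
  m$voxels[1] <- TRUE
  s <- extraction_settings(normalize = FALSE, resample_spacing = c(1, 1, 1))
  pp <- preprocess(v, roi_mask(m$voxels, v), s)
  expect_true(all(abs(dim(pp$volume$voxels) - c(12, 10, 8)) <= 1))

  # sphere of radius 10 voxels at 2 mm: nearest-neighbour resampling to 1 mm
  # preserves physical volume within 15%
  full <- preprocess(image_volume(array(0, c(24, 24, 24)) + ph$volumes$PP$voxels,
                                  spacing = c(2, 2, 2)),
                     roi_mask(ph$mask$voxels,
                              image_volume(ph$volumes$PP$voxels, spacing = c(2, 2, 2))),
                     s)
  vol_before <- sum(ph$mask$voxels) * 8   # mm^3
  vol_after <- sum(full$mask$voxels) * 1
  expect_lt(abs(vol_after - vol_before) / vol_before, 0.15)
})

test_that("first-order features are exact on a constant ROI", {
  arr <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
  arr[2:4, 2:4, 2:4] <- 42
  v <- image_volume(arr)
  mvox <- array(FALSE, c(5, 5, 5)); mvox[2:4, 2:4, 2:4] <- TRUE
  s <- extraction_settings(normalize = FALSE, resample_spacing = NULL)
  sf <- extract_static_features(v, roi_mask(mvox, v), s)
  expect_equal(unname(sf["firstorder_Entropy"]), 0)
  expect_equal(unname(sf["firstorder_Variance"]), 0)
  expect_equal(unname(sf["firstorder_Uniformity"]), 1)
  expect_equal(unname(sf["firstorder_Mean"]), 42)
  expect_equal(unname(sf["firstorder_Energy"]), 27 * 42^2)
})

test_that("intensity features are invariant to an additive constant when normalizing", {
  ph <- simulate_phantom_images(noise_sd = 3, seed = 2)
  v <- ph$volumes$AP
  v2 <- image_volume(v$voxels + 250, spacing = v$spacing, phase = v$phase)
  s <- extraction_settings()
  a <- extract_static_features(v, ph$mask, s)
  b <- extract_static_features(v2, ph$mask, s)
  io <- grep("^(firstorder|glcm)_", names(a))
  expect_equal(a[io], b[io], tolerance = 1e-9)
})

test_that("shape features depend on the mask only; sphere has elongation = flatness = 1", {
  ph <- simulate_phantom_images(grid = c(26, 26, 26), radii = c(9, 9, 9), noise_sd = 0)
  s <- extraction_settings(normalize = FALSE, resample_spacing = NULL)
  sf <- extract_static_features(ph$volumes$PP, ph$mask, s)
  expect_equal(unname(sf["shape_Elongation"]), 1, tolerance = 1e-10)
  expect_equal(unname(sf["shape_Flatness"]), 1, tolerance = 1e-10)
  # different intensities, same mask -> identical shape features
  sf2 <- extract_static_features(ph$volumes$AP, ph$mask, s)
  sh <- grep("^shape_", names(sf))
  expect_identical(sf[sh], sf2[sh])
  # mask voxel count = lattice points inside the ellipsoid
  ph2 <- simulate_phantom_images(grid = c(32, 32, 24), radii = c(8, 6, 5), noise_sd = 0)
  ctr <- (c(32, 32, 24) + 1) / 2
  cnt <- 0
  for (x in 1:32) for (y in 1:32) for (z in 1:24)
    cnt <- cnt + (((x - ctr[1]) / 8)^2 + ((y - ctr[2]) / 6)^2 + ((z - ctr[3]) / 5)^2 <= 1)
  expect_equal(sum(ph2$mask$voxels), cnt)
})

test_that("GLCM features match brute-force pair counting on random small ROIs", {
  set.seed(99)
  offs <- dynradiomics:::.glcm_offsets()
  expect_equal(nrow(offs), 13)
  for (r in 1:15) {
    d <- sample(3:6, 3, replace = TRUE)
    ng <- sample(2:5, 1)
    lev <- array(sample(seq_len(ng), prod(d), replace = TRUE), d)
    mask <- array(runif(prod(d)) < 0.75, d)
    if (sum(mask) < 4) next
    # counts per direction agree with the triple-loop oracle
    for (o in sample(seq_len(13), 3)) {
      expect_equal(dynradiomics:::.glcm_count(lev, mask, offs[o, ], ng),
                   oracle_glcm_counts(lev, mask, offs[o, ], ng),
                   ignore_attr = TRUE)
    }
    # direction-averaged contrast agrees with the by-definition formula
    Ps <- lapply(seq_len(13), function(o) oracle_glcm_counts(lev, mask, offs[o, ], ng))
    Ps <- Filter(function(P) sum(P) > 0, Ps)
    expected <- mean(vapply(Ps, oracle_glcm_contrast, numeric(1)))
    got <- dynradiomics:::glcm_features(lev, mask, n_levels = ng)["glcm_Contrast"]
    expect_equal(unname(got), expected, tolerance = 1e-12)
  }
})

test_that("a checkerboard plane gives the hand-counted in-plane GLCM contrast", {
  lev <- array(1L, c(3, 3, 1))
  lev[, , 1] <- (outer(1:3, 1:3, `+`) %% 2L) + 1L   # levels 1/2 checkerboard
  mask <- array(TRUE, c(3, 3, 1))
  offs <- dynradiomics:::.glcm_offsets()
  ax <- which(apply(offs, 1, function(o) all(o == c(1, 0, 0)) || all(o == c(0, 1, 0))))
  for (o in ax) {
    P <- dynradiomics:::.glcm_count(lev, mask, offs[o, ], 2)
    # every axis-adjacent pair alternates levels: all 12 (x2 symmetric) counts
    # off-diagonal -> contrast (1-2)^2 * 1 = 1
    st <- dynradiomics:::.glcm_stats(P)
    expect_equal(unname(st["glcm_Contrast"]), 1)
    expect_equal(sum(diag(P)), 0)
  }
})

test_that("single-voxel ROIs yield flagged NaN shape/GLCM, not silent zeros", {
  arr <- array(rnorm(27), c(3, 3, 3))
  mvox <- array(FALSE, c(3, 3, 3)); mvox[2, 2, 2] <- TRUE
  v <- image_volume(arr)
  s <- extraction_settings(normalize = FALSE, resample_spacing = NULL)
  sf <- extract_static_features(v, roi_mask(mvox, v), s)
  expect_true(is.na(sf["shape_Elongation"]))
  expect_true(is.na(sf["glcm_Contrast"]))
  expect_true(length(attr(sf, "flags")) >= 2)
})

test_that("constant features are dropped at the 1e-12 range tolerance", {
  m <- cbind(a = c(1, 1, 1), b = c(1, 2, 3), c = c(2, 2, 2 + 1e-15))
  out <- drop_constant_features(m)
  expect_identical(colnames(out), "b")
  expect_equal(attr(out, "n_removed"), 2)
  m2 <- cbind(a = c(1, 2, 3), b = c(4, 6, 5))
  expect_equal(drop_constant_features(m2), m2, ignore_attr = TRUE)
  expect_error(drop_constant_features(cbind(a = c(1, 1))), "constant")
})
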