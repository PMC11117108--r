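test_that("compcor removes exactly the noise components", {
  set.seed(31)
  Tn <- 400
  noise <- matrix(rnorm(20 * Tn), 20, Tn)
  pc1 <- prcomp(t(noise), center = TRUE)$x[, 1]
  # a voxel equal to PC1 is annihilated
  res <- compcor_denoise(matrix(pc1, 1), noise)
  expect_lt(max(abs(res)), 1e-8)
  # data orthogonal to the noise PCs pass through (up to the intercept)
  pcs <- prcomp(t(noise), center = TRUE)$x[, 1:5]
  ortho <- t(qr.resid(qr(cbind(1, pcs)), rnorm(Tn)))
  expect_equal(compcor_denoise(ortho, noise), ortho, tolerance = 1e-8)
  # planted drift spanning the noise PCs is removed from the signal
  clean <- sin(seq_len(Tn) / 7)
  contaminated <- matrix(clean + 2 * pc1, 1)
  rec <- compcor_denoise(contaminated, noise)
  expect_gt(cor(drop(rec), clean), 0.99)
  expect_warning(compcor_denoise(matrix(rnorm(2 * Tn), 2), noise[1:3, ]),
                 "components")
})

test_that("seed ROI selection is a thresholded sphere around the peak", {
  dims <- c(9, 9, 9)
  mask <- make_grid(dims)
  stat <- array(0, dims)
  ctr <- c(5, 5, 5)
  ijk <- arrayInd(seq_len(prod(dims)), dims)
  d2 <- rowSums((ijk - matrix(ctr, prod(dims), 3, byrow = TRUE))^2)
  stat[] <- exp(-d2 / 8)                      # Gaussian bump, peak at ctr
  roi <- define_seed_roi(stat, mask, voxel_size_mm = c(3, 3, 3),
                         radius_mm = 9, n_voxels = 20)
  # brute-force sphere: voxels within 9 mm (= 3 voxels) of the peak
  sphere <- which(sqrt(d2) * 3 <= 9)
  expect_true(all(roi %in% sphere))
  expect_length(roi, 20)
  # all returned voxels beat every excluded sphere voxel
  expect_gte(min(stat[roi]), max(stat[setdiff(sphere, roi)]))
  # single-voxel mask returns that voxel (with a short-sphere warning)
  m1 <- array(FALSE, dims); m1[2, 3, 4] <- TRUE
  expect_warning(roi1 <- define_seed_roi(stat, m1), "only 1")
  expect_equal(roi1, which(m1))
  expect_error(define_seed_roi(stat, array(FALSE, dims)), "empty")
  # ties at the cutoff resolve by ascending voxel index, deterministically
  flat <- array(1, dims)   # peak at the corner: small truncated sphere
  r1 <- suppressWarnings(define_seed_roi(flat, mask,
                                         voxel_size_mm = c(3, 3, 3),
                                         n_voxels = 10))
  r2 <- suppressWarnings(define_seed_roi(flat, mask,
                                         voxel_size_mm = c(3, 3, 3),
                                         n_voxels = 10))
  expect_identical(r1, r2)
  expect_equal(r1, sort(r1))
})

test_that("seed_mean averages across the ROI per time point", {
  d <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4), 2, byrow = TRUE)
  expect_equal(seed_mean(d, 1:2), c(1, 2, 3, 4))
  d2 <- rbind(a = c(1, -2, 3), b = -c(1, -2, 3))
  expect_equal(seed_mean(d2, 1:2), c(0, 0, 0))
  set.seed(37)
  d3 <- matrix(rnorm(12), 3, 4)
  expect_equal(seed_mean(d3, c(1, 3)), (d3[1, ] + d3[3, ]) / 2)
  expect_error(seed_mean(d3, integer(0)), "empty")
  expect_error(seed_mean(d3, 5), "outside")
})

test_that("coordinate maps flag degenerate voxels and find planted orders", {
  set.seed(41)
  Tn <- 2000
  seed_ts <- rnorm(Tn)
  data <- rbind(seed_ts,                                  # identical
                rnorm(Tn),                                # independent
                hermite_poly(seed_ts, 2),                 # planted square
                rep(1, Tn))                               # degenerate
  expect_message(cm <- map_coordinates(seed_ts, data), "1 degenerate")
  expect_true(attr(cm, "degenerate")[4])
  expect_true(all(is.na(cm[4, ])))
  # identical series: order-1 loading ~ k1 * E[x^2] / E[He_1^2] = k1
  expect_equal(cm[1, "c1"], hermite_norm_const(1), tolerance = 0.1)
  # independent noise: all loadings ~ 0
  expect_lt(max(abs(cm[2, ])), 3 / sqrt(Tn) * 3)
  # planted quadratic: after z-scoring y, order-2 loading ~ k2 / sd(He_2)
  expect_equal(cm[3, "c2"],
               hermite_norm_const(2) / sqrt(2), tolerance = 0.1)
  expect_error(map_coordinates(seed_ts, matrix(1, 2, Tn)), "constant")
})

test_that("fc map matches the linear coordinate on linear planted data", {
  set.seed(43)
  centers <- cbind(0, seq(-1, 1, length.out = 8), 0, 0, 0)
  sim <- sim_clustered_maps(centers, voxels_per_cluster = 10,
                            n_time = 500, noise_sd = 0.3, seed = 47)
  cm <- map_coordinates(sim$x, sim$y)
  fc <- fc_map(sim$x, sim$y)
  expect_gt(cor(fc, cm[, "c1"], method = "spearman"), 0.95)
})

test_that("planted sign patterns are recovered across a volume", {
  sim <- sim_clustered_maps(planted_centers(), voxels_per_cluster = 40,
                            n_time = 500, noise_sd = 0.2, seed = 53)
  cm <- map_coordinates(sim$x, sim$y, standardize = FALSE)
  truth <- planted_centers()[sim$labels, ]
  big <- abs(truth) > 0.5      # coordinates that carry signal
  agree <- sign(unclass(cm))[big] == sign(truth)[big]
  expect_gt(mean(agree), 0.95)
})

test_that("NIfTI volumes round-trip through the mask helpers", {
  dims <- c(5, 4, 3)
  mask <- array(runif(prod(dims)) > 0.3, dims)
  V <- sum(mask); Tn <- 6
  arr <- array(0, c(dims, Tn))
  series <- matrix(rnorm(V * Tn), V, Tn)
  flat <- matrix(0, prod(dims), Tn); flat[which(mask), ] <- series
  arr[] <- flat
  f_img <- tempfile(fileext = ".nii.gz")
  f_mask <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), f_img)
  RNifti::writeNifti(RNifti::asNifti(array(as.numeric(mask), dims)), f_mask)
  got <- read_masked_series(f_img, f_mask)
  expect_equal(got$data, series, tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(got$mask, mask, ignore_attr = TRUE)
  # write per-voxel values back out and re-read
  f_out <- tempfile(fileext = ".nii.gz")
  write_masked_volume(series, mask, f_out)
  back <- RNifti::readNifti(f_out)
  expect_equal(matrix(back, prod(dims), Tn)[which(mask), ], series,
               tolerance = 1e-6, ignore_attr = TRUE)
})
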