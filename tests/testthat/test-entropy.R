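test_that("coarse-graining averages non-overlapping blocks and drops the remainder", {
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5, 6), 2), c(1.5, 3.5, 5.5))
  x <- rnorm(50)
  expect_identical(coarse_grain(x, 1), x)
  expect_length(coarse_grain(rnorm(383), 15), 25)   # floor(383/15)
  expect_equal(coarse_grain(c(1, 2, 3, 4, 5), 2), c(1.5, 3.5))
  expect_error(coarse_grain(x, 0), "scale")
  expect_error(coarse_grain(x, 51), "exceeds")
})

test_that("nested coarse-graining at scale 2 twice equals scale 4 when N divides evenly", {
  set.seed(4)
  x <- rnorm(64)
  expect_equal(coarse_grain(coarse_grain(x, 2), 2), coarse_grain(x, 4))
})

test_that("sample entropy handles degenerate and periodic signals", {
  expect_equal(sample_entropy(rep(3.7, 50), 2, 0.1), 0)
  expect_equal(sample_entropy(rep(3.7, 50), 2, 0), 0)
  # alternating +1/-1: every m-template match extends to an (m+1)-match
  expect_equal(sample_entropy(rep(c(1, -1), 10), 2, 0.2), 0)
  # any period-p signal with p <= m is 0 under the 1..N-m convention
  expect_equal(sample_entropy(rep(c(0, 1), 25), 2, 0.1), 0)
  expect_error(sample_entropy(c(1, 2, 3), 2, 0.1), "too short")
  expect_error(sample_entropy(c(rnorm(20), NA), 2, 0.1), "non-finite")
})

test_that("sample entropy is invariant under positive affine transforms of signal and tolerance", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(80)
    r <- 0.25
    expect_identical(sample_entropy(x, 2, r),
                     sample_entropy(3.2 * x + 7, 2, 3.2 * r))
  }
})

test_that("compiled sample entropy matches the naive double-loop oracle exactly", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    m <- sample(1:3, 1)
    x <- rnorm(n)
    r <- runif(1, 0.1, 0.5)
    expect_identical(sample_entropy(x, m, r), naive_sampen(x, m, r))
  }
})

test_that("sample entropy approaches the iid Gaussian analytic limit", {
  # for iid Gaussian noise the conditional probability of an (m+1)-match
  # given an m-match is P(|X - Y| <= r) = 2*pnorm(r/sqrt(2)) - 1
  set.seed(9)
  n <- 4000
  vals <- replicate(8, {
    x <- rnorm(n)
    sample_entropy(x, 2, 0.3 * sqrt(mean((x - mean(x))^2)))
  })
  expect_lt(abs(mean(vals) - (-log(2 * pnorm(0.3 / sqrt(2)) - 1))), 0.05)
})

test_that("multiscale entropy averages per-scale SampEn and is deterministic", {
  set.seed(5)
  x <- rnorm(400)
  p <- multiscale_entropy(x, entropy_params())
  expect_length(p$sampen, 15)
  expect_equal(p$mse, mean(p$sampen, na.rm = TRUE))
  expect_equal(p$n_valid_scales, sum(!is.na(p$sampen)))
  expect_identical(p, multiscale_entropy(x, entropy_params()))
  pc <- multiscale_entropy(rep(2, 400), entropy_params())
  expect_equal(pc$sampen, rep(0, 15))
  expect_equal(pc$mse, 0)
})

test_that("white-noise SampEn decreases across scales under the fixed-tolerance convention", {
  # fixed r_abs while the coarse-grained SD shrinks by sqrt(scale)
  set.seed(21)
  prof <- rowMeans(replicate(12, multiscale_entropy(rnorm(1200),
    entropy_params(scales = 8))$sampen))
  expect_true(all(diff(prof) < 0))
})

test_that("per-scale tolerance option recomputes r from each coarse-grained series", {
  set.seed(6)
  x <- rnorm(600)
  p <- multiscale_entropy(x, entropy_params(scales = 4,
    tolerance_reference = "per_scale_sd"))
  cg <- coarse_grain(x, 4)
  expect_equal(p$sampen[4],
               sample_entropy(cg, 2, 0.3 * sqrt(mean((cg - mean(cg))^2))))
})

test_that("scale-to-frequency mapping matches 1/(scale * TR)", {
  expect_equal(scale_to_frequency(1, 0.8), 1.25)
  expect_equal(scale_to_frequency(15, 0.8), 1 / 12)
  expect_equal(scale_to_frequency(2, 0.5), 1)
  expect_error(scale_to_frequency(0, 0.8), "scale")
})

test_that("run averaging is an element-wise mean with pairwise NA exclusion", {
  a <- array(1, c(2, 2, 2)); b <- array(2, c(2, 2, 2))
  avg <- average_runs(list(a, b))
  expect_equal(as.vector(avg), rep(1.5, 8))
  expect_equal(average_runs(list(a, a)), a, ignore_attr = TRUE)
  a[1] <- NA
  avg <- average_runs(list(a, b))
  expect_equal(avg[1], 2)                    # defined value carried through
  expect_equal(attr(avg, "n_valid")[1], 1)   # flagged as single-run
  expect_error(average_runs(list(a, array(1, c(2, 2)))), "mismatch")
})

test_that("profile averaging across runs matches scale-wise means", {
  set.seed(8)
  p1 <- multiscale_entropy(rnorm(300), entropy_params(scales = 5))
  p2 <- multiscale_entropy(rnorm(300), entropy_params(scales = 5))
  avg <- average_runs(list(p1, p2))
  expect_equal(avg$sampen, (p1$sampen + p2$sampen) / 2)
  expect_equal(avg$mse, mean(avg$sampen))
})

test_that("voxel-wise MSE maps constants to zero and respects the mask", {
  set.seed(12)
  n <- 120
  bold <- array(rnorm(4 * 4 * 2 * n), c(4, 4, 2, n))
  bold[1:2, , , ] <- 5                      # constant half
  mask <- array(TRUE, c(4, 4, 2))
  map <- voxelwise_mse(bold, mask, entropy_params(scales = 3))
  expect_equal(dim(map), c(4, 4, 2))
  expect_true(all(map[1:2, , ] == 0))
  expect_true(all(map[3:4, , ] > 0))
  empty <- voxelwise_mse(bold, array(FALSE, c(4, 4, 2)),
                         entropy_params(scales = 3))
  expect_true(all(is.na(empty)))
  expect_error(voxelwise_mse(bold, array(TRUE, c(3, 4, 2))), "grid")
})

test_that("white-noise regions have higher MSE than strongly autocorrelated regions", {
  set.seed(13)
  n <- 200
  white <- matrix(rnorm(4 * n), 4)
  slow <- t(replicate(4, as.numeric(stats::filter(rnorm(n, sd = sqrt(1 - 0.9^2)),
                                                  0.9, method = "recursive"))))
  arr <- rbind(white, slow)    # 8 voxels x time
  bold4d <- array(0, c(2, 2, 2, n))
  bold4d[] <- as.vector(arr)   # voxel i gets row i (column-major fill)
  map <- voxelwise_mse(bold4d, NULL, entropy_params(scales = 3))
  # voxels 1..4 white, 5..8 AR(0.9): scale-1-dominated short profile orders them
  expect_gt(mean(map[1:4]), mean(map[5:8]))
})

test_that("MSE maps and label volumes round-trip through NIfTI", {
  set.seed(14)
  map <- array(runif(4 * 4 * 3), c(4, 4, 3))
  tf <- tempfile(fileext = ".nii.gz")
  write_nifti_map(map, tf)
  back <- read_nifti_volume(tf)
  expect_equal(as.array(back), map, tolerance = 1e-6, ignore_attr = TRUE)
  atlas <- array(sample(0:3, 24, replace = TRUE), c(4, 3, 2))
  ta <- tempfile(fileext = ".nii.gz")
  write_nifti_map(atlas, ta)
  expect_equal(as.array(read_nifti_volume(ta)), atlas, ignore_attr = TRUE)
})

test_that("ROI means summarize defined voxels and flag missing labels", {
  map <- array(c(1, 3, NA, 7), c(2, 2, 1))
  atlas <- array(c(1L, 1L, 2L, 3L), c(2, 2, 1))
  expect_equal(roi_mean(map, atlas, 1), 2)
  expect_equal(roi_mean(map, atlas, 3), 7)
  expect_error(roi_mean(map, atlas, 9), "absent")
  expect_warning(v <- roi_mean(map, atlas, 2), "no defined")
  expect_true(is.na(v))
})
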