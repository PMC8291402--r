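desk_cfg <- optimize_config(opening_kernel = c(19, 19, 19),
                            boxfilter_kernel = c(25, 25, 25),
                            downsample_factor = 2)

test_that("stripe correction removes periodic drift without moving anatomy", {
  # stripe-free volume is (nearly) untouched
  set.seed(1)
  v <- volume3d(array(100 + rnorm(16 * 64 * 16, 0, 2), c(16, 64, 16)))
  out <- correct_strips(v, 2, 33)
  expect_lt(max(abs(out$voxels - v$voxels)), 0.5)
  expect_lt(abs(mean(out$voxels) - mean(v$voxels)), 1e-9)

  # >= 90% suppression at the stripe frequency across periods 8..64
  for (period in c(8, 16, 32, 64)) {
    base <- volume3d(array(100, c(16, 512, 16)))
    d <- degrade(base, artifact_spec(20, period, 2, 0, 64, 0))
    cor <- correct_strips(d, 2, 3 * period + 1)
    supp <- 1 - fft_stripe_magnitude(cor, 2, period) /
      fft_stripe_magnitude(d, 2, period)
    expect_gt(supp, 0.90)
  }

  expect_error(correct_strips(v, 2, 4), "odd")
  expect_error(correct_strips(v, 1, 33), "exceeds")
})

test_that("background estimation flattens staining fields but keeps ramps", {
  # constant volume reproduces itself
  v <- volume3d(array(77, c(32, 48, 48)))
  bg <- estimate_background(v, desk_cfg)
  expect_lt(max(abs(bg$voxels - 77)), 1e-6)

  # thin bright cylinder vanishes from the reference
  m <- cylinder_mask(r = 2, length_um = 40, dims = c(32L, 48L, 64L),
                     center = c(24.5, 16.5))
  vox <- array(100, dim(m$voxels)); vox[m$voxels == 1] <- 200
  bg2 <- estimate_background(volume3d(vox), desk_cfg)
  expect_lt(max(abs(bg2$voxels - 100)), 1)

  # linear ramp is reproduced away from borders
  ramp <- sweep(array(0, c(32, 48, 96)), 3, seq(50, 150, length.out = 96), `+`)
  bg3 <- estimate_background(volume3d(ramp, dtype_range = c(0, 255)),
                             desk_cfg)
  interior <- bg3$voxels[9:24, 13:36, 25:72]
  expect_lt(max(abs(interior - ramp[9:24, 13:36, 25:72])), 5)

  expect_error(estimate_background(volume3d(array(1, c(8, 64, 64))),
                                   optimize_config(downsample_factor = 1)),
               "axis z")
})

test_that("flat-field correction reduces background variation", {
  v <- volume3d(array(runif(16^3, 90, 110), c(16, 16, 16)))
  bgc <- volume3d(array(50, c(16, 16, 16)))
  expect_equal(correct_background(v, bgc)$voxels, v$voxels)

  expect_equal(unique(as.vector(correct_background(v, v)$voxels)),
               mean(v$voxels), tolerance = 1e-9)

  # ramp background over a vessel phantom: CV of true-background voxels
  # drops by at least 80%
  spec <- phantom_spec(soma_density = 0, seed = 3)
  ras <- rasterize(generate_tree(spec), spec)
  vox <- sweep(ras$clean$voxels, 3, seq(-40, 40, length.out = 128), `+`)
  vr <- volume3d(vox)
  corr <- correct_background(vr, estimate_background(vr, desk_cfg))
  bgvox <- ras$truth_mask$voxels == 0
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(corr$voxels[bgvox]), 0.2 * cv(vr$voxels[bgvox]))

  expect_error(correct_background(v, volume3d(array(1, c(8, 8, 8)))),
               "shapes differ")
})

test_that("bilateral denoising preserves edges while averaging plateaus", {
  v <- volume3d(array(123, c(12, 12, 12)))
  expect_lt(max(abs(denoise_bilateral(v)$voxels - 123)), 1e-9)

  # noisy step edge: edge position fixed, plateau noise halved
  set.seed(2)
  step <- array(50, c(16, 16, 32))
  step[, , 17:32] <- 150
  noisy <- step + array(rnorm(length(step), 0, 5), dim(step))
  den <- denoise_bilateral(volume3d(noisy), sigma_spatial = 1,
                           sigma_range = 10)
  edge_before <- (noisy[, , 16] + noisy[, , 17]) / 2
  expect_true(all(den$voxels[, , 16] < 100) && all(den$voxels[, , 17] > 100))
  expect_lt(sd(den$voxels[, , 2:14] - 50), 0.5 * sd(noisy[, , 2:14] - 50))

  # single impulse attenuated by >= 60%
  imp <- array(100, c(9, 9, 9)); imp[5, 5, 5] <- 200
  di <- denoise_bilateral(volume3d(imp), sigma_spatial = 1, sigma_range = 60)
  expect_lt(di$voxels[5, 5, 5] - 100, 0.4 * 100)

  expect_error(denoise_bilateral(v, sigma_spatial = 0), "sigmas")
})

test_that("linear contrast stretch is the prescribed affine map", {
  vals <- array(rep(seq(10, 60, by = 1), length.out = 16^3), c(16, 16, 16))
  out <- enhance_contrast(volume3d(vals), c(0, 100))
  expect_equal(min(out$voxels), 0)
  expect_equal(max(out$voxels), 255)
  expect_equal(out$voxels[vals == 35][1], (35 - 10) / 50 * 255,
               tolerance = 1e-9)

  # full-range volume with (0, 100) percentiles: identity
  full <- array(seq(0, 255, length.out = 12^3), c(12, 12, 12))
  expect_equal(enhance_contrast(volume3d(full), c(0, 100))$voxels, full,
               tolerance = 1e-9)

  expect_error(enhance_contrast(volume3d(array(7, c(8, 8, 8)))),
               "degenerate")

  # monotone on the non-clipped range (property over random volumes)
  set.seed(3)
  for (i in 1:5) {
    v <- array(runif(10^3, 20, 200), c(10, 10, 10))
    s <- enhance_contrast(volume3d(v), c(5, 95))
    q <- quantile(v, c(.05, .95))
    inside <- v > q[1] & v < q[2]
    o <- order(v[inside])
    expect_true(all(diff(s$voxels[inside][o]) >= 0))
  }
})

test_that("the full optimization chain improves contrast and keeps geometry", {
  spec <- phantom_spec(seed = 2)
  ras <- rasterize(generate_tree(spec), spec)
  truth <- ras$truth_mask$voxels == 1
  deg <- degrade(ras$clean, artifact_spec(seed = 11))
  opt <- optimize_volume(deg, desk_cfg)

  mich <- function(v) {
    mv <- mean(v$voxels[truth]); mb <- mean(v$voxels[!truth])
    (mv - mb) / (mv + mb)
  }
  expect_gt(mich(opt), mich(deg))
  expect_s3_class(attr(opt, "log"), "data.frame")
  expect_equal(attr(opt, "log")$stage,
               c("input", "strips", "background", "denoise", "contrast"))

  # optimization does not destroy clean data: extraction Dice on the clean
  # volume is no worse than on the degraded-then-optimized one (- 0.02)
  d_clean <- dice(threshold_vessels(opt_clean <- optimize_volume(ras$clean,
                                                                 desk_cfg),
                                    "otsu", warn_raw = FALSE)$voxels == 1,
                  truth)
  d_opt <- dice(threshold_vessels(opt, "otsu", warn_raw = FALSE)$voxels == 1,
                truth)
  expect_gte(d_clean, d_opt - 0.02)

  # no geometric drift of a cylinder phantom through the whole chain
  cyl <- cylinder_mask(r = 3, length_um = 80, dims = c(48L, 64L, 96L),
                       center = c(32.5, 24.5))
  vox <- array(100, dim(cyl$voxels)); vox[cyl$voxels == 1] <- 200
  dc <- degrade(volume3d(vox), artifact_spec(seed = 12))
  oc <- optimize_volume(dc, desk_cfg)
  m_out <- clean_mask(threshold_vessels(oc, "otsu", warn_raw = FALSE), 27)
  expect_lt(max(abs(mask_centroid(m_out$voxels) -
                      mask_centroid(cyl$voxels))), 0.5)

  expect_error(optimize_volume(deg, desk_cfg,
                               stages = c("contrast", "strips", "background",
                                          "denoise")),
               "fixed")
})
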