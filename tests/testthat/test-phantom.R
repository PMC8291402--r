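test_that("tree generation is deterministic and respects the spec", {
  spec <- phantom_spec(seed = 11L)
  t1 <- generate_tree(spec)
  t2 <- generate_tree(spec)
  expect_identical(t1, t2)

  # unbranched single trunk
  solo <- phantom_spec(volume_shape = c(32, 32, 128), trunk_spacing = 100,
                       n_branch_levels = 0, comb_mode = FALSE, seed = 1)
  tr <- generate_tree(solo)
  expect_length(tr$segments, 1)
  expect_equal(tr$segments[[1]]$level, 1L)

  # structural invariants on a full tree
  ext <- rev(spec$volume_shape * spec$spacing)
  for (s in t1$segments) {
    expect_true(all(s$radius > 0))
    expect_true(all(s$points >= 0 & s$points <= rep(ext, each = nrow(s$points))))
    if (!is.na(s$parent)) {
      p <- t1$segments[[s$parent]]
      expect_equal(s$level, p$level + 1L)
      expect_lt(s$parent, s$id)  # parents precede children: acyclic
      # child starts on its parent's centerline
      d <- sqrt(rowSums((p$points - matrix(s$points[1, ], nrow(p$points), 3,
                                           byrow = TRUE))^2))
      expect_lt(min(d), 2.1)
    }
  }

  expect_error(generate_tree(phantom_spec(volume_shape = c(4, 4, 4),
                                          seed = 1)),
               "too small")
})

test_that("generated branch angles follow the requested law", {
  # deterministic angles: mean 60, sd 0, halved by the group effect
  spec <- phantom_spec(volume_shape = c(64, 128, 128), n_branch_levels = 1,
                       comb_mode = FALSE, branch_angle_mean = 60,
                       branch_angle_sd = 0, angle_scale = 0.5, seed = 3)
  ta <- tree_branch_angles(generate_tree(spec))
  expect_gt(nrow(ta), 5)
  expect_true(all(abs(ta$angle_deg - 30) < 0.1))

  # stochastic angles recover the generative mean
  spec2 <- phantom_spec(branch_angle_mean = 40, branch_angle_sd = 5,
                        comb_mode = FALSE, seed = 5)
  ta2 <- tree_branch_angles(generate_tree(spec2))
  expect_gt(nrow(ta2), 30)
  expect_lt(abs(mean(ta2$angle_deg) - 40), 3)

  # comb capillaries leave near-perpendicularly with sub-10-um diameters
  spec3 <- phantom_spec(n_branch_levels = 0, comb_mode = TRUE, seed = 2)
  tr3 <- generate_tree(spec3)
  combs <- Filter(function(s) s$level == 2L, tr3$segments)
  expect_gt(length(combs), 3)
  for (s in combs) expect_lt(max(2 * s$radius), 10)
  ta3 <- tree_branch_angles(tr3)
  expect_true(all(ta3$angle_deg > 75))
})

test_that("rasterization matches capsule geometry", {
  # straight cylinder: voxel count close to analytic pi r^2 L (+ end caps)
  pts <- seg_pts(c(28, 32.5, 32.5), c(228, 32.5, 32.5))
  m <- polyline_mask(pts, rep(3, nrow(pts)), c(64L, 64L, 256L))
  expect_lt(abs(sum(m$voxels) - pi * 9 * 200) / (pi * 9 * 200), 0.10)

  # empty tree: mask all zero, clean = tissue only
  spec <- phantom_spec(volume_shape = c(32, 48, 48), trunk_spacing = 100,
                       n_branch_levels = 0, comb_mode = FALSE, seed = 1)
  tr <- generate_tree(spec)
  tr$segments <- list()
  ras <- rasterize(tr, spec)
  expect_equal(sum(ras$truth_mask$voxels), 0)
  il <- spec$intensity_levels
  expect_true(all(ras$clean$voxels %in% c(il["parenchyma"], il["soma"])))

  # sub-voxel capillary still rasterizes as one connected path
  pts2 <- seg_pts(c(5, 5.3, 5.7), c(40, 28.2, 24.9), step = 1)
  m2 <- polyline_mask(pts2, rep(0.4, nrow(pts2)), c(32L, 32L, 48L))
  lab <- vascmorph:::.label26(m2$voxels)
  expect_equal(max(lab), 1L)
  expect_gt(sum(m2$voxels), 20)

  expect_error(rasterize(tr, spec, spacing = c(0, 1, 1)), "positive")
})

test_that("artifact degradation is additive, seeded and class-independent", {
  base <- volume3d(array(100, c(16, 64, 16)))
  null_art <- artifact_spec(strip_amplitude = 0, background_amplitude = 0,
                            noise_sd = 0)
  expect_equal(degrade(base, null_art)$voxels, base$voxels)

  # pure stripes: mean absolute deviation = 2A/pi
  stripes <- artifact_spec(strip_amplitude = 20, strip_period = 16,
                           strip_axis = 2, background_amplitude = 0,
                           noise_sd = 0)
  d <- degrade(base, stripes)
  expect_lt(abs(mean(abs(d$voxels - 100)) - 2 * 20 / pi) / (2 * 20 / pi),
            0.05)

  # determinism
  art <- artifact_spec(seed = 9)
  expect_identical(degrade(base, art)$voxels, degrade(base, art)$voxels)

  # independent substreams: changing the stripe settings leaves the
  # background + noise fields untouched
  a1 <- artifact_spec(strip_amplitude = 0, seed = 9)
  a2 <- artifact_spec(strip_amplitude = 20, seed = 9)
  d1 <- degrade(base, a1)
  d2 <- degrade(base, a2)
  i <- seq_len(dim(base$voxels)[2])
  stripe <- 20 * sin(2 * pi * (i - 1) / a2$strip_period)
  resid <- sweep(d2$voxels, 2, stripe, `-`)
  expect_lt(max(abs(resid - d1$voxels)), 1e-9)

  expect_error(artifact_spec(strip_period = 1), "strip_period")
  expect_error(artifact_spec(noise_sd = -1), "amplitudes")
})

test_that("analytic tree morphometry matches closed forms and is additive", {
  # hand-built tree: one straight cylinder r = 3, L = 200
  cyl <- list(id = 1L, parent = NA_integer_, level = 1L,
              points = seg_pts(c(28, 32, 32), c(228, 32, 32)),
              radius = rep(3, nrow(seg_pts(c(28, 32, 32), c(228, 32, 32)))))
  tree <- structure(list(nodes = NULL, segments = list(cyl)),
                    class = "vessel_tree")
  rep1 <- true_morphometry(tree, shape = c(64, 64, 256), spacing = c(1, 1, 1))
  V <- 64 * 64 * 256
  expect_equal(rep1$total_length, 200, tolerance = 1e-6)
  expect_equal(rep1$length_density, 200 / V * 1e3, tolerance = 1e-6)
  expect_equal(rep1$volume_fraction, 100 * pi * 9 * 200 / V, tolerance = 1e-6)
  expect_equal(rep1$mean_diameter, 6, tolerance = 1e-6)

  # additivity: two disjoint identical cylinders double length and volume
  cyl2 <- cyl; cyl2$id <- 2L
  cyl2$points <- cyl$points + matrix(rep(c(0, 0, 20), nrow(cyl$points)),
                                     ncol = 3, byrow = TRUE)
  tree2 <- tree; tree2$segments <- list(cyl, cyl2)
  rep2 <- true_morphometry(tree2, shape = c(64, 64, 256),
                           spacing = c(1, 1, 1))
  expect_equal(rep2$total_length, 2 * rep1$total_length)
  expect_equal(rep2$volume_fraction, 2 * rep1$volume_fraction,
               tolerance = 1e-9)
  expect_equal(rep2$mean_diameter, rep1$mean_diameter)
})

test_that("truth-mask volume fraction approaches the analytic fraction with finer sampling", {
  # isolated tube (no junction overlap): rasterized fraction converges
  spec <- phantom_spec(volume_shape = c(32, 48, 128), trunk_spacing = 100,
                       n_branch_levels = 0, comb_mode = FALSE,
                       soma_density = 0, seed = 2)
  tr <- generate_tree(spec)
  tm <- true_morphometry(tr)
  vf1 <- 100 * mean(rasterize(tr, spec)$truth_mask$voxels)
  vf05 <- 100 * mean(rasterize(tr, spec, shape = c(64, 96, 256),
                               spacing = c(0.5, 0.5, 0.5))$truth_mask$voxels)
  err1 <- abs(vf1 - tm$volume_fraction)
  err05 <- abs(vf05 - tm$volume_fraction)
  expect_lt(err05, err1 / 2 + 1e-6)
})
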