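test_that("a straight cylinder skeletonizes to one full-length centered segment", {
  m <- cylinder_mask(r = 3, length_um = 200)
  g <- skeletonize(m)
  expect_length(g$segments, 1)
  deg <- vascmorph:::node_degrees(g)
  expect_equal(sum(deg == 1), 2)
  expect_equal(sum(deg >= 3), 0)
  len <- sum(vapply(g$segments, vascmorph:::segment_length, numeric(1)))
  expect_lt(abs(len - 200), 4)

  expect_error(skeletonize(vessel_mask(array(0L, c(8, 8, 8)), c(1, 1, 1))),
               "empty")

  single <- array(0L, c(8, 8, 8)); single[4, 4, 4] <- 1L
  gd <- skeletonize(vessel_mask(single, c(1, 1, 1)))
  expect_true(isTRUE(attr(gd, "degenerate")))
})

test_that("junction topology and branch angles are recovered", {
  for (th in c(30, 60, 90)) {
    m <- y_junction_mask(th)
    g <- skeletonize(m)
    deg <- vascmorph:::node_degrees(g)
    expect_equal(sum(deg >= 3), 1)
    expect_length(g$segments, 3)
    g <- measure_diameters(g, m)
    minx <- vapply(g$segments, function(s) min(s$points[, 1]), numeric(1))
    g <- assign_branch_levels(g, root = which.min(minx))
    ba <- subset(branch_angles(g), !continuation)
    expect_equal(nrow(ba), 2)
    expect_true(all(abs(ba$angle_deg - th) < 5))
  }
})

test_that("local diameters follow the distance transform of the mask", {
  m <- cylinder_mask(r = 3, length_um = 200)
  g <- measure_diameters(skeletonize(m), m)
  d <- unlist(lapply(g$segments, `[[`, "diameter"))
  expect_lt(abs(mean(d) - 6), 0.5)

  # ball: maximum diameter ~ 2R at the center
  b <- ball_mask(R = 10, n = 28L)
  e <- vascmorph:::.edt3d(b$voxels, c(1, 1, 1))
  expect_lt(abs(2 * max(e) - 20), 1.5)

  # two tandem radii: local diameters near 4 in the thin half and 8 in
  # the thick half, away from the step
  pts <- rbind(seg_pts(c(10, 24.5, 24.5), c(60, 24.5, 24.5)),
               seg_pts(c(60, 24.5, 24.5), c(110, 24.5, 24.5)))
  r <- c(rep(2, 26), rep(4, 26))
  mm <- polyline_mask(pts, r, c(48L, 48L, 120L))
  gg <- measure_diameters(skeletonize(mm), mm)
  allP <- do.call(rbind, lapply(gg$segments, `[[`, "points"))
  allD <- unlist(lapply(gg$segments, `[[`, "diameter"))
  thin <- allP[, 1] > 15 & allP[, 1] < 50
  thick <- allP[, 1] > 70 & allP[, 1] < 105
  expect_lt(abs(mean(allD[thin]) - 4), 0.6)
  expect_lt(abs(mean(allD[thick]) - 8), 0.6)
})

test_that("branch levels follow the generation structure", {
  # single segment
  g1 <- make_graph(list(seg_pts(c(0, 0, 0), c(30, 0, 0))))
  g1 <- assign_branch_levels(g1)
  expect_equal(g1$segments[[1]]$level, 1L)

  # perfect binary tree of depth 4: levels 1..5 with counts 1, 2, 4, 8, 16
  bt <- assign_branch_levels(binary_tree_graph(depth = 4),
                             root = 1L)
  lv <- vapply(bt$segments, `[[`, integer(1), "level")
  expect_equal(as.integer(table(lv)), c(1L, 2L, 4L, 8L, 16L))

  # synthetic analytic angles: child at 60 degrees, child antiparallel
  g2 <- make_graph(list(seg_pts(c(0, 0, 0), c(40, 0, 0)),
                        seg_pts(c(40, 0, 0),
                                c(40 + 30 * cos(pi / 3), 30 * sin(pi / 3), 0)),
                        seg_pts(c(40, 0, 0), c(10, 0, 1e-9))))
  g2 <- assign_branch_levels(g2, root = 1L)
  ba <- branch_angles(g2)
  ba <- ba[order(ba$child), ]
  expect_equal(ba$angle_deg[ba$child == 2], 60, tolerance = 0.5)
  expect_equal(ba$angle_deg[ba$child == 3], 180, tolerance = 0.5)
})

test_that("measured branch levels and angles track the generative tree", {
  # sparse, well-resolved single-trunk phantoms: the measured mean branch
  # angle reproduces the generative mean
  gm <- mm <- numeric(0)
  match_lvl <- 0L; match_tot <- 0L
  for (seed in 1:4) {
    spec <- phantom_spec(volume_shape = c(48, 64, 256), trunk_spacing = 60,
                         trunk_radius = 3.5, radius_decay = 0.7,
                         n_branch_levels = 1, branch_angle_mean = 40,
                         branch_angle_sd = 5, comb_mode = FALSE,
                         soma_density = 0, seed = seed)
    tr <- generate_tree(spec)
    ras <- rasterize(tr, spec)
    m <- vessel_mask(ras$truth_mask$voxels, spec$spacing)
    g <- assign_branch_levels(measure_diameters(skeletonize(m), m))
    bb <- subset(branch_angles(g), !continuation)
    ta <- tree_branch_angles(tr)
    gm <- c(gm, mean(ta$angle_deg)); mm <- c(mm, mean(bb$angle_deg))
    # matched children carry the generative level (2)
    tpos <- t(vapply(ta$child, function(id) tr$segments[[id]]$points[1, ],
                     numeric(3)))
    for (i in seq_len(nrow(bb))) {
      s <- g$segments[[bb$child[i]]]
      att <- if (s$node_from == bb$node[i]) s$points[1, ] else
        s$points[nrow(s$points), ]
      if (min(sqrt(rowSums(sweep(tpos, 2, att)^2))) < 4) {
        match_tot <- match_tot + 1L
        if (bb$level[i] == 2L) match_lvl <- match_lvl + 1L
      }
    }
  }
  expect_lt(abs(mean(mm - gm)), 2)
  expect_gt(match_lvl / match_tot, 0.95)
})

test_that("regional morphometry matches analytic oracles and partitions exactly", {
  m <- cylinder_mask(r = 3, length_um = 200)
  g <- assign_branch_levels(measure_diameters(skeletonize(m), m))
  rep1 <- region_morphometry(g, m)
  V <- prod(dim(m$voxels))
  expect_lt(abs(rep1$length_density - 200 / V * 1e3) / (200 / V * 1e3), 0.05)
  expect_lt(abs(rep1$volume_fraction - 100 * pi * 9 * 200 / V) /
              (100 * pi * 9 * 200 / V), 0.10)
  expect_equal(rep1$n_segments, 1)
  expect_equal(sum(rep1$diameter_histogram), rep1$n_segments)

  # all-small segments: everything below 5 um
  small <- morphometry_report(segment_mean_diameters = rep(2, 7))
  expect_equal(small$pct_below_5um, 100)
  expect_equal(sum(small$diameter_histogram), 7)

  # partition additivity is exact
  spec <- phantom_spec(seed = 4)
  ras <- rasterize(generate_tree(spec), spec)
  mm2 <- vessel_mask(ras$truth_mask$voxels, spec$spacing)
  gg <- assign_branch_levels(measure_diameters(skeletonize(mm2), mm2))
  labs <- array(1L, dim(mm2$voxels)); labs[, , 65:128] <- 2L
  rmask <- region_mask(labs, spec$spacing, c(left = 1, right = 2))
  rl <- region_morphometry(gg, mm2, rmask, "left")
  rr <- region_morphometry(gg, mm2, rmask, "right")
  rw <- region_morphometry(gg, mm2)
  expect_equal(rl$total_length + rr$total_length, rw$total_length,
               tolerance = 1e-9)
  vox_l <- rl$volume_fraction * sum(labs == 1)
  vox_r <- rr$volume_fraction * sum(labs == 2)
  expect_equal(vox_l + vox_r, rw$volume_fraction * length(labs),
               tolerance = 1e-9)
  expect_error(region_morphometry(gg, mm2, rmask, "CA3"), "available")

  # isotropic shrinkage correction: lengths and diameters scale by
  # 1/(1-s), the length density by (1-s)^2, the volume fraction not at all
  s <- 0.259
  rs <- region_morphometry(gg, mm2, shrinkage_correction = s)
  expect_equal(rs$total_length, rw$total_length / (1 - s))
  expect_equal(rs$mean_diameter, rw$mean_diameter / (1 - s))
  expect_equal(rs$length_density, rw$length_density * (1 - s)^2)
  expect_equal(rs$volume_fraction, rw$volume_fraction)
})

test_that("subtree extraction re-roots levels", {
  bt <- assign_branch_levels(binary_tree_graph(depth = 4), root = 1L)
  whole <- extract_subtree(bt, 1)
  expect_length(whole$segments, length(bt$segments))

  sub <- extract_subtree(bt, 1, max_level = 2)
  expect_length(sub$segments, 3)

  # re-rooting at an internal segment renumbers levels from 1
  mid <- which(vapply(bt$segments, `[[`, integer(1), "level") == 2)[1]
  sub2 <- extract_subtree(bt, mid)
  lv <- vapply(sub2$segments, `[[`, integer(1), "level")
  expect_equal(min(lv), 1L)
  expect_equal(max(lv), 4L)
})

test_that("measured morphometry scales with the generative parameters", {
  measure <- function(spec, tree = generate_tree(spec), shape = NULL) {
    ras <- if (is.null(shape)) rasterize(tree, spec) else
      rasterize(tree, spec, shape = shape)
    m <- vessel_mask(ras$truth_mask$voxels, spec$spacing)
    g <- assign_branch_levels(measure_diameters(skeletonize(m), m))
    region_morphometry(g, m)
  }
  # doubling all radii of a fixed tree doubles the mean diameter and
  # (nearly) quadruples the volume fraction
  spec <- phantom_spec(volume_shape = c(96, 160, 160), soma_density = 0,
                       seed = 3)
  tr <- generate_tree(spec)
  tr2 <- tr
  for (i in seq_along(tr2$segments))
    tr2$segments[[i]]$radius <- 2 * tr2$segments[[i]]$radius
  rA <- measure(spec, tr)
  rB <- measure(spec, tr2)
  expect_lt(abs(rB$mean_diameter / rA$mean_diameter - 2), 0.1)
  expect_lt(abs(rB$volume_fraction / rA$volume_fraction - 4), 0.4)

  # a global diameter scaling of 0.85 is recovered as a 0.85 +- 0.05
  # mean-diameter ratio (five seeds)
  ratios <- vapply(1:5, function(s) {
    a <- measure(phantom_spec(seed = s))
    b <- measure(phantom_spec(seed = s, diameter_scale = 0.85))
    b$mean_diameter / a$mean_diameter
  }, numeric(1))
  expect_true(all(abs(ratios - 0.85) < 0.05))
})
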