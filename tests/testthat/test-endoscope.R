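test_that("iso-surface meshes enclose the right volume with valid topology", {
  b <- ball_mask(R = 10, n = 28L)
  mesh <- mesh_vessel(b)
  vol <- mesh_signed_volume(mesh)
  expect_lt(abs(vol - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  expect_true(all(abs(sqrt(rowSums(mesh$normals^2)) - 1) < 1e-6))

  # a single voxel still meshes to a small closed positive-volume surface
  single <- array(0L, c(8, 8, 8)); single[4, 4, 4] <- 1L
  ms <- mesh_vessel(vessel_mask(single, c(1, 1, 1)))
  expect_gt(mesh_signed_volume(ms), 0)

  # cylinder surface is a closed genus-0 manifold (Euler characteristic 2)
  cyl <- cylinder_mask(r = 5, length_um = 60, dims = c(32L, 32L, 80L),
                       center = c(16.5, 16.5))
  mc <- mesh_vessel(cyl)
  edges <- rbind(mc$triangles[, 1:2], mc$triangles[, 2:3],
                 mc$triangles[, c(3, 1)])
  E <- nrow(unique(t(apply(edges, 1, sort))))
  expect_equal(nrow(mc$vertices) - E + nrow(mc$triangles), 2)

  expect_error(mesh_vessel(vessel_mask(array(0L, c(6, 6, 6)), c(1, 1, 1))),
               "empty")
})

test_that("the lumen-distance field reads the local diameter", {
  # sphere R = 20: chords through the center, median ~ 2R
  sp <- normal_distance_field(mesh_vessel(ball_mask(R = 20, n = 48L)),
                              max_ray_um = 100)
  expect_lt(abs(median(sp$scalar, na.rm = TRUE) - 40) / 40, 0.05)
  ok <- sp$scalar[!is.na(sp$scalar)]
  expect_true(all(ok > 0 & ok <= 100))

  # long cylinder r = 5: mid-section scalar ~ 10
  cyl <- cylinder_mask(r = 5, length_um = 80, dims = c(32L, 32L, 100L),
                       center = c(16.5, 16.5))
  mc <- normal_distance_field(mesh_vessel(cyl), max_ray_um = 100)
  mid <- mc$vertices[, 1] > 30 & mc$vertices[, 1] < 70
  expect_lt(abs(median(mc$scalar[mid], na.rm = TRUE) - 10) / 10, 0.10)

  # open spherical cap: rays from the cut rim escape through the opening
  hemi <- mesh_vessel(ball_mask(R = 12, n = 32L))
  zcut <- 21
  keep <- apply(hemi$triangles, 1, function(tr)
    all(hemi$vertices[tr, 3] >= zcut))
  hemi$triangles <- hemi$triangles[keep, , drop = FALSE]
  hemi <- normal_distance_field(hemi, max_ray_um = 60)
  rim <- abs(hemi$vertices[, 3] - zcut) < 1.5 &
    rowSums(abs(hemi$normals)) > 0
  expect_gt(mean(is.na(hemi$scalar[rim])), 0.5)

  # tubes across the reported diameter range still mesh and measure
  for (dnom in c(2, 30)) {
    n <- max(24L, as.integer(2 * dnom) + 16L)
    tube <- cylinder_mask(r = dnom / 2, length_um = 3 * dnom,
                          dims = c(n, n, as.integer(4 * dnom)),
                          center = c(n / 2 + 0.5, n / 2 + 0.5))
    mt <- normal_distance_field(mesh_vessel(tube), max_ray_um = 4 * dnom)
    expect_gt(mesh_signed_volume(mt), 0)
    med <- median(mt$scalar, na.rm = TRUE)
    expect_gt(med, dnom / 2)
    expect_lt(med, 2 * dnom)
  }
})

test_that("camera paths are lumen-centered minimal-rotation frames", {
  # straight centerline: constant frame
  g <- make_graph(list(seg_pts(c(5, 16, 16), c(70, 16, 16))))
  cp <- camera_path(g, 1, step_um = 2, smooth_window_um = 4)
  expect_true(all(abs(cp$vx - 1) < 1e-9))
  expect_equal(sd(cp$ux), 0)
  expect_true(all(abs(cp$ux * cp$vx + cp$uy * cp$vy + cp$uz * cp$vz) < 1e-9))

  # planar 90-degree arc: parallel transport accumulates < 1 degree twist
  th <- seq(0, pi / 2, length.out = 200)
  arc <- cbind(50 * cos(th), 50 * sin(th), rep(0, 200))
  ga <- make_graph(list(arc))
  cpa <- camera_path(ga, 1, step_um = 1, smooth_window_um = 3)
  u0 <- as.numeric(cpa[1, c("ux", "uy", "uz")])
  u1 <- as.numeric(cpa[nrow(cpa), c("ux", "uy", "uz")])
  # in-plane curves transport the plane normal onto itself
  twist <- acos(pmin(1, abs(sum(u0 * u1)))) * 180 / pi
  expect_lt(twist, 1)

  # all poses inside the lumen of a straight tube
  tube <- cylinder_mask(r = 4, length_um = 60, dims = c(32L, 32L, 80L),
                        center = c(16.5, 16.5))
  gt <- skeletonize(tube)
  cpt <- camera_path(gt, 1, step_um = 2, smooth_window_um = 6, mask = tube)
  expect_true(all(cpt$inside))

  expect_error(camera_path(make_graph(list(
    seg_pts(c(0, 0, 0), c(10, 0, 0)),
    seg_pts(c(50, 50, 0), c(60, 50, 0)))), c(1, 2)), "not connected")
})

test_that("endoscopy export round-trips and is byte-stable", {
  tube <- cylinder_mask(r = 4, length_um = 40, dims = c(24L, 24L, 60L),
                        center = c(12.5, 12.5))
  mesh <- normal_distance_field(mesh_vessel(tube), max_ray_um = 50)
  path <- camera_path(skeletonize(tube), 1, step_um = 2)
  d1 <- file.path(tempdir(), "endo1")
  d2 <- file.path(tempdir(), "endo2")
  f1 <- export_endoscopy(mesh, path, d1)
  f2 <- export_endoscopy(mesh, path, d2)

  back <- read_ply(f1[["mesh"]])
  expect_equal(nrow(back$vertices), nrow(mesh$vertices))
  expect_equal(back$scalar, mesh$scalar, tolerance = 1e-5)
  man <- jsonlite::read_json(f1[["manifest"]])
  expect_equal(man$n_poses, nrow(path))

  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
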