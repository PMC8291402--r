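test_that("the pooled t-test matches closed forms and an integration oracle", {
  tt <- ttest_unpaired(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.2878, tolerance = 1e-3)

  # mirrored samples with equal means
  expect_equal(ttest_unpaired(c(-1, 0, 1), c(1, 0, -1))$p, 1)
  tt2 <- ttest_unpaired(c(5, 7, 9), c(5, 7, 9))
  expect_equal(tt2$t, 0)
  expect_equal(tt2$p, 1)

  expect_error(ttest_unpaired(c(1, 1), c(1, 1)), "zero")
  expect_error(ttest_unpaired(1, c(1, 2)), "at least 2")

  # p-value agrees with direct integration of the t density to 6 d.p.
  set.seed(10)
  for (i in 1:100) {
    x <- rnorm(sample(3:8, 1)); y <- rnorm(sample(3:8, 1), sd = 1.5)
    tt <- ttest_unpaired(x, y)
    p_int <- 2 * integrate(function(u) dt(u, tt$df), abs(tt$t), Inf,
                           rel.tol = 1e-10)$value
    expect_equal(tt$p, p_int, tolerance = 1e-6)
    # and with the standard implementation as a cross-check
    ref <- t.test(x, y, var.equal = TRUE)
    expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(tt$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the type-I error rate is controlled at the nominal level", {
  set.seed(11)
  n_rep <- 2000
  flags <- vapply(seq_len(n_rep), function(i) {
    ttest_unpaired(rnorm(3, 10, 1), rnorm(3, 10, 1))$p < 0.05
  }, logical(1))
  expect_gt(mean(flags), 0.03)
  expect_lt(mean(flags), 0.07)
})

test_that("a 15-20% diameter reduction is detected at realistic dispersion", {
  # n = 3 per group, within-group CV 5%: power >= 90% over 20 replicates
  set.seed(12)
  hits <- vapply(1:20, function(i) {
    wt <- rnorm(3, 3.8, 0.19)
    ad <- rnorm(3, 3.8 * 0.82, 0.19 * 0.82)
    ttest_unpaired(wt, ad)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

fake_subject <- function(d, vf, ld, pct, angles = NULL) {
  rep <- morphometry_report(mean_diameter = d, volume_fraction = vf,
                            length_density = ld,
                            segment_mean_diameters = numeric(0))
  rep$pct_below_5um <- pct
  list(reports = list(whole = rep), angles = angles)
}

test_that("region comparison reports one row per metric with s.e.m. dispersion", {
  g1 <- list(fake_subject(3.8, 1.8, 1.5, 70), fake_subject(3.9, 1.9, 1.6, 68),
             fake_subject(3.7, 1.7, 1.4, 72))
  g2 <- list(fake_subject(3.1, 1.1, 1.5, 95), fake_subject(3.0, 1.2, 1.4, 97),
             fake_subject(3.2, 1.0, 1.6, 96))
  study <- group_study(list(WT = g1, AD = g2))
  cmp <- compare_regions(study)
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$dispersion == "sem"))
  md <- cmp[cmp$metric == "mean_diameter", ]
  expect_equal(md$direction, "down")
  expect_true(md$significant)
  expect_equal(md$df, 4)
  pct <- cmp[cmp$metric == "pct_below_5um", ]
  expect_equal(pct$direction, "up")

  # two identical groups: t = 0, p = 1, nothing flagged
  same <- group_study(list(A = g1, B = g1))
  cs <- compare_regions(same)
  expect_true(all(cs$p == 1))
  expect_true(!any(cs$significant))

  expect_error(group_study(list(WT = g1[1], AD = g2)), "at least 2")
  expect_error(group_study(list(WT = g1, AD = g2), alpha = 1.2), "alpha")
})

test_that("angle-by-level comparison aggregates per subject and filters sparse levels", {
  mk_angles <- function(shift = 0, n = 8) {
    do.call(rbind, lapply(1:3, function(lv)
      data.frame(node = 1, parent = 1, child = 1, level = lv,
                 continuation = FALSE,
                 angle_deg = rnorm(n, 45 - 5 * lv + shift, 2))))
  }
  set.seed(13)
  g1 <- lapply(1:3, function(i) fake_subject(3.8, 1.8, 1.5, 70, mk_angles(0)))
  g2 <- lapply(1:3, function(i) fake_subject(3.1, 1.1, 1.4, 95,
                                             mk_angles(-8)))
  study <- group_study(list(WT = g1, AD = g2))
  ac <- compare_angle_by_level(study, max_level = 8)
  expect_equal(ac$level, 1:3)       # levels beyond the data are absent
  expect_true(all(ac$direction == "down"))
  expect_true(all(ac$dispersion == "sd"))

  # a level with too few branches in one subject is dropped for that subject
  g1b <- g1
  g1b[[1]]$angles <- rbind(g1b[[1]]$angles,
                           data.frame(node = 1, parent = 1, child = 1,
                                      level = 5, continuation = FALSE,
                                      angle_deg = 30))
  study_b <- group_study(list(WT = g1b, AD = g2))
  ac_b <- compare_angle_by_level(study_b, max_level = 8, min_branches = 3)
  excl <- attr(ac_b, "excluded")
  expect_true(!is.null(excl) && any(excl$level == 5))
  expect_false(5 %in% ac_b$level)
})

test_that("the end-to-end pipeline is deterministic and resumable", {
  small <- function(dir) pipeline_config(
    out_dir = dir, seed = 42L,
    groups = list(WT = list(n = 2L, spec = list()),
                  AD = list(n = 2L, spec = list(diameter_scale = 0.8,
                                                angle_scale = 0.75))),
    phantom = list(volume_shape = c(48, 96, 96), n_branch_levels = 2))
  d1 <- file.path(tempdir(), "pipe1")
  d2 <- file.path(tempdir(), "pipe2")
  r1 <- run_pipeline(small(d1))
  r2 <- run_pipeline(small(d2))
  f1 <- sort(list.files(d1, pattern = "subject_.*json", full.names = TRUE))
  f2 <- sort(list.files(d2, pattern = "subject_.*json", full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_true(file.exists(file.path(d1, "region_comparison.csv")))

  # resume: existing subjects are loaded, comparisons unchanged
  cfg <- small(d1); cfg$resume <- TRUE
  r3 <- run_pipeline(cfg)
  st <- vapply(r3$manifest$subjects, `[[`, character(1), "status")
  expect_true(all(st == "resumed"))
  expect_equal(r3$region_comparison$p, r1$region_comparison$p,
               tolerance = 1e-9)

  # a failing stage is recorded in the manifest before the error surfaces
  bad <- small(file.path(tempdir(), "pipe_bad"))
  bad$optimize <- list(opening_kernel = c(301, 301, 301),
                       downsample_factor = 1L)
  expect_error(run_pipeline(bad), "failed at stage 'optimize'")
  man <- jsonlite::read_json(file.path(tempdir(), "pipe_bad",
                                       "manifest.json"))
  expect_equal(man$subjects$WT_01$status, "failed")
  expect_equal(man$subjects$WT_01$stage, "optimize")
})
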