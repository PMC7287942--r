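test_that("frozen skeleton (zero step SD) yields exactly zero features", {
  ch <- tiny_cohort(seed = 2, n_asd = 2, n_td = 2, base_step_sd = 0,
                    p_drop = 0)
  tab <- build_feature_table(ch, joints = "head", segments = "V")
  expect_equal(max(abs(tab$values)), 0)
})

test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_asd = 2, n_td = 2,
                       schedule = segment_schedule(duration_factor = 0.02),
                       seed = 9)
  a <- generate_recording(cfg, "s", "ASD", seed = 123)
  b <- generate_recording(cfg, "s", "ASD", seed = 123)
  expect_identical(a$frames, b$frames)

  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$recordings[["TD01"]]$frames, c2$recordings[["TD01"]]$frames)
  expect_identical(c1$subjects, c2$subjects)
})

test_that("cohort counts and manifest follow the configuration", {
  ch <- tiny_cohort(seed = 5, n_asd = 3, n_td = 4)
  expect_length(ch$recordings, 7)
  expect_equal(sum(ch$subjects$group == "ASD"), 3)
  expect_equal(sum(ch$subjects$group == "TD"), 4)
  expect_identical(names(ch$recordings), ch$subjects$subject_id)
})

test_that("mean step norm approaches the chi-3 closed form", {
  # ~2500 frames at sd 0.01/axis; fixed subject multiplier
  cfg <- cohort_config(n_asd = 1, n_td = 1, base_step_sd = 0.01,
                       subject_sdlog = 0, p_drop = 0,
                       schedule = segment_schedule(duration_factor = 0.1),
                       seed = 31)
  rec <- generate_recording(cfg, "s", "TD", seed = 31)
  j3d <- recording_to_3d(rec, cfg$cam)
  d <- joint_displacements(j3d[["8"]])
  expect_equal(mean(d), expected_step_norm(0.01), tolerance = 0.03)
  expect_equal(expected_step_norm(1), 1.595769, tolerance = 1e-6)
})

test_that("confidence dropout matches its nominal probability", {
  cfg <- cohort_config(n_asd = 1, n_td = 1, p_drop = 0.1,
                       schedule = segment_schedule(duration_factor = 0.05),
                       seed = 17)
  rec <- generate_recording(cfg, "s", "TD", seed = 17)
  cc <- as.matrix(rec$frames[, grep("_c$", names(rec$frames))])
  frac <- mean(cc < 0.5)
  n <- length(cc)
  expect_lt(abs(frac - 0.1), 4 * sqrt(0.1 * 0.9 / n))
  # retained confidences stay above the filter
  expect_true(all(cc[cc >= 0.5] >= 2 * cfg$conf_mean - 1))
})

test_that("null cohorts are exchangeable: joint test rejects at ~5%", {
  reject <- logical(200)
  for (i in seq_along(reject)) {
    ch <- tiny_cohort(seed = 5000 + i, n_asd = 10, n_td = 10,
                      duration_factor = 0.02)
    tab <- build_feature_table(ch, joints = 15, segments = "V")
    reject[i] <- compare_joint(tab, 15, "V")$p < 0.05
  }
  rate <- mean(reject)
  # exact test at n = 10/10: attainable level just under 0.05
  expect_lt(rate, 0.10)
  expect_gt(rate, 0.005)
})

test_that("reported-effects preset elevates affected joints in the ASD group", {
  ch <- tiny_cohort(seed = 77, n_asd = 10, n_td = 10, duration_factor = 0.05,
                    effect_map = effect_preset("reported"))
  tab <- build_feature_table(ch, joints = "head",
                             segments = c("V", "VA", "VAO"))
  cmp <- joint_group_tests(tab)
  expect_true(all(cmp$median_asd > cmp$median_td))
  expect_true(all(cmp$direction == "ASD>TD"))
  # an unaffected part stays exchangeable in a stimulus it is not mapped to
  tab2 <- build_feature_table(ch, joints = "feet", segments = "VAO")
  cmp2 <- joint_group_tests(tab2)
  expect_true(all(cmp2$p > 0.05))
})
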