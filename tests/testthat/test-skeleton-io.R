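test_that("pose streams parse, validate, and reject malformed input", {
  sch <- segment_schedule(duration_factor = 0.01)
  fr <- flat_frames(c(0, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pose_stream(subject_recording("s1", "ASD", fr, sch), path)

  rec <- read_pose_stream(path, sch, "s1", "ASD")
  expect_s3_class(rec, "subject_recording")
  expect_equal(nrow(rec$frames), 2)
  expect_equal(rec$group, "ASD")

  # a file carrying only 24 joints is a format error
  short <- fr[, 1:(1 + 24 * 4)]
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(short, p2, row.names = FALSE)
  expect_error(read_pose_stream(p2, sch, "s1", "ASD"), "format error")

  # empty file
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(kinemarker:::pose_columns(), collapse = ","), p3)
  expect_error(read_pose_stream(p3, sch, "s1", "ASD"), "empty-input")

  # non-monotone timestamps are rejected at validation
  expect_error(subject_recording("s1", "ASD", flat_frames(c(0.5, 0)), sch),
               "increasing")
})

test_that("write/read round trip is exact for both dialects, and reading sorts", {
  cfg <- cohort_config(n_asd = 1, n_td = 1,
                       schedule = segment_schedule(duration_factor = 0.01),
                       seed = 3)
  rec <- generate_recording(cfg, "s1", "ASD", seed = 11)
  for (ext in c(".csv", ".jsonl")) {
    path <- withr::local_tempfile(fileext = ext)
    write_pose_stream(rec, path)
    back <- read_pose_stream(path, cfg$schedule, "s1", "ASD")
    expect_equal(back$frames, rec$frames, tolerance = 0)
  }

  # shuffled rows come back in timestamp order with identical features
  path <- withr::local_tempfile(fileext = ".csv")
  shuffled <- rec
  set.seed(4)
  shuffled$frames <- rec$frames[sample(nrow(rec$frames)), ]
  txt <- utils::read.csv({write_pose_stream(rec, path); path}, check.names = FALSE)
  utils::write.csv(txt[sample(nrow(txt)), ], path, row.names = FALSE)
  sorted <- read_pose_stream(path, cfg$schedule, "s1", "ASD")
  t1 <- build_feature_table(list(sorted), joints = "head", segments = "V")
  t2 <- build_feature_table(list(rec), joints = "head", segments = "V")
  expect_equal(t1$values, t2$values)
})

test_that("pinhole back-projection follows the stated closed form", {
  cam <- camera_model(fx = 600, fy = 600, cx = 424, cy = 240)
  joints <- data.frame(u = rep(cam$cx, 25), v = rep(cam$cy, 25),
                       z = 2, c = 0.9)

  # principal-point ray
  p <- project_to_3d(joints, cam)
  expect_equal(p$X, rep(0, 25))
  expect_equal(p$Y, rep(0, 25))
  expect_equal(p$Z, rep(2, 25))
  expect_equal(p$c, rep(0.9, 25))

  # degenerate depth collapses to the origin
  joints$z <- 0; joints$u <- 999; joints$v <- -50
  p0 <- project_to_3d(joints, cam)
  expect_equal(unlist(p0[, c("X", "Y", "Z")]), rep(0, 75), ignore_attr = TRUE)

  # one focal length to the right of the principal point at z = 1.5
  joints$u <- cam$cx + cam$fx; joints$v <- cam$cy; joints$z <- 1.5
  p1 <- project_to_3d(joints, cam)
  expect_equal(p1$X, rep(1.5, 25))
  expect_equal(p1$Y, rep(0, 25))

  # linear in z at fixed (u, v)
  joints$u <- 700; joints$v <- 100
  joints$z <- 1
  a <- project_to_3d(joints, cam)
  joints$z <- 3
  b <- project_to_3d(joints, cam)
  expect_equal(b$X, 3 * a$X)
  expect_equal(b$Y, 3 * a$Y)

  joints$z <- -1
  expect_error(project_to_3d(joints, cam), "negative depth")
})

test_that("segmentation uses half-open intervals and partitions retained frames", {
  sch <- segment_schedule()  # 840 s, six segments
  fr <- flat_frames(0:839)   # uniform 1 Hz
  rec <- subject_recording("s", "TD", fr, sch)
  segs <- segment_recording(rec, quiet = TRUE)

  expect_equal(vapply(segs, nrow, integer(1)),
               c(BL_V = 120L, V = 160L, BL_VA = 120L, VA = 160L,
                 BL_VAO = 120L, VAO = 160L))
  expect_equal(attr(segs, "dropped") + sum(vapply(segs, nrow, integer(1))),
               nrow(fr))

  # frame exactly at a segment start belongs to it; at the end it does not
  v <- sch[sch$label == "V", ]
  expect_true(v$start %in% segs$V$t)
  expect_false(v$end %in% segs$V$t)
  expect_true(v$end %in% segs$BL_VA$t)
})

test_that("body-part partition matches the analysis grouping", {
  expect_equal(body_part_joints("head"), c(15L, 16L, 17L, 18L))
  expect_equal(body_part_joints("trunk"), c(1L, 8L))
  expect_equal(body_part_joints("arms"), 2:7)
  expect_equal(body_part_joints("legs"), 9:14)
  expect_equal(body_part_joints("feet"), 19:24)
  # nose is excluded from "all" unless asked for
  expect_false(0L %in% body_part_joints("all"))
  expect_equal(length(body_part_joints("all")), 24L)
  expect_true(0L %in% body_part_joints("all", include_nose = TRUE))
  expect_error(body_part_joints(25), "joint ids")
})
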