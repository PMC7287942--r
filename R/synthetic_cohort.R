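# Synthetic two-group cohorts of skeleton recordings.
#
# Each joint follows an anchored Gaussian random walk in 3D camera
# coordinates; the per-axis step SD is base_step_sd times a multiplicative
# factor lambda(group, joint, segment). The walk makes the feature the
# analysis extracts -- mean inter-frame displacement -- available in closed
# form: an isotropic 3D Gaussian step with per-axis SD sigma has expected
# norm sigma * sqrt(2) * gamma(2) / gamma(3/2) = 1.5958 sigma (chi
# distribution, 3 df).

#' Expected step norm of an isotropic 3D Gaussian walk
#'
#' The chi-3 mean: a step with i.i.d. `N(0, sigma^2)` components on three
#' axes has expected Euclidean norm `sigma * sqrt(2) * gamma(2) / gamma(3/2)
#' = 1.5958 sigma`.
#'
#' @param sigma Per-axis step standard deviation.
#' @return Expected step norm, same units as `sigma`.
#' @export
expected_step_norm <- function(sigma = 1) {
  sigma * sqrt(2) * gamma(2) / gamma(1.5)
}

# Static anchor pose: a standing child ~2 m from the camera, camera frame
# (X right, Y down, Z away). Values are plausible, not calibrated; only the
# walk around them carries signal.
body25_anchor <- function(distance = 2) {
  a <- matrix(0, nrow = 25, ncol = 3, dimnames = list(NULL, c("X", "Y", "Z")))
  a[, 3] <- distance
  xy <- rbind(
    c(0.00, -0.65), c(0.00, -0.50),                  # 0 nose, 1 neck
    c(-0.15, -0.50), c(-0.20, -0.30), c(-0.22, -0.10), # 2-4 R shoulder/elbow/wrist
    c(0.15, -0.50), c(0.20, -0.30), c(0.22, -0.10),    # 5-7 L shoulder/elbow/wrist
    c(0.00, -0.05),                                    # 8 mid hip
    c(-0.10, -0.05), c(-0.11, 0.30), c(-0.12, 0.60),   # 9-11 R hip/knee/ankle
    c(0.10, -0.05), c(0.11, 0.30), c(0.12, 0.60),      # 12-14 L hip/knee/ankle
    c(-0.03, -0.68), c(0.03, -0.68),                   # 15-16 eyes
    c(-0.08, -0.66), c(0.08, -0.66),                   # 17-18 ears
    c(0.14, 0.68), c(0.16, 0.68), c(0.10, 0.64),       # 19-21 L toes/heel
    c(-0.14, 0.68), c(-0.16, 0.68), c(-0.10, 0.64)     # 22-24 R toes/heel
  )
  a[, 1:2] <- xy
  a
}

#' Synthetic cohort configuration
#'
#' Parameters of the two-group cohort generator. Defaults mirror the study
#' conditions the analysis targets: 22 ASD and 25 TD children, a 30 Hz
#' depth camera, the six-segment session schedule, and small frame-to-frame
#' joint motion (3 mm per axis).
#'
#' @param n_asd,n_td Group sizes (default 22 / 25).
#' @param frame_rate Frames per second (default 30).
#' @param schedule A [segment_schedule()]; default the full 840 s session.
#' @param base_step_sd Per-axis random-walk step SD in meters per frame
#'   (default 0.003).
#' @param effect_map `NULL` (no group differences) or a data.frame with
#'   columns `joint`, `segment`, `lambda`: multiplicative step-SD factor
#'   applied to ASD subjects for that joint in that segment
#'   (`lambda >= 0`; unlisted cells keep `lambda = 1`).
#' @param subject_sdlog SD (log scale) of a per-subject lognormal
#'   multiplier on `base_step_sd`, giving between-subject movement
#'   variability (default 0.15).
#' @param conf_mean Mean detection confidence of retained joints, in
#'   (0.75, 1]; retained confidences are uniform on
#'   `[2 * conf_mean - 1, 1]` (default 0.9).
#' @param p_drop Per frame-joint dropout probability; dropped samples draw
#'   a confidence uniform on `[0, 0.5)`, below the analysis filter
#'   (default 0.02).
#' @param cam A [camera_model()] used for the forward projection.
#' @param seed Master seed; per-subject sub-seeds are derived from it.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_asd = 22L, n_td = 25L, frame_rate = 30,
                          schedule = segment_schedule(),
                          base_step_sd = 0.003, effect_map = NULL,
                          subject_sdlog = 0.15,
                          conf_mean = 0.9, p_drop = 0.02,
                          cam = camera_model(), seed = 1L) {
  stopifnot(n_asd >= 1, n_td >= 1, frame_rate > 0, base_step_sd >= 0,
            subject_sdlog >= 0, conf_mean > 0.75, conf_mean <= 1,
            p_drop >= 0, p_drop <= 1,
            inherits(schedule, "segment_schedule"),
            inherits(cam, "camera_model"))
  if (!is.null(effect_map)) {
    stopifnot(is.data.frame(effect_map),
              all(c("joint", "segment", "lambda") %in% names(effect_map)),
              all(effect_map$lambda >= 0),
              all(effect_map$joint %in% 0:24),
              all(effect_map$segment %in% schedule$label))
  }
  structure(
    list(n_asd = as.integer(n_asd), n_td = as.integer(n_td),
         frame_rate = frame_rate, schedule = schedule,
         base_step_sd = base_step_sd, effect_map = effect_map,
         subject_sdlog = subject_sdlog,
         conf_mean = conf_mean, p_drop = p_drop, cam = cam,
         seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Preset effect maps for the cohort generator
#'
#' `"null"` returns no group differences. `"reported"` is a qualitative
#' emulation of the reported group contrasts: elevated ASD head movement in
#' all three stimulus conditions (the dominant effect), plus milder leg and
#' trunk elevation in the visual condition. It emulates direction and
#' localization of effects, not calibrated effect sizes.
#'
#' @param name `"null"` or `"reported"`.
#' @param head_lambda Step-SD multiplier for head joints in stimulus
#'   segments (default 3).
#' @return An effect-map data.frame (or `NULL` for `"null"`) suitable for
#'   [cohort_config()]'s `effect_map`.
#' @export
effect_preset <- function(name = c("reported", "null"), head_lambda = 3) {
  name <- match.arg(name)
  if (name == "null") return(NULL)
  rbind(
    expand.grid(joint = body_part_joints("head"),
                segment = c("V", "VA", "VAO"), lambda = head_lambda,
                stringsAsFactors = FALSE),
    expand.grid(joint = body_part_joints("legs"), segment = "V",
                lambda = 1.5, stringsAsFactors = FALSE),
    data.frame(joint = 1L, segment = "V", lambda = 1.5)
  )
}

# lambda matrix: joints x frames (via segment of each frame's timestamp).
lambda_for_frames <- function(config, group, t) {
  lam <- matrix(1, nrow = 25, ncol = length(t))
  em <- config$effect_map
  if (group != "ASD" || is.null(em) || nrow(em) == 0) return(lam)
  sch <- config$schedule
  seg_of_t <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(sch)))
    seg_of_t[t >= sch$start[i] & t < sch$end[i]] <- sch$label[i]
  for (k in seq_len(nrow(em))) {
    sel <- which(seg_of_t == em$segment[k])
    lam[em$joint[k] + 1L, sel] <- em$lambda[k]
  }
  lam
}

#' Generate one synthetic subject recording
#'
#' Simulates all 25 joints as anchored Gaussian random walks (per-axis step
#' SD = `base_step_sd * lambda(group, joint, segment) * subject multiplier`),
#' forward-projects positions through the camera model to `(u, v, z)`, and
#' draws per frame-joint confidences from the dropout model. Deterministic
#' given `seed`.
#'
#' @param config A [cohort_config()].
#' @param subject_id Subject identifier.
#' @param group `"ASD"` or `"TD"`.
#' @param seed Seed for this subject (default `config$seed`).
#' @return A [subject_recording()].
#' @export
generate_recording <- function(config, subject_id, group, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group, c("ASD", "TD"))
  set.seed(seed)
  total <- max(config$schedule$end)
  n <- floor(total * config$frame_rate)
  t <- (seq_len(n) - 1L) / config$frame_rate
  anchor <- body25_anchor()
  cam <- config$cam
  subj_mult <- exp(stats::rnorm(1, 0, config$subject_sdlog))
  # lambda of the step i -> i+1 follows the segment of frame i
  lam <- lambda_for_frames(config, group, t)[, -n, drop = FALSE]
  frames <- matrix(0, nrow = n, ncol = 1 + 25 * 4)
  colnames(frames) <- pose_columns()
  frames[, "t"] <- t
  for (j in 1:25) {
    sds <- config$base_step_sd * subj_mult * lam[j, ]
    steps <- matrix(stats::rnorm(3 * (n - 1L)), ncol = 3) * sds
    pos <- rbind(rep(0, 3), apply(steps, 2, cumsum))
    pos <- sweep(pos, 2, anchor[j, ], "+")
    colnames(pos) <- c("X", "Y", "Z")
    z <- 0.05 + abs(pos[, "Z"] - 0.05)  # reflect: depth stays positive
    drop <- stats::runif(n) < config$p_drop
    conf <- ifelse(drop, stats::runif(n, 0, 0.5),
                   stats::runif(n, 2 * config$conf_mean - 1, 1))
    frames[, sprintf("j%d_u", j - 1L)] <- cam$cx + cam$fx * pos[, "X"] / z
    frames[, sprintf("j%d_v", j - 1L)] <- cam$cy + cam$fy * pos[, "Y"] / z
    frames[, sprintf("j%d_z", j - 1L)] <- z
    frames[, sprintf("j%d_c", j - 1L)] <- conf
  }
  subject_recording(subject_id, group, as.data.frame(frames), config$schedule)
}

#' Generate a full labelled cohort
#'
#' Produces `n_asd + n_td` recordings with deterministic per-subject
#' sub-seeds derived from the master seed, plus a subject manifest.
#' Optionally writes each pose stream plus `manifest.csv` and
#' `schedule.csv` under `dir`, so a cohort directory is self-describing.
#'
#' @param config A [cohort_config()].
#' @param dir Optional output directory for pose-stream CSVs and the
#'   manifest; created if needed.
#' @return A list with `recordings` (named list of [subject_recording()])
#'   and `subjects` (data.frame: `subject_id`, `group`, `seed`).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ids <- c(sprintf("ASD%02d", seq_len(config$n_asd)),
           sprintf("TD%02d", seq_len(config$n_td)))
  groups <- rep(c("ASD", "TD"), c(config$n_asd, config$n_td))
  seeds <- (as.numeric(config$seed) * 1009 + seq_along(ids) * 7919) %% 2147483647
  recs <- vector("list", length(ids))
  names(recs) <- ids
  for (i in seq_along(ids))
    recs[[i]] <- generate_recording(config, ids[i], groups[i], seed = seeds[i])
  subjects <- data.frame(subject_id = ids, group = groups, seed = seeds,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(ids))
      write_pose_stream(recs[[i]], file.path(dir, paste0(ids[i], ".csv")))
    utils::write.csv(subjects, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(config$schedule),
                     file.path(dir, "schedule.csv"), row.names = FALSE)
  }
  list(recordings = recs, subjects = subjects)
}
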