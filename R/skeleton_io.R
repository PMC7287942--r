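# Canonical data model and I/O for BODY_25 pose streams.
#
# A pose stream is one row per frame: a timestamp plus, for each of the 25
# joints, image coordinates (u, v) in pixels, depth z in meters and a
# detection confidence c in [0, 1] -- the output shape of a BODY_25-style
# pose estimator run on RGB-D video.

N_JOINTS <- 25L

#' Body-part partition of the BODY_25 skeleton
#'
#' Returns the joint indices (0-based, BODY_25 layout) belonging to a named
#' body part, as used throughout the analysis: head = eyes and ears
#' \{15, 16, 17, 18\}, trunk = neck and mid-hip \{1, 8\}, arms = shoulders,
#' elbows, wrists \{2..7\}, legs = hips, knees, ankles \{9..14\}, feet = toes
#' and heels \{19..24\}. `"all"` is the union of the five parts; the nose
#' (joint 0) belongs to no analysis group unless `include_nose = TRUE`.
#'
#' @param part One of `"head"`, `"trunk"`, `"arms"`, `"legs"`, `"feet"`,
#'   `"all"`, or an integer vector of joint ids (returned validated).
#' @param include_nose Include joint 0 in `"all"`? Default `FALSE`.
#' @return Integer vector of joint ids in `[0, 24]`.
#' @export
#' @examples
#' body_part_joints("head")
#' body_part_joints("all")
body_part_joints <- function(part, include_nose = FALSE) {
  if (is.numeric(part)) {
    ids <- as.integer(part)
    if (any(ids < 0L | ids > 24L)) stop("joint ids must lie in [0, 24]")
    return(ids)
  }
  part <- match.arg(part, c("head", "trunk", "arms", "legs", "feet", "all"))
  sets <- list(
    head  = c(15L, 16L, 17L, 18L),
    trunk = c(1L, 8L),
    arms  = 2:7,
    legs  = 9:14,
    feet  = 19:24
  )
  if (part == "all") {
    ids <- sort(unlist(sets, use.names = FALSE))
    if (include_nose) ids <- c(0L, ids)
    return(as.integer(ids))
  }
  as.integer(sets[[part]])
}

#' Pinhole camera model
#'
#' Intrinsics used to move between image coordinates plus depth and 3D
#' camera-frame coordinates. Defaults are a plausible RGB-D sensor at
#' 848x480; they only matter for geometric consistency of synthetic data,
#' not for the analysis itself.
#'
#' @param fx,fy Focal lengths in pixels (> 0).
#' @param cx,cy Principal point in pixels.
#' @return An object of class `"camera_model"`.
#' @export
camera_model <- function(fx = 600, fy = 600, cx = 424, cy = 240) {
  stopifnot(is.numeric(fx), is.numeric(fy), fx > 0, fy > 0)
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy), class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("Pinhole camera: fx=%g fy=%g cx=%g cy=%g\n", x$fx, x$fy, x$cx, x$cy))
  invisible(x)
}

SEGMENT_LABELS <- c("BL_V", "V", "BL_VA", "VA", "BL_VAO", "VAO")
STIMULUS_LABELS <- c("V", "VA", "VAO")

#' Session segment schedule
#'
#' Ordered, non-overlapping time segments labelling the recording session:
#' three stimulus conditions (V visual, VA visual-auditory, VAO
#' visual-auditory-olfactory), each preceded by a baseline (BL_*). The
#' default schedule is 120 s per baseline and 160 s per stimulus, 840 s
#' total; `duration_factor` rescales all segments proportionally (handy for
#' fast test cohorts).
#'
#' @param labels Character vector of segment labels.
#' @param start,end Numeric vectors of segment bounds in seconds.
#' @param duration_factor Multiplies all default durations (ignored when
#'   explicit bounds are given).
#' @return An object of class `"segment_schedule"`: a data.frame with
#'   columns `label`, `start`, `end`.
#' @export
#' @examples
#' segment_schedule()                      # the full 14-minute session
#' segment_schedule(duration_factor = 0.1) # 84 s, for quick simulations
segment_schedule <- function(labels = NULL, start = NULL, end = NULL,
                             duration_factor = 1) {
  if (is.null(labels)) {
    stopifnot(duration_factor > 0)
    dur <- rep(c(120, 160), 3) * duration_factor
    end <- cumsum(dur)
    start <- c(0, end[-6])
    labels <- SEGMENT_LABELS
  }
  stopifnot(length(labels) == length(start), length(start) == length(end))
  if (any(end <= start)) stop("each segment must satisfy end > start")
  if (is.unsorted(start) || any(start[-1] < end[-length(end)] - 1e-12))
    stop("segments must be ordered and non-overlapping")
  if (anyDuplicated(labels)) stop("segment labels must be unique")
  structure(
    data.frame(label = as.character(labels), start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("segment_schedule", "data.frame")
  )
}

#' @export
print.segment_schedule <- function(x, ...) {
  cat(sprintf("Segment schedule: %d segments, %.1f s total\n",
              nrow(x), max(x$end) - min(x$start)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Subject recording container
#'
#' Bundles a subject's frame stream (a data.frame with column `t` and, per
#' joint j, columns `j<j>_u`, `j<j>_v`, `j<j>_z`, `j<j>_c`) with the session
#' schedule and group label.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param group `"ASD"` or `"TD"`.
#' @param frames Frame data.frame as above; must be sorted by `t`.
#' @param schedule A [segment_schedule()].
#' @return An object of class `"subject_recording"`.
#' @export
subject_recording <- function(subject_id, group, frames, schedule) {
  group <- match.arg(group, c("ASD", "TD"))
  stopifnot(inherits(schedule, "segment_schedule"))
  validate_frames(frames)
  if (nrow(frames) > 0) {
    span <- range(frames$t)
    if (span[1] < min(schedule$start) - 1e-9 || span[2] > max(schedule$end) + 1e-9)
      stop("frame timestamps fall outside the schedule span")
  }
  structure(
    list(subject_id = as.character(subject_id), group = group,
         frames = frames, schedule = schedule),
    class = "subject_recording"
  )
}

#' @export
print.subject_recording <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %d frames over %.1f s, %d segments\n",
              x$subject_id, x$group, nrow(x$frames),
              if (nrow(x$frames)) diff(range(x$frames$t)) else 0,
              nrow(x$schedule)))
  invisible(x)
}

pose_columns <- function() {
  c("t", as.vector(t(outer(paste0("j", 0:(N_JOINTS - 1L)),
                           c("u", "v", "z", "c"), paste, sep = "_"))))
}

validate_frames <- function(frames) {
  cols <- pose_columns()
  missing <- setdiff(cols, names(frames))
  if (length(missing) > 0)
    stop("pose-stream format error: missing columns ", paste(missing, collapse = ", "))
  if (nrow(frames) == 0) return(invisible(frames))
  if (is.unsorted(frames$t, strictly = TRUE))
    stop("validation error: timestamps must be strictly increasing")
  cc <- as.matrix(frames[, grep("_c$", cols, value = TRUE)])
  if (any(!is.finite(cc)) || any(cc < 0) || any(cc > 1))
    stop("validation error: confidences must lie in [0, 1]")
  zz <- as.matrix(frames[, grep("_z$", cols, value = TRUE)])
  if (any(!is.finite(zz)) || any(zz < 0))
    stop("validation error: depths must be non-negative")
  invisible(frames)
}

#' Read a pose stream from disk
#'
#' Reads a per-frame pose stream in either the flat CSV dialect (header
#' `t,j0_u,j0_v,j0_z,j0_c,...,j24_c`) or JSON-lines (one object per frame
#' with the same fields), validates it, and returns a
#' [subject_recording()].
#'
#' @param path File path; format chosen by extension (`.jsonl` for
#'   JSON-lines, otherwise CSV) or via `format`.
#' @param schedule A [segment_schedule()].
#' @param subject_id,group Subject metadata.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer from the extension.
#' @return A [subject_recording()] with frames sorted by timestamp.
#' @export
read_pose_stream <- function(path, schedule, subject_id, group, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  format <- match.arg(format, c("csv", "jsonl"))
  frames <- if (format == "csv") {
    utils::read.csv(path, check.names = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) data.frame() else
      do.call(rbind, lapply(lines, function(l)
        as.data.frame(jsonlite::fromJSON(l), check.names = FALSE)))
  }
  if (nrow(frames) == 0) stop("empty-input error: no frames in ", path)
  missing <- setdiff(pose_columns(), names(frames))
  if (length(missing) > 0)
    stop("pose-stream format error: missing columns ", paste(missing, collapse = ", "))
  frames <- frames[, pose_columns()]
  bad <- !stats::complete.cases(frames)
  if (any(bad)) {
    warning(sum(bad), " malformed row(s) rejected")
    frames <- frames[!bad, , drop = FALSE]
  }
  frames <- frames[order(frames$t), , drop = FALSE]
  if (anyDuplicated(frames$t))
    stop("validation error: duplicated timestamps")
  rownames(frames) <- NULL
  subject_recording(subject_id, group, frames, schedule)
}

#' Write a pose stream to disk
#'
#' Inverse of [read_pose_stream()]; numeric fields survive a round trip
#' bit-identically (full-precision CSV via 17 significant digits, or
#' JSON-lines).
#'
#' @param rec A [subject_recording()].
#' @param path Output file path.
#' @param format `"csv"`, `"jsonl"`, or `NULL` to infer from the extension.
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "subject_recording"))
  if (is.null(format))
    format <- if (grepl("\\.jsonl$", path, ignore.case = TRUE)) "jsonl" else "csv"
  format <- match.arg(format, c("csv", "jsonl"))
  fr <- rec$frames
  if (format == "csv") {
    txt <- vapply(seq_len(nrow(fr)), function(i)
      paste(format(as.numeric(fr[i, ]), digits = 17, trim = TRUE, scientific = FALSE),
            collapse = ","), character(1))
    writeLines(c(paste(pose_columns(), collapse = ","), txt), path)
  } else {
    nm <- pose_columns()
    writeLines(vapply(seq_len(nrow(fr)), function(i) {
      vals <- format(as.numeric(fr[i, ]), digits = 17, trim = TRUE,
                     scientific = FALSE)
      paste0("{", paste0("\"", nm, "\":", vals, collapse = ","), "}")
    }, character(1)), path)
  }
  invisible(path)
}

#' Back-project a skeleton frame to 3D
#'
#' Pinhole back-projection of each joint's image coordinates and depth to
#' camera-frame meters: `X = (u - cx) * z / fx`, `Y = (v - cy) * z / fy`,
#' `Z = z`. Confidence is carried through unchanged. At `z = 0` the joint
#' maps to the origin regardless of `(u, v)`.
#'
#' @param frame A single frame: either one row of a pose-stream data.frame
#'   or a data.frame/matrix with columns `u`, `v`, `z`, `c` (25 rows).
#' @param cam A [camera_model()].
#' @return A data.frame with 25 rows and columns `joint`, `X`, `Y`, `Z`, `c`.
#' @export
project_to_3d <- function(frame, cam) {
  stopifnot(inherits(cam, "camera_model"))
  j <- as_joint_matrix(frame)
  if (any(j[, "z"] < 0)) stop("validation error: negative depth")
  data.frame(
    joint = 0:(N_JOINTS - 1L),
    X = (j[, "u"] - cam$cx) * j[, "z"] / cam$fx,
    Y = (j[, "v"] - cam$cy) * j[, "z"] / cam$fy,
    Z = j[, "z"],
    c = j[, "c"]
  )
}

# Accepts one pose-stream row or a 25x4 (u,v,z,c) table.
as_joint_matrix <- function(frame) {
  if (is.data.frame(frame) && all(c("u", "v", "z", "c") %in% names(frame))) {
    stopifnot(nrow(frame) == N_JOINTS)
    return(cbind(u = frame$u, v = frame$v, z = frame$z, c = frame$c))
  }
  if (is.matrix(frame) && ncol(frame) == 4) {
    stopifnot(nrow(frame) == N_JOINTS)
    colnames(frame) <- c("u", "v", "z", "c")
    return(frame)
  }
  row <- as.numeric(frame[pose_columns()[-1]])
  matrix(row, nrow = N_JOINTS, ncol = 4, byrow = TRUE,
         dimnames = list(NULL, c("u", "v", "z", "c")))
}

#' Project all frames of a recording to per-joint 3D series
#'
#' @param rec A [subject_recording()].
#' @param cam A [camera_model()].
#' @return A list with one element per joint id (`"0"` .. `"24"`), each a
#'   data.frame with columns `frame` (0-based original frame index), `t`,
#'   `X`, `Y`, `Z`, `c`.
#' @export
recording_to_3d <- function(rec, cam = camera_model()) {
  stopifnot(inherits(rec, "subject_recording"))
  fr <- rec$frames
  n <- nrow(fr)
  out <- vector("list", N_JOINTS)
  names(out) <- as.character(0:(N_JOINTS - 1L))
  for (j in 0:(N_JOINTS - 1L)) {
    u <- fr[[sprintf("j%d_u", j)]]; v <- fr[[sprintf("j%d_v", j)]]
    z <- fr[[sprintf("j%d_z", j)]]; c <- fr[[sprintf("j%d_c", j)]]
    out[[j + 1L]] <- data.frame(
      frame = seq_len(n) - 1L, t = fr$t,
      X = (u - cam$cx) * z / cam$fx,
      Y = (v - cam$cy) * z / cam$fy,
      Z = z, c = c
    )
  }
  out
}

#' Split a recording by the session schedule
#'
#' Assigns each frame to at most one segment by the half-open convention
#' `start <= t < end`; frames outside every segment are dropped (their count
#' is reported in the `"dropped"` attribute and via a message).
#'
#' @param rec A [subject_recording()].
#' @param quiet Suppress the dropped-frame message.
#' @return A named list (one element per schedule label) of frame
#'   data.frames, each carrying a `"frame_index"` attribute with the
#'   original 0-based frame indices; attribute `"dropped"` holds the count
#'   of unassigned frames.
#' @export
segment_recording <- function(rec, quiet = FALSE) {
  stopifnot(inherits(rec, "subject_recording"))
  fr <- rec$frames
  sch <- rec$schedule
  out <- vector("list", nrow(sch))
  names(out) <- sch$label
  assigned <- rep(FALSE, nrow(fr))
  for (i in seq_len(nrow(sch))) {
    sel <- fr$t >= sch$start[i] & fr$t < sch$end[i]
    seg <- fr[sel, , drop = FALSE]
    attr(seg, "frame_index") <- which(sel) - 1L
    out[[i]] <- seg
    assigned <- assigned | sel
  }
  dropped <- sum(!assigned)
  if (dropped > 0 && !quiet)
    message(dropped, " frame(s) outside all segments dropped")
  attr(out, "dropped") <- dropped
  out
}
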