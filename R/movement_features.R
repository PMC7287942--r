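# Per-joint movement quantification: confidence filtering, inter-frame
# Euclidean displacement, and the subjects x (joint, segment) mean-movement
# feature table used by the statistics and the classifier.

#' Drop low-confidence joint samples
#'
#' Removes samples whose detection confidence falls strictly below the
#' threshold; samples at exactly the threshold are retained. Retained
#' samples keep their original frame indices, so downstream displacement
#' computation can recognize gaps.
#'
#' @param series Data.frame with at least columns `frame` and `c` (as
#'   produced by [recording_to_3d()]).
#' @param threshold Confidence threshold (default 0.5).
#' @return The retained rows of `series`.
#' @export
filter_low_confidence <- function(series, threshold = 0.5) {
  stopifnot(all(c("frame", "c") %in% names(series)))
  series[series$c >= threshold, , drop = FALSE]
}

#' Inter-frame displacement of a joint
#'
#' Euclidean distance between the joint's 3D positions at consecutive
#' original frames. Only pairs of retained samples at *adjacent* original
#' frame indices produce a value: a gap left by confidence filtering yields
#' no displacement rather than a bridged (inflated) one.
#'
#' @param series Data.frame with columns `frame`, `X`, `Y`, `Z`, sorted by
#'   `frame`.
#' @return Numeric vector of displacements in meters per frame-step
#'   (possibly empty).
#' @export
joint_displacements <- function(series) {
  stopifnot(all(c("frame", "X", "Y", "Z") %in% names(series)))
  n <- nrow(series)
  if (n < 2) return(numeric(0))
  if (is.unsorted(series$frame)) stop("series must be sorted by frame index")
  adj <- which(diff(series$frame) == 1L)
  if (length(adj) == 0) return(numeric(0))
  dx <- series$X[adj + 1L] - series$X[adj]
  dy <- series$Y[adj + 1L] - series$Y[adj]
  dz <- series$Z[adj + 1L] - series$Z[adj]
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Mean movement of a joint
#'
#' Arithmetic mean of the displacement values; `NA` when no displacement
#' pair survived filtering.
#'
#' @param displacements Numeric vector from [joint_displacements()].
#' @return Scalar mean, or `NA_real_` for empty input.
#' @export
mean_movement <- function(displacements) {
  if (length(displacements) == 0) return(NA_real_)
  mean(displacements)
}

#' Build the subjects x (joint, segment) feature table
#'
#' For every subject, segments the recording, back-projects joints to 3D,
#' filters low-confidence samples, and computes the mean inter-frame
#' displacement of each requested joint within each requested segment.
#' Cells with no valid displacement pair are imputed with the column
#' median (the imputation count is recorded in the object).
#'
#' @param recordings A list of [subject_recording()] (or the list returned
#'   by [generate_cohort()]).
#' @param joints A body-part name accepted by [body_part_joints()] or an
#'   integer vector of joint ids.
#' @param segments Character vector of segment labels to include (default
#'   the three stimulus conditions, baselines excluded).
#' @param threshold Confidence threshold for [filter_low_confidence()].
#' @param cam A [camera_model()] for the 3D back-projection.
#' @return An object of class `"feature_table"`: a list with `values`
#'   (numeric matrix, subjects x features, column names `j<joint>_<segment>`),
#'   `subjects` (data.frame `subject_id`, `group`), `columns` (data.frame
#'   `joint`, `segment`), `threshold`, `n_imputed`.
#' @export
build_feature_table <- function(recordings, joints = "all",
                                segments = STIMULUS_LABELS,
                                threshold = 0.5, cam = camera_model()) {
  if (is.list(recordings) && !is.null(recordings$recordings))
    recordings <- recordings$recordings
  stopifnot(length(recordings) >= 1,
            all(vapply(recordings, inherits, logical(1), "subject_recording")))
  joint_ids <- body_part_joints(joints)
  sch <- recordings[[1]]$schedule
  bad <- setdiff(segments, sch$label)
  if (length(bad)) stop("unknown segment label(s): ", paste(bad, collapse = ", "))

  cols <- expand.grid(joint = joint_ids, segment = segments,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  col_names <- sprintf("j%d_%s", cols$joint, cols$segment)
  values <- matrix(NA_real_, nrow = length(recordings), ncol = nrow(cols),
                   dimnames = list(NULL, col_names))
  ids <- character(length(recordings))
  groups <- character(length(recordings))

  for (s in seq_along(recordings)) {
    rec <- recordings[[s]]
    ids[s] <- rec$subject_id
    groups[s] <- rec$group
    segs <- segment_recording(rec, quiet = TRUE)
    j3d <- recording_to_3d(rec, cam)
    for (seg in segments) {
      idx <- attr(segs[[seg]], "frame_index")
      for (k in which(cols$segment == seg)) {
        j <- cols$joint[k]
        series <- j3d[[as.character(j)]][idx + 1L, , drop = FALSE]
        series <- filter_low_confidence(series, threshold)
        values[s, k] <- mean_movement(joint_displacements(series))
      }
    }
  }

  n_imputed <- 0L
  for (k in seq_len(ncol(values))) {
    miss <- is.na(values[, k])
    if (all(miss)) stop("column ", col_names[k], " missing for all subjects")
    if (any(miss)) {
      values[miss, k] <- stats::median(values[!miss, k])
      n_imputed <- n_imputed + sum(miss)
    }
  }

  structure(
    list(values = values,
         subjects = data.frame(subject_id = ids, group = groups,
                               stringsAsFactors = FALSE),
         columns = cols, threshold = threshold, n_imputed = n_imputed),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "Feature table: %d subjects (%d ASD / %d TD) x %d features (%d joints x %d segments)\n",
    nrow(x$values), sum(x$subjects$group == "ASD"), sum(x$subjects$group == "TD"),
    ncol(x$values), length(unique(x$columns$joint)), length(unique(x$columns$segment))))
  cat(sprintf("Mean displacement (m/frame-step), confidence >= %.2f; %d cell(s) imputed\n",
              x$threshold, x$n_imputed))
  invisible(x)
}

#' Tidy view of a feature table
#'
#' @param x A `"feature_table"`.
#' @param ... Unused.
#' @return Long data.frame: `subject_id`, `group`, `joint`, `segment`,
#'   `value`.
#' @export
as.data.frame.feature_table <- function(x, ...) {
  long <- expand.grid(s = seq_len(nrow(x$values)), k = seq_len(ncol(x$values)))
  data.frame(
    subject_id = x$subjects$subject_id[long$s],
    group = x$subjects$group[long$s],
    joint = x$columns$joint[long$k],
    segment = x$columns$segment[long$k],
    value = x$values[cbind(long$s, long$k)],
    stringsAsFactors = FALSE
  )
}

#' Write a feature table to CSV
#'
#' @param x A `"feature_table"`.
#' @param path Output path; the wide layout puts subjects in rows.
#' @param layout `"wide"` (subject_id, group, one column per feature) or
#'   `"tidy"` (long format).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path, layout = c("wide", "tidy")) {
  layout <- match.arg(layout)
  df <- if (layout == "wide") {
    cbind(x$subjects, as.data.frame(x$values))
  } else {
    as.data.frame(x)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
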