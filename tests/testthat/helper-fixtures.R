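# Shared fixtures, built in code at test time.

# Small, fast synthetic cohort.
tiny_cohort <- function(seed = 1, n_asd = 5, n_td = 6, duration_factor = 0.05,
                        effect_map = NULL, ...) {
  generate_cohort(cohort_config(
    n_asd = n_asd, n_td = n_td,
    schedule = segment_schedule(duration_factor = duration_factor),
    effect_map = effect_map, seed = seed, ...))
}

# Minimal single-column feature table wrapping two group samples, for
# exercising the statistics on arbitrary vectors.
make_ft <- function(asd_values, td_values, joint = 0L, segment = "V") {
  values <- matrix(c(asd_values, td_values), ncol = 1,
                   dimnames = list(NULL, sprintf("j%d_%s", joint, segment)))
  structure(
    list(values = values,
         subjects = data.frame(
           subject_id = sprintf("S%02d", seq_len(length(asd_values) + length(td_values))),
           group = rep(c("ASD", "TD"), c(length(asd_values), length(td_values))),
           stringsAsFactors = FALSE),
         columns = data.frame(joint = joint, segment = segment,
                              stringsAsFactors = FALSE),
         threshold = 0.5, n_imputed = 0L),
    class = "feature_table")
}

# Brute-force two-sided exact rank-sum p-value by enumerating all
# C(m+n, m) group assignments of the pooled ranks.
ranksum_enum_p <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  m <- length(x)
  w_obs <- sum(r[seq_len(m)])
  ws <- utils::combn(length(pooled), m, function(idx) sum(r[idx]))
  p_le <- mean(ws <= w_obs)
  p_ge <- mean(ws >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# A single-frame pose row with all joints at a fixed (u, v, z, c).
flat_frame <- function(t, u = 424, v = 240, z = 2, conf = 0.9) {
  row <- c(t, rep(c(u, v, z, conf), 25))
  names(row) <- kinemarker:::pose_columns()
  as.data.frame(as.list(row), check.names = FALSE)
}

# Stack flat frames at given timestamps into a frames data.frame.
flat_frames <- function(ts, ...) {
  do.call(rbind, lapply(ts, flat_frame, ...))
}
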