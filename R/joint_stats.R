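# Per-joint, per-segment two-group comparison: Shapiro-Wilk normality
# screen, two-sample Wilcoxon rank-sum test, and significance tiers.

#' Shapiro-Wilk normality screen for two groups
#'
#' Runs the Shapiro-Wilk test within each group and declares the cell
#' non-normal if either group rejects at `alpha`. With fewer than 3 finite
#' values in a group the screen is skipped and flagged.
#'
#' @param x,y Numeric vectors (the two groups).
#' @param alpha Rejection level (default 0.05).
#' @return List with `normal` (logical, `NA` if skipped), `p` (two
#'   per-group p-values, `NA` if skipped), `skipped` (logical).
#' @export
normality_screen <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3)
    return(list(normal = NA, p = c(NA_real_, NA_real_), skipped = TRUE))
  # shapiro.test errors on zero range; a constant sample is trivially
  # non-normal for our purposes
  p <- vapply(list(x, y), function(v) {
    if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  }, numeric(1))
  list(normal = all(p >= alpha), p = p, skipped = FALSE)
}

significance_tier <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Compare one joint x segment cell between groups
#'
#' Two-sample Wilcoxon rank-sum (Mann-Whitney) test on the ASD and TD
#' values of one feature column, two-sided. The exact null distribution is
#' used when both groups have at most 20 observations and the pooled values
#' are tie-free; otherwise the tie-corrected normal approximation (with
#' continuity correction) applies. Significance tiers: `*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001.
#'
#' @param table A `"feature_table"`.
#' @param joint Joint id.
#' @param segment Segment label.
#' @param paired Use the paired signed-rank variant (requires equal group
#'   sizes; default `FALSE`, since the groups are independent children).
#' @return A one-row data.frame: `joint`, `segment`, `median_asd`,
#'   `median_td`, `statistic`, `p`, `tier`, `direction` (`"ASD>TD"`,
#'   `"TD>ASD"` or `"equal"` by median difference).
#' @export
compare_joint <- function(table, joint, segment, paired = FALSE) {
  stopifnot(inherits(table, "feature_table"))
  k <- which(table$columns$joint == joint & table$columns$segment == segment)
  if (length(k) != 1)
    stop("no feature column for joint ", joint, " in segment ", segment)
  v <- table$values[, k]
  x <- v[table$subjects$group == "ASD"]
  y <- v[table$subjects$group == "TD"]
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0)
    stop("empty group for joint ", joint, " in segment ", segment)
  if (length(x) < 2 || length(y) < 2)
    stop("need >= 2 values per group for joint ", joint, " segment ", segment)
  exact <- !paired && length(x) <= 20 && length(y) <= 20 &&
    !anyDuplicated(c(x, y))
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact, correct = TRUE)
  )
  mx <- stats::median(x); my <- stats::median(y)
  data.frame(
    joint = joint, segment = segment,
    median_asd = mx, median_td = my,
    statistic = unname(wt$statistic), p = wt$p.value,
    tier = significance_tier(wt$p.value),
    direction = if (mx > my) "ASD>TD" else if (mx < my) "TD>ASD" else "equal",
    stringsAsFactors = FALSE
  )
}

#' Compare every joint x segment cell of a feature table
#'
#' Applies [normality_screen()] and [compare_joint()] to each column,
#' producing the summary grid of group differences across the skeleton and
#' session. No multiple-testing correction is applied by default (set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted p-values in an extra
#' column).
#'
#' @param table A `"feature_table"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data.frame with one row per feature column: the
#'   [compare_joint()] fields plus `normal` from the screen (and `p_adj`
#'   when `adjust = "BH"`).
#' @export
joint_group_tests <- function(table, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(table, "feature_table"))
  rows <- lapply(seq_len(nrow(table$columns)), function(k) {
    j <- table$columns$joint[k]; s <- table$columns$segment[k]
    cmp <- compare_joint(table, j, s)
    v <- table$values[, k]
    scr <- normality_screen(v[table$subjects$group == "ASD"],
                            v[table$subjects$group == "TD"])
    cmp$normal <- scr$normal
    cmp
  })
  out <- do.call(rbind, rows)
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
  }
  rownames(out) <- NULL
  out
}
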