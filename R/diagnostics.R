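# ---------------------------------------------------------------------------
# Group classification and operating characteristics (Se / Sp / Ac)
# ---------------------------------------------------------------------------

#' Construct a marker table
#'
#' Long-format table of per-sample diagnostic markers: one row per
#' `(sample, marker)` pair, with the sample's group label.  Marker names
#' follow the `"Z2@a=15/beta"` convention (statistic, scale, map).
#'
#' @param sample character or integer sample identifiers.
#' @param group group labels; exactly the values `"control"` and
#'   `"experimental"` are expected for classification.
#' @param marker marker names.
#' @param value numeric marker values.
#' @return `data.frame` of class `"marker_table"`.
#' @export
marker_table <- function(sample, group, marker, value) {
  df <- data.frame(
    sample = as.character(sample), group = as.character(group),
    marker = as.character(marker), value = as.numeric(value),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df[, c("sample", "marker")])) {
    stop("duplicated (sample, marker) pairs")
  }
  class(df) <- c("marker_table", "data.frame")
  df
}

#' Marker name helper
#' @param stat `"Z1"` or `"Z2"`.
#' @param scale wavelet scale (pixels).
#' @param map `"alpha"` or `"beta"`.
#' @return marker name string such as `"Z2@a=15/beta"`.
#' @export
marker_name <- function(stat, scale, map) {
  sprintf("%s@a=%g/%s", stat, scale, map)
}

#' Per-group marker summaries
#'
#' Group mean and standard error of the mean for every marker, the format
#' of the published marker tables (mean +- SE per group).
#'
#' @param table a [marker_table()].
#' @return `data.frame` with columns `marker`, `group`, `n`, `mean`, `se`.
#' @export
summarize_markers <- function(table) {
  sp <- split(table$value, list(table$marker, table$group), drop = TRUE)
  if (any(lengths(sp) < 2)) stop("every (marker, group) needs >= 2 samples")
  out <- do.call(rbind, lapply(names(sp), function(k) {
    v <- sp[[k]]
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    data.frame(
      marker = paste(parts[-length(parts)], collapse = "."),
      group = parts[length(parts)],
      n = length(v), mean = mean(v), se = sd(v) / sqrt(length(v)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$marker, out$group), ]
}

#' Operating characteristics of a binary diagnostic test
#'
#' `Se = 100 * A / N` (correct positives among the experimental group),
#' `Sp = 100 * B / H` (correct negatives among the control group),
#' `Ac = 100 * (A + B) / (N + H)`.  `Ac` is flagged balanced for equal
#' group sizes `N = H`.
#'
#' @param a true-positive count, `0 <= a <= n`.
#' @param b true-negative count, `0 <= b <= h`.
#' @param n experimental group size, `>= 1`.
#' @param h control group size, `>= 1`.
#' @return list with `se`, `sp`, `ac` (percent) and `balanced`.
#' @export
operating_characteristics <- function(a, b, n, h) {
  if (n < 1 || h < 1) stop("group sizes must be >= 1")
  if (a < 0 || a > n || b < 0 || b > h) stop("counts out of range")
  list(
    se = 100 * a / n, sp = 100 * b / h, ac = 100 * (a + b) / (n + h),
    balanced = n == h
  )
}

#' Grade a balanced accuracy
#'
#' Maps an accuracy percentage onto the five-level grading scale:
#' `<= 80` Unsatisfactory, `(80, 85]` Satisfactory, `(85, 90]` Good,
#' `(90, 95]` Very good, `> 95` Excellent.  The half-open intervals close
#' the gaps between the printed integer band edges; grading is applied to
#' the unrounded value.
#'
#' @param ac accuracy in percent, `[0, 100]`.
#' @return grade label (character).
#' @export
grade_accuracy <- function(ac) {
  if (!is.finite(ac) || ac < 0 || ac > 100) stop("ac must be in [0, 100]")
  if (ac <= 80) "Unsatisfactory"
  else if (ac <= 85) "Satisfactory"
  else if (ac <= 90) "Good"
  else if (ac <= 95) "Very good"
  else "Excellent"
}

#' Leave-one-out midpoint-threshold classification on one marker
#'
#' For each held-out sample, the decision threshold is the midpoint of the
#' two group means computed on the remaining samples; the held-out sample is
#' assigned to the group whose mean lies on its side of the threshold.
#' Ties (value exactly at the threshold) go to the control group.  The
#' accumulated confusion counts give Se, Sp and Ac, and the balanced
#' accuracy is graded on the five-level scale.
#'
#' @param table a [marker_table()] with groups `"control"` and
#'   `"experimental"`.
#' @param marker marker name to classify on.
#' @return list of class `"diagnostic_report"`: counts `a`, `b`, `n`, `h`,
#'   percentages `se`, `sp`, `ac` (one-decimal `*_rounded` variants
#'   included), `balanced`, `grade`, `marker`.
#' @export
threshold_classify <- function(table, marker) {
  tab <- table[table$marker == marker, ]
  if (!nrow(tab)) stop("marker not present: ", marker)
  groups <- c("control", "experimental")
  if (!all(groups %in% tab$group)) stop("need control and experimental groups")
  ctrl <- tab[tab$group == "control", ]
  expr <- tab[tab$group == "experimental", ]
  if (nrow(ctrl) < 2 || nrow(expr) < 2) stop("need >= 2 samples per group")
  ids <- tab$sample
  if (anyDuplicated(ids)) stop("duplicate samples for marker ", marker)
  a <- 0L; b <- 0L
  for (i in seq_len(nrow(tab))) {
    held <- tab[i, ]
    train <- tab[-i, ]
    mc <- mean(train$value[train$group == "control"])
    me <- mean(train$value[train$group == "experimental"])
    thr <- (mc + me) / 2
    # side of the threshold nearer the experimental mean; ties -> control
    assigned <- if (held$value == thr) "control"
    else if ((held$value > thr) == (me > mc)) "experimental"
    else "control"
    if (held$group == "experimental" && assigned == "experimental") a <- a + 1L
    if (held$group == "control" && assigned == "control") b <- b + 1L
  }
  oc <- operating_characteristics(a, b, nrow(expr), nrow(ctrl))
  structure(
    list(
      a = a, b = b, n = nrow(expr), h = nrow(ctrl),
      se = oc$se, sp = oc$sp, ac = oc$ac,
      se_rounded = round(oc$se, 1), sp_rounded = round(oc$sp, 1),
      ac_rounded = round(oc$ac, 1),
      balanced = oc$balanced, grade = grade_accuracy(oc$ac), marker = marker
    ),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf(
    "marker %s: Se %.1f%%, Sp %.1f%%, Ac %.1f%% (%s)%s\n",
    x$marker, x$se, x$sp, x$ac, x$grade,
    if (x$balanced) " [balanced]" else ""
  ))
  invisible(x)
}
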