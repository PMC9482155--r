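# Per-marker ROC analysis and decision-threshold calibration under a
# specificity constraint. The AUC is the Mann-Whitney two-sample statistic
# (ties count 1/2); its null p-value comes from the two-sided rank-sum test.

#' Nonparametric ROC AUC with rank-sum p-value
#'
#' AUC is the Mann-Whitney U statistic normalized by
#' `n_case * n_control`, ties counted 0.5 — the probability that a random
#' case value exceeds a random control value. The p-value is the two-sided
#' Wilcoxon rank-sum test of AUC = 0.5.
#'
#' @param case_values,control_values Numeric vectors of marker values
#'   (e.g. methylated-copy concentrations), at least one each.
#' @return A list with `auc` and `p_value`.
#' @export
#' @examples
#' roc_auc(c(2, 3), c(0, 1))   # perfect separation: AUC 1
roc_auc <- function(case_values, control_values) {
  stopifnot(length(case_values) >= 1L, length(control_values) >= 1L,
            !anyNA(case_values), !anyNA(control_values))
  n1 <- length(case_values)
  n0 <- length(control_values)
  r <- rank(c(case_values, control_values))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  auc <- u / (n1 * n0)
  if (length(unique(c(case_values, control_values))) == 1L)
    return(list(auc = 0.5, p_value = 1))
  p <- suppressWarnings(
    stats::wilcox.test(case_values, control_values,
                       alternative = "two.sided")$p.value)
  list(auc = auc, p_value = p)
}

#' Threshold calibration configuration
#'
#' @param specificity_floor Specificity that a threshold must strictly
#'   exceed (default 0.95).
#' @param control_groups Cohort groups used as calibration controls
#'   (default healthy controls only; other-cancer controls are
#'   evaluation-only).
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(specificity_floor = 0.95,
                               control_groups = "control_healthy") {
  if (specificity_floor <= 0 || specificity_floor >= 1)
    stop("specificity_floor must lie strictly in (0, 1)")
  structure(list(specificity_floor = specificity_floor,
                 control_groups = control_groups),
            class = "calibration_config")
}

#' Calibrate a single marker's decision threshold
#'
#' Candidate thresholds are the midpoints between consecutive distinct
#' pooled values plus extremes (below the minimum, at the maximum). A
#' sample is positive when its value is strictly greater than the
#' threshold. Among thresholds whose specificity strictly exceeds
#' `specificity_floor`, the one maximizing sensitivity is chosen,
#' breaking ties by higher specificity and then by higher threshold.
#'
#' @param case_values,control_values Numeric marker values.
#' @param config A [calibration_config()].
#' @param marker_id Identifier stored in the result.
#' @return A list of class `marker_threshold`: `marker_id`, `threshold`,
#'   `calibration_sensitivity`, `calibration_specificity`, `auc`,
#'   `auc_p_value`.
#' @export
calibrate_threshold <- function(case_values, control_values,
                                config = calibration_config(),
                                marker_id = "marker") {
  stopifnot(inherits(config, "calibration_config"),
            length(case_values) >= 1L, length(control_values) >= 1L,
            !anyNA(case_values), !anyNA(control_values))
  pooled <- sort(unique(c(case_values, control_values)))
  cand <- c(pooled[1L] - 1,
            if (length(pooled) > 1L) (pooled[-1L] + pooled[-length(pooled)]) / 2,
            pooled[length(pooled)])
  spec <- vapply(cand, function(t) mean(control_values <= t), 0)
  sens <- vapply(cand, function(t) mean(case_values > t), 0)
  ok <- spec > config$specificity_floor
  if (!any(ok))
    stop(sprintf(
      "no threshold attains specificity > %.3f for marker '%s' (%d controls, all positive at every cut)",
      config$specificity_floor, marker_id, length(control_values)))
  # maximize sensitivity; ties -> higher specificity, then higher threshold
  o <- order(-sens[ok], -spec[ok], -cand[ok])
  pick <- which(ok)[o[1L]]
  a <- roc_auc(case_values, control_values)
  structure(list(marker_id = marker_id, threshold = cand[pick],
                 calibration_sensitivity = sens[pick],
                 calibration_specificity = spec[pick],
                 auc = a$auc, auc_p_value = a$p_value),
            class = "marker_threshold")
}

#' @export
print.marker_threshold <- function(x, ...) {
  cat(sprintf(
    "<marker_threshold> %s: threshold %.4g (sens %.1f%%, spec %.1f%%, AUC %.3f, p %.3g)\n",
    x$marker_id, x$threshold, 100 * x$calibration_sensitivity,
    100 * x$calibration_specificity, x$auc, x$auc_p_value))
  invisible(x)
}

#' Calibrate thresholds for every marker in a cohort
#'
#' @param cohort A `cohort_table` (see [read_cohort()]).
#' @param config A [calibration_config()]; calibration controls default to
#'   healthy controls only.
#' @return A list of class `marker_threshold_set`, one `marker_threshold`
#'   per marker column.
#' @export
calibrate_panel <- function(cohort, config = calibration_config()) {
  stopifnot(inherits(cohort, "cohort_table"))
  markers <- attr(cohort, "markers")
  is_case <- cohort$group == "case"
  is_ctrl <- cohort$group %in% config$control_groups
  if (!any(is_case) || !any(is_ctrl))
    stop("calibration needs at least one case and one control sample")
  out <- lapply(markers, function(mk) {
    cv <- cohort[[mk]][is_case]
    kv <- cohort[[mk]][is_ctrl]
    calibrate_threshold(cv[!is.na(cv)], kv[!is.na(kv)], config, marker_id = mk)
  })
  names(out) <- markers
  class(out) <- "marker_threshold_set"
  out
}

#' @export
print.marker_threshold_set <- function(x, ...) {
  cat(sprintf("<marker_threshold_set> %d markers\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

#' Coerce a threshold set to a data frame
#'
#' @param x A `marker_threshold_set`.
#' @param ... Unused.
#' @return Data frame with one row per marker.
#' @export
as.data.frame.marker_threshold_set <- function(x, ...) {
  data.frame(marker_id = vapply(x, `[[`, character(1L), "marker_id"),
             threshold = vapply(x, `[[`, numeric(1L), "threshold"),
             calibration_sensitivity =
               vapply(x, `[[`, numeric(1L), "calibration_sensitivity"),
             calibration_specificity =
               vapply(x, `[[`, numeric(1L), "calibration_specificity"),
             auc = vapply(x, `[[`, numeric(1L), "auc"),
             auc_p_value = vapply(x, `[[`, numeric(1L), "auc_p_value"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Tissue-stage biomarker selection filter
#'
#' Keeps markers with calibration sensitivity strictly above
#' `min_sensitivity` and a significant AUC.
#'
#' @param markers A `marker_threshold_set` or list of `marker_threshold`.
#' @param min_sensitivity Sensitivity bound, strict (default 0.5).
#' @param alpha AUC p-value significance level (default 0.05).
#' @return The retained subset, same class.
#' @export
tissue_selection_filter <- function(markers, min_sensitivity = 0.5,
                                    alpha = 0.05) {
  keep <- vapply(markers, function(m)
    m$calibration_sensitivity > min_sensitivity && m$auc_p_value < alpha,
    logical(1L))
  out <- markers[keep]
  class(out) <- class(markers)
  out
}
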