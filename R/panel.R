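# Three-state panel scoring: binary per-marker calls, methylated-marker
# counting, and the negative / inconclusive / positive classification, plus
# the positivity-cutoff search and a fitted-panel S3 interface.

#' Panel scoring rule
#'
#' A panel result is NEGATIVE with 0 methylated markers, POSITIVE with at
#' least `positive_cutoff_k`, and INCONCLUSIVE in between (the band
#' `1 .. k-1`, empty when `k = 1`).
#'
#' @param n_markers Panel size (default 8).
#' @param positive_cutoff_k Minimum methylated markers for a positive call
#'   (default 2).
#' @return A list of class `panel_rule`.
#' @export
panel_rule <- function(n_markers = 8L, positive_cutoff_k = 2L) {
  n_markers <- as.integer(n_markers)
  positive_cutoff_k <- as.integer(positive_cutoff_k)
  if (positive_cutoff_k < 1L || positive_cutoff_k > n_markers)
    stop("positive_cutoff_k must lie in 1..n_markers")
  structure(list(n_markers = n_markers, positive_cutoff_k = positive_cutoff_k,
                 negative_at = 0L),
            class = "panel_rule")
}

#' Binary marker calls from concentrations and thresholds
#'
#' A marker is methylated when its concentration is strictly greater than
#' its calibrated threshold; a value equal to the threshold is negative.
#' Missing values give missing calls.
#'
#' @param values Named numeric vector of marker concentrations.
#' @param thresholds A `marker_threshold_set` (or list of
#'   `marker_threshold`) aligned by marker id.
#' @return Named logical vector of calls (NA where the value is missing).
#' @export
call_markers <- function(values, thresholds) {
  thr_ids <- vapply(thresholds, `[[`, character(1L), "marker_id")
  if (is.null(names(values))) {
    if (length(values) != length(thresholds))
      stop("unnamed values must match the threshold set length")
    names(values) <- thr_ids
  }
  if (!setequal(names(values), thr_ids))
    stop("marker ids of values and thresholds do not match")
  thr <- stats::setNames(vapply(thresholds, `[[`, numeric(1L), "threshold"),
                         thr_ids)[names(values)]
  values > thr
}

#' Classify one sample's marker calls into the three-state outcome
#'
#' With complete calls: 0 methylated markers is NEGATIVE, at least `k` is
#' POSITIVE, in between is INCONCLUSIVE. With missing calls the rule is
#' conservative: POSITIVE if the observed positives already reach `k`,
#' otherwise INCONCLUSIVE — a NEGATIVE result is never issued with missing
#' markers, because only a certain all-negative panel spares cystoscopy.
#'
#' @param calls Logical vector of marker calls (may contain NA).
#' @param rule A [panel_rule()].
#' @param sample_id Identifier stored in the result.
#' @return A list of class `panel_call`: `sample_id`, `marker_calls`,
#'   `n_methylated` (observed positives), `n_missing`, `outcome` (factor
#'   NEGATIVE/INCONCLUSIVE/POSITIVE).
#' @export
classify_panel <- function(calls, rule = panel_rule(), sample_id = NA_character_) {
  stopifnot(inherits(rule, "panel_rule"))
  if (length(calls) != rule$n_markers)
    stop("expected ", rule$n_markers, " marker calls, got ", length(calls))
  k <- rule$positive_cutoff_k
  n_pos <- sum(calls, na.rm = TRUE)
  n_miss <- sum(is.na(calls))
  outcome <- if (n_pos >= k) "POSITIVE"
             else if (n_miss > 0L) "INCONCLUSIVE"
             else if (n_pos == 0L) "NEGATIVE"
             else "INCONCLUSIVE"
  structure(list(sample_id = sample_id, marker_calls = calls,
                 n_methylated = n_pos, n_missing = n_miss,
                 outcome = factor(outcome, levels = c("NEGATIVE",
                                                      "INCONCLUSIVE",
                                                      "POSITIVE"))),
            class = "panel_call")
}

#' @export
print.panel_call <- function(x, ...) {
  cat(sprintf("<panel_call> %s: %d/%d methylated -> %s\n",
              x$sample_id, x$n_methylated, length(x$marker_calls),
              as.character(x$outcome)))
  invisible(x)
}

#' Score every sample of a cohort against a threshold set
#'
#' @param cohort A `cohort_table`.
#' @param thresholds A `marker_threshold_set` covering the cohort's
#'   markers.
#' @param rule A [panel_rule()].
#' @return A data frame of class `panel_calls`: `sample_id`, `group`,
#'   `stage`, `grade`, one logical column per marker call, `n_methylated`,
#'   `n_missing`, `outcome`.
#' @export
score_cohort <- function(cohort, thresholds, rule = panel_rule()) {
  stopifnot(inherits(cohort, "cohort_table"))
  markers <- attr(cohort, "markers")
  if (length(markers) != rule$n_markers)
    stop("cohort has ", length(markers), " markers but the rule expects ",
         rule$n_markers)
  vals <- as.matrix(cohort[, markers, drop = FALSE])
  thr_ids <- vapply(thresholds, `[[`, character(1L), "marker_id")
  if (!setequal(markers, thr_ids))
    stop("marker ids of cohort and thresholds do not match")
  thr <- stats::setNames(vapply(thresholds, `[[`, numeric(1L), "threshold"),
                         thr_ids)[markers]
  calls <- sweep(vals, 2L, thr, `>`)
  pc <- lapply(seq_len(nrow(cohort)), function(i)
    classify_panel(calls[i, ], rule, sample_id = cohort$sample_id[i]))
  out <- data.frame(sample_id = cohort$sample_id, group = cohort$group,
                    stage = cohort$stage, grade = cohort$grade,
                    stringsAsFactors = FALSE)
  cc <- as.data.frame(calls)
  names(cc) <- paste0("call.", markers)
  out <- cbind(out, cc)
  out$n_methylated <- vapply(pc, `[[`, integer(1L), "n_methylated")
  out$n_missing <- vapply(pc, `[[`, integer(1L), "n_missing")
  out$outcome <- factor(vapply(pc, function(p) as.character(p$outcome),
                               character(1L)),
                        levels = c("NEGATIVE", "INCONCLUSIVE", "POSITIVE"))
  attr(out, "markers") <- markers
  attr(out, "rule") <- rule
  class(out) <- c("panel_calls", "data.frame")
  out
}

#' Search the panel positivity cutoff
#'
#' For each cutoff `k`, samples with 0 methylated markers are negative,
#' those with at least `k` positive, and counts in `1..k-1` inconclusive;
#' sensitivity and specificity are computed over conclusive samples only.
#' The recommended `k` maximizes Youden's J times the conclusive rate (a
#' documented stand-in for an informal "best combination" criterion); the
#' full table is always returned so callers can apply their own rule.
#'
#' @param n_methylated Integer vector of methylated-marker counts.
#' @param is_case Logical vector, `TRUE` for confirmed disease.
#' @param n_markers Panel size (default 8).
#' @param utility Function of `(sensitivity, specificity,
#'   conclusive_rate)` returning the quantity to maximize.
#' @return A list with `table` (data frame over `k = 1..n_markers`:
#'   sensitivity, specificity, conclusive_rate, utility; undefined metrics
#'   are NA) and `recommended_k`.
#' @export
cutoff_search <- function(n_methylated, is_case, n_markers = 8L,
                          utility = function(sens, spec, concl)
                            (sens + spec - 1) * concl) {
  stopifnot(length(n_methylated) == length(is_case), !anyNA(n_methylated))
  ks <- seq_len(n_markers)
  rows <- lapply(ks, function(k) {
    pos <- n_methylated >= k
    neg <- n_methylated == 0L
    concl <- pos | neg
    sens <- if (any(concl & is_case)) mean(pos[concl & is_case]) else NA_real_
    spec <- if (any(concl & !is_case)) mean(neg[concl & !is_case]) else NA_real_
    cr <- mean(concl)
    data.frame(k = k, sensitivity = sens, specificity = spec,
               conclusive_rate = cr,
               utility = if (is.na(sens) || is.na(spec)) NA_real_
                         else utility(sens, spec, cr))
  })
  tab <- do.call(rbind, rows)
  rec <- if (all(is.na(tab$utility))) NA_integer_
         else tab$k[which.max(tab$utility)]
  list(table = tab, recommended_k = rec)
}

#' Fit a methylation biomarker panel on a discovery cohort
#'
#' Calibrates a per-marker decision threshold on the discovery cohort
#' (cases versus healthy controls, specificity strictly above the floor)
#' and fixes the three-state panel rule, yielding a fitted object that can
#' score new cohorts via [predict.urometh_panel()].
#'
#' @param cohort Discovery `cohort_table`.
#' @param rule A [panel_rule()] (default 2-of-8).
#' @param config A [calibration_config()].
#' @return An object of class `urometh_panel` with elements `thresholds`
#'   (a `marker_threshold_set`), `rule`, `config` and `discovery_summary`
#'   (the panel's diagnostic summary on the discovery cohort itself).
#' @seealso [predict.urometh_panel()], [coef.urometh_panel()],
#'   [diagnostic_summary()]
#' @export
panel_fit <- function(cohort, rule = panel_rule(),
                      config = calibration_config()) {
  thresholds <- calibrate_panel(cohort, config)
  calls <- score_cohort(cohort, thresholds, rule)
  disc <- diagnostic_summary(calls$outcome, cohort$group == "case")
  structure(list(thresholds = thresholds, rule = rule, config = config,
                 markers = attr(cohort, "markers"),
                 discovery_summary = disc,
                 n_discovery = nrow(cohort)),
            class = "urometh_panel")
}

#' @export
print.urometh_panel <- function(x, ...) {
  cat(sprintf("<urometh_panel> %d-marker panel, positive at >= %d methylated\n",
              x$rule$n_markers, x$rule$positive_cutoff_k))
  cat(sprintf("  calibrated on %d samples (specificity floor %.2f, controls: %s)\n",
              x$n_discovery, x$config$specificity_floor,
              paste(x$config$control_groups, collapse = ", ")))
  invisible(x)
}

#' @export
summary.urometh_panel <- function(object, ...) {
  cat("Fitted methylation biomarker panel\n\n")
  print(object)
  cat("\nPer-marker calibration:\n")
  print(as.data.frame(object$thresholds), digits = 3)
  cat("\nDiscovery-cohort performance (conclusive results only):\n")
  print(object$discovery_summary)
  invisible(object)
}

#' @export
coef.urometh_panel <- function(object, ...) {
  stats::setNames(vapply(object$thresholds, `[[`, numeric(1L), "threshold"),
                  vapply(object$thresholds, `[[`, character(1L), "marker_id"))
}

#' Score a cohort with a fitted panel
#'
#' @param object A fitted `urometh_panel`.
#' @param newdata A `cohort_table` with the same marker columns.
#' @param ... Unused.
#' @return A `panel_calls` data frame (see [score_cohort()]).
#' @export
predict.urometh_panel <- function(object, newdata, ...) {
  score_cohort(newdata, object$thresholds, object$rule)
}
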