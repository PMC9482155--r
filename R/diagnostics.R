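# Diagnostic-accuracy evaluation of three-state panel results: accuracy on
# conclusive samples with Clopper-Pearson 95% CIs, prevalence-based
# predictive values, spared-cystoscopy rate and stratified sensitivity.

.cp_ci <- function(x, n, conf = 0.95) {
  if (n == 0L) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  c(ci[1L], ci[2L])
}

#' Summarize three-state panel results against disease labels
#'
#' Inconclusive samples are excluded from the confusion counts; sensitivity
#' and specificity are computed over conclusive samples only, with exact
#' (Clopper-Pearson) 95% confidence intervals. The spared-cystoscopy
#' fraction is the rate of true negatives among all tested patients
#' (inconclusive results still require cystoscopy). When a prevalence is
#' supplied, PPV and NPV are computed from sensitivity, specificity and
#' prevalence via Bayes' formula, never from cohort column totals.
#'
#' @param outcomes Factor/character vector of panel outcomes
#'   (NEGATIVE/INCONCLUSIVE/POSITIVE), e.g. `calls$outcome` from
#'   [score_cohort()].
#' @param is_case Logical vector, `TRUE` for confirmed disease.
#' @param prevalence Optional assumed population prevalence in (0, 1) for
#'   predictive values (e.g. 0.20 for gross-hematuria patients).
#' @return A list of class `diagnostic_summary` with counts (`n_total`,
#'   `n_conclusive`, `tp`, `fp`, `tn`, `fn`, `n_inconclusive_cases`,
#'   `n_inconclusive_controls`), rates (`sensitivity`, `specificity` with
#'   `*_ci`, `conclusive_rate`, `spared_fraction`) and, when prevalence is
#'   given, `prevalence`, `ppv`, `npv`. Undefined rates are `NA`, never 0.
#' @export
diagnostic_summary <- function(outcomes, is_case, prevalence = NULL) {
  stopifnot(length(outcomes) == length(is_case), !anyNA(is_case))
  outcomes <- as.character(outcomes)
  if (!all(outcomes %in% c("NEGATIVE", "INCONCLUSIVE", "POSITIVE")))
    stop("outcomes must be NEGATIVE, INCONCLUSIVE or POSITIVE")
  concl <- outcomes != "INCONCLUSIVE"
  pos <- outcomes == "POSITIVE"
  tp <- sum(concl & is_case & pos)
  fn <- sum(concl & is_case & !pos)
  fp <- sum(concl & !is_case & pos)
  tn <- sum(concl & !is_case & !pos)
  n_total <- length(outcomes)
  n_conclusive <- sum(concl)
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NA_real_
  out <- list(n_total = n_total, n_conclusive = n_conclusive,
              tp = tp, fp = fp, tn = tn, fn = fn,
              n_inconclusive_cases = sum(!concl & is_case),
              n_inconclusive_controls = sum(!concl & !is_case),
              sensitivity = sens,
              sensitivity_ci = .cp_ci(tp, tp + fn),
              specificity = spec,
              specificity_ci = .cp_ci(tn, tn + fp),
              conclusive_rate = n_conclusive / n_total,
              spared_fraction = tn / n_total)
  if (!is.null(prevalence)) {
    pv <- predictive_values(sens, spec, prevalence)
    out$prevalence <- prevalence
    out$ppv <- pv$ppv
    out$npv <- pv$npv
  }
  class(out) <- "diagnostic_summary"
  out
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  pct <- function(v) ifelse(is.na(v), "NA", sprintf("%.1f%%", 100 * v))
  cat(sprintf("Conclusive patients  %s (%d/%d)\n",
              pct(x$conclusive_rate), x$n_conclusive, x$n_total))
  cat(sprintf("Sensitivity          %s (%d/%d), 95%% CI %s-%s\n",
              pct(x$sensitivity), x$tp, x$tp + x$fn,
              pct(x$sensitivity_ci[1L]), pct(x$sensitivity_ci[2L])))
  cat(sprintf("Specificity          %s (%d/%d), 95%% CI %s-%s\n",
              pct(x$specificity), x$tn, x$tn + x$fp,
              pct(x$specificity_ci[1L]), pct(x$specificity_ci[2L])))
  if (!is.null(x$ppv)) {
    cat(sprintf("PPV                  %s (at prevalence %.0f%%)\n",
                pct(x$ppv), 100 * x$prevalence))
    cat(sprintf("NPV                  %s (at prevalence %.0f%%)\n",
                pct(x$npv), 100 * x$prevalence))
  }
  cat(sprintf("Spared cystoscopies  %s (%d/%d)\n",
              pct(x$spared_fraction), x$tn, x$n_total))
  invisible(x)
}

#' Prevalence-based predictive values
#'
#' `ppv = sens*pi / (sens*pi + (1-spec)*(1-pi))` and
#' `npv = spec*(1-pi) / (spec*(1-pi) + (1-sens)*pi)`.
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @param prevalence Assumed disease prevalence in (0, 1).
#' @return A list with `ppv` and `npv` (`NA` where a denominator is 0).
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  stopifnot(prevalence > 0, prevalence < 1)
  if (is.na(sensitivity) || is.na(specificity))
    return(list(ppv = NA_real_, npv = NA_real_))
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  pi1 <- prevalence
  dp <- sensitivity * pi1 + (1 - specificity) * (1 - pi1)
  dn <- specificity * (1 - pi1) + (1 - sensitivity) * pi1
  list(ppv = if (dp > 0) sensitivity * pi1 / dp else NA_real_,
       npv = if (dn > 0) specificity * (1 - pi1) / dn else NA_real_)
}

#' Sensitivity stratified by tumor stage or grade
#'
#' Per stratum, inconclusive cases are excluded and sensitivity is
#' `tp / (tp + fn)` among the stratum's conclusive cases.
#'
#' @param outcomes Panel outcomes (as in [diagnostic_summary()]).
#' @param is_case Logical disease labels.
#' @param strata Stratum label per sample (stage or grade); only case
#'   samples are used, cases with missing stratum are counted separately.
#' @return A data frame with `stratum`, `n_conclusive`, `tp`,
#'   `sensitivity` (NA for empty strata), plus an attribute
#'   `n_missing_stratum`.
#' @export
stratified_sensitivity <- function(outcomes, is_case, strata) {
  stopifnot(length(outcomes) == length(is_case),
            length(strata) == length(is_case))
  outcomes <- as.character(outcomes)
  cases <- which(is_case)
  miss <- sum(is.na(strata[cases]))
  cases <- cases[!is.na(strata[cases])]
  levs <- unique(strata[cases])
  ord <- match(levs, c("Ta", "T1", "T2", "T3", "T4", "CIS", "low", "high"))
  levs <- levs[order(ifelse(is.na(ord), 99L, ord), levs)]
  rows <- lapply(levs, function(s) {
    i <- cases[strata[cases] == s]
    concl <- outcomes[i] != "INCONCLUSIVE"
    tp <- sum(outcomes[i][concl] == "POSITIVE")
    n <- sum(concl)
    data.frame(stratum = s, n_conclusive = n, tp = tp,
               sensitivity = if (n > 0L) tp / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_missing_stratum") <- miss
  out
}

#' Test for age-dependent marker methylation among cases
#'
#' Splits cases at the median age into two equally sized groups (ties at
#' the median go to the younger group) and runs a two-sided Wilcoxon
#' rank-sum test per marker between the groups.
#'
#' @param case_marker_values Numeric matrix/data frame of marker
#'   concentrations, one row per case.
#' @param ages Numeric ages, one per case.
#' @return A list with `split_age`, `group` (factor `younger`/`older`) and
#'   `p_values` (named per marker). With fewer than 4 cases the test is
#'   flagged underpowered and p-values are not reported.
#' @export
age_split_test <- function(case_marker_values, ages) {
  m <- as.matrix(case_marker_values)
  stopifnot(nrow(m) == length(ages), !anyNA(ages))
  n <- length(ages)
  if (n < 2L) stop("need at least 2 cases with ages")
  ord <- order(ages)
  half <- n %/% 2L
  group <- rep("older", n)
  group[ord[seq_len(half + n %% 2L)]] <- "younger"  # ties at median -> lower
  group <- factor(group, levels = c("younger", "older"))
  split_age <- stats::median(ages)
  if (n < 4L)
    return(list(split_age = split_age, group = group,
                p_values = NULL, underpowered = TRUE))
  p <- apply(m, 2L, function(v)
    suppressWarnings(stats::wilcox.test(v[group == "younger"],
                                        v[group == "older"],
                                        alternative = "two.sided")$p.value))
  list(split_age = split_age, group = group,
       p_values = p, underpowered = FALSE)
}
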