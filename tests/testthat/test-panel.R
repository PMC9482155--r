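make_thresholds <- function(values) {
  out <- lapply(names(values), function(id)
    structure(list(marker_id = id, threshold = values[[id]],
                   calibration_sensitivity = 0.6,
                   calibration_specificity = 0.96,
                   auc = 0.8, auc_p_value = 0.001),
              class = "marker_threshold"))
  names(out) <- names(values)
  class(out) <- "marker_threshold_set"
  out
}

test_that("marker calls are strict greater-than comparisons", {
  thr <- make_thresholds(setNames(as.list(rep(1, 8)), paste0("m", 1:8)))
  vals <- setNames(rep(0, 8), paste0("m", 1:8))
  expect_equal(unname(call_markers(vals, thr)), rep(FALSE, 8))
  vals[] <- 1  # equal to threshold -> negative
  expect_equal(unname(call_markers(vals, thr)), rep(FALSE, 8))
  set.seed(101)
  vals[] <- runif(8, 0, 2)
  expect_equal(unname(call_markers(vals, thr)), unname(vals > 1))
  names(vals)[1] <- "bogus"
  expect_error(call_markers(vals, thr), "ids")
})

test_that("three-state classification partitions count space", {
  rule <- panel_rule(8, 2)
  mk <- function(n_pos) c(rep(TRUE, n_pos), rep(FALSE, 8 - n_pos))
  expect_equal(as.character(classify_panel(mk(0), rule)$outcome), "NEGATIVE")
  expect_equal(as.character(classify_panel(mk(1), rule)$outcome), "INCONCLUSIVE")
  expect_equal(as.character(classify_panel(mk(2), rule)$outcome), "POSITIVE")
  expect_equal(as.character(classify_panel(mk(8), rule)$outcome), "POSITIVE")
  # k = 1 has no inconclusive band
  expect_equal(as.character(classify_panel(mk(1), panel_rule(8, 1))$outcome),
               "POSITIVE")
  # raising k never promotes a sample toward POSITIVE
  rank <- c(NEGATIVE = 0, INCONCLUSIVE = 1, POSITIVE = 2)
  for (n_pos in 0:8) {
    oc <- vapply(1:8, function(k)
      rank[as.character(classify_panel(mk(n_pos), panel_rule(8, k))$outcome)], 0)
    expect_true(all(diff(oc) <= 0))
  }
})

test_that("missing marker calls never produce a NEGATIVE result", {
  rule <- panel_rule(8, 2)
  calls <- c(TRUE, TRUE, NA, rep(FALSE, 5))
  expect_equal(as.character(classify_panel(calls, rule)$outcome), "POSITIVE")
  calls <- c(rep(FALSE, 7), NA)
  expect_equal(as.character(classify_panel(calls, rule)$outcome), "INCONCLUSIVE")
  calls <- c(TRUE, rep(FALSE, 6), NA)
  expect_equal(as.character(classify_panel(calls, rule)$outcome), "INCONCLUSIVE")
})

test_that("cutoff search matches a brute-force loop and flags undefined cells", {
  set.seed(111)
  n <- 200
  is_case <- runif(n) < 0.4
  counts <- ifelse(is_case, rbinom(n, 8, 0.5), rbinom(n, 8, 0.05))
  cs <- cutoff_search(counts, is_case)
  expect_equal(cs$table$conclusive_rate[1], 1)  # k = 1: no inconclusive band
  for (k in 1:8) {
    pos <- counts >= k; neg <- counts == 0; concl <- pos | neg
    sens <- if (any(concl & is_case)) sum(pos & is_case) / sum(concl & is_case) else NA_real_
    spec <- if (any(concl & !is_case)) sum(neg & !is_case) / sum(concl & !is_case) else NA_real_
    expect_equal(cs$table$sensitivity[k], sens)
    expect_equal(cs$table$specificity[k], spec)
    expect_equal(cs$table$conclusive_rate[k], mean(concl))
  }
  # clean separation: k = 2 is perfect
  counts2 <- ifelse(is_case, pmax(2L, counts), 0L)
  cs2 <- cutoff_search(counts2, is_case)
  expect_equal(cs2$table$sensitivity[2], 1)
  expect_equal(cs2$table$specificity[2], 1)
  # all-inconclusive cells are NA, not 0
  cs3 <- cutoff_search(rep(1L, 10), rep(c(TRUE, FALSE), 5), n_markers = 3L)
  expect_true(is.na(cs3$table$sensitivity[2]))
})

test_that("a fitted panel scores cohorts and exposes coefficients", {
  disc <- simulate_urine_cohort(urine_sim_config(preset = "discovery", seed = 8L))
  fit <- panel_fit(disc$cohort)
  expect_s3_class(fit, "urometh_panel")
  expect_named(coef(fit), attr(disc$cohort, "markers"))
  expect_output(print(fit), "8-marker panel")
  expect_output(summary(fit), "Per-marker calibration")
  ev <- simulate_urine_cohort(urine_sim_config(preset = "hematuria", seed = 9L))
  calls <- predict(fit, ev$cohort)
  expect_s3_class(calls, "panel_calls")
  expect_equal(nrow(calls), 273L)
  expect_true(all(calls$n_methylated ==
                    rowSums(as.matrix(calls[, paste0("call.", fit$markers)]))))
  # outcome consistent with the rule for every sample
  k <- fit$rule$positive_cutoff_k
  expect_true(all((calls$n_methylated >= k) == (calls$outcome == "POSITIVE")))
  expect_true(all((calls$n_methylated == 0) == (calls$outcome == "NEGATIVE")))
})

test_that("panel sensitivity at k = 2 exceeds every single-marker sensitivity", {
  disc <- simulate_urine_cohort(urine_sim_config(preset = "discovery", seed = 10L))
  fit <- panel_fit(disc$cohort)
  ev <- simulate_urine_cohort(urine_sim_config(preset = "hematuria", seed = 11L))
  calls <- predict(fit, ev$cohort)
  is_case <- ev$cohort$group == "case"
  s <- diagnostic_summary(calls$outcome, is_case)
  marker_sens <- colMeans(as.matrix(
    calls[is_case, paste0("call.", fit$markers)]))
  expect_true(all(s$sensitivity > marker_sens))
})
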