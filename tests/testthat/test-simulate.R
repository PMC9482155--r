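test_that("RRBS simulation is seed-deterministic down to the written files", {
  cfg <- rrbs_sim_config(n_cpgs = 400L, n_planted = 2L, seed = 42L)
  a <- simulate_rrbs(cfg)
  b <- simulate_rrbs(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_coverage_file(a$samples[[1]], f1)
  write_coverage_file(b$samples[[1]], f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(a$truth, b$truth)
})

test_that("planted regions separate the groups; null config plants nothing", {
  cfg <- rrbs_sim_config(n_cpgs = 600L, coverage_mean = 50, n_planted = 3L,
                         planted_dmrs = data.frame(span_bp = 400L,
                                                   target_beta = 1.0,
                                                   offtarget_beta = 0.0,
                                                   n_cpgs = 10L)[rep(1, 3), ],
                         seed = 5L)
  rr <- simulate_rrbs(cfg)
  # with betas 1 vs 0 the group difference inside each region is extreme
  for (r in seq_len(nrow(rr$truth))) {
    betas <- vapply(rr$samples, function(s) {
      rec <- s$records
      i <- rec$pos >= rr$truth$start[r] & rec$pos < rr$truth$end[r]
      mean(rec$n_meth[i] / (rec$n_meth[i] + rec$n_unmeth[i]))
    }, 0)
    delta <- mean(betas[rr$groups == "target"]) -
      mean(betas[rr$groups == "offtarget"])
    expect_gt(delta, 0.9)
  }
  null <- simulate_rrbs(rrbs_sim_config(n_cpgs = 500L, n_planted = 0L, seed = 1L))
  expect_equal(nrow(null$truth), 0L)
})

test_that("invalid simulator configs are rejected", {
  expect_error(rrbs_sim_config(planted_dmrs = data.frame(
    span_bp = 100L, target_beta = 1.2, offtarget_beta = 0, n_cpgs = 5L)),
    "betas")
  expect_error(urine_sim_config(per_marker_specificity = rep(1.0, 8)),
               "strictly in")
  expect_error(urine_sim_config(per_marker_sensitivity = rep(0, 8)),
               "strictly in")
})

test_that("urine cohorts hit their marginal positivity rates", {
  cfg <- urine_sim_config(n_cases = 2000L, n_controls_healthy = 2000L,
                          n_controls_other = 0L, seed = 9L)
  sim <- simulate_urine_cohort(cfg)
  st <- sim$truth$state
  is_case <- sim$cohort$group == "case"
  sens_hat <- colMeans(st[is_case, ])
  fp_hat <- colMeans(st[!is_case, ])
  se_s <- sqrt(cfg$per_marker_sensitivity * (1 - cfg$per_marker_sensitivity) / 2000)
  se_f <- sqrt(cfg$per_marker_specificity * (1 - cfg$per_marker_specificity) / 2000)
  expect_true(all(abs(sens_hat - cfg$per_marker_sensitivity) <= 3 * se_s))
  expect_true(all(abs(fp_hat - (1 - cfg$per_marker_specificity)) <= 3 * se_f))
})

test_that("zero shedding variance makes case marker states independent", {
  cfg <- urine_sim_config(n_cases = 10000L, n_controls_healthy = 1L,
                          n_controls_other = 0L, shedding_sd = 0, seed = 2L)
  st <- simulate_urine_cohort(cfg)$truth$state[1:10000, ] * 1
  phis <- combn(ncol(st), 2, function(jk) cor(st[, jk[1]], st[, jk[2]]))
  expect_true(all(abs(phis) < 0.05))
  # and positive shedding variance induces positive correlation
  cfg2 <- urine_sim_config(n_cases = 4000L, n_controls_healthy = 1L,
                           n_controls_other = 0L, shedding_sd = 2, seed = 2L)
  st2 <- simulate_urine_cohort(cfg2)$truth$state[1:4000, ] * 1
  phis2 <- combn(ncol(st2), 2, function(jk) cor(st2[, jk[1]], st2[, jk[2]]))
  expect_true(all(phis2 > 0))
})

test_that("perfect specificity yields no positive markers in healthy controls", {
  cfg <- urine_sim_config(n_cases = 5L, n_controls_healthy = 500L,
                          per_marker_specificity = rep(1 - 1e-12, 8),
                          seed = 3L)
  sim <- simulate_urine_cohort(cfg)
  st <- sim$truth$state[sim$cohort$group == "control_healthy", ]
  expect_equal(sum(st), 0L)
})

test_that("the hematuria preset matches the series composition", {
  cfg <- urine_sim_config(preset = "hematuria", seed = 1L)
  sim <- simulate_urine_cohort(cfg)
  expect_equal(nrow(sim$cohort), 273L)
  expect_equal(sum(sim$cohort$group == "case"), 93L)
  expect_equal(93 / 273, 0.341, tolerance = 0.002)  # 34.1% case fraction
  # stage/grade only for cases, explicit NA elsewhere
  expect_true(all(is.na(sim$cohort$stage[sim$cohort$group != "case"])))
  expect_true(all(sim$cohort$stage[sim$cohort$group == "case"] %in%
                    c("Ta", "T1", "T2", "T3", "T4", "CIS")))
})
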