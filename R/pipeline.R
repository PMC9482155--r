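# End-to-end orchestration: simulate -> discover -> calibrate -> score ->
# evaluate, writing every intermediate artifact plus a manifest with the
# seed, config hash and per-stage record counts.

#' Pipeline configuration
#'
#' Bundles the per-stage configurations with a master seed and output
#' directory. Stage seeds are derived deterministically from the master
#' seed so one integer reproduces the whole run.
#'
#' @param rrbs An [rrbs_sim_config()].
#' @param discovery_cohort,evaluation_cohort [urine_sim_config()]s for the
#'   threshold-calibration and evaluation series (defaults: the discovery
#'   and hematuria presets).
#' @param windows A [window_config()].
#' @param calibration A [calibration_config()].
#' @param rule A [panel_rule()].
#' @param prevalence Assumed prevalence for predictive values.
#' @param seed Master seed (overrides the stage config seeds).
#' @param out_dir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rrbs = rrbs_sim_config(),
                            discovery_cohort = urine_sim_config(preset = "discovery"),
                            evaluation_cohort = urine_sim_config(preset = "hematuria"),
                            windows = window_config(),
                            calibration = calibration_config(),
                            rule = panel_rule(),
                            prevalence = 0.20,
                            seed = 1L, out_dir = "urometh_run") {
  seed <- as.integer(seed)
  rrbs$seed <- seed + 101L
  discovery_cohort$seed <- seed + 202L
  evaluation_cohort$seed <- seed + 303L
  structure(list(rrbs = rrbs, discovery_cohort = discovery_cohort,
                 evaluation_cohort = evaluation_cohort, windows = windows,
                 calibration = calibration, rule = rule,
                 prevalence = prevalence, seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

.config_json <- function(config) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  x <- strip(config)
  x$out_dir <- NULL  # run location is not part of the analysis config
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                   dataframe = "rows", pretty = TRUE)
}

#' Run the full pipeline
#'
#' Simulates cell-line RRBS data and two urine cohorts, discovers DMR
#' candidates, calibrates per-marker thresholds on the discovery cohort,
#' scores both cohorts with the panel rule, searches the positivity cutoff
#' and writes diagnostic reports. All artifacts land under
#' `config$out_dir`; the returned manifest lists paths, per-stage record
#' counts and md5 checksums, and the archived config file's hash is
#' embedded in every report.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return The run manifest (list), invisibly written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(...) file.path(config$out_dir, ...)

  cfg_path <- p("config.json")
  writeLines(.config_json(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  say("[simulate] RRBS cell lines (seed %d)", config$rrbs$seed)
  rr <- simulate_rrbs(config$rrbs)
  dir.create(p("coverage"), showWarnings = FALSE)
  cov_paths <- vapply(rr$samples, function(s)
    write_coverage_file(s, p("coverage", paste0(s$sample_id, ".cov"))),
    character(1L))
  utils::write.table(
    data.frame(sample_id = names(rr$groups), group = unname(rr$groups)),
    p("groups.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rr$truth, p("planted_dmrs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[discover] window scan at %s bp",
      paste(config$windows$window_sizes, collapse = "/"))
  disc <- discover_dmrs(rr$samples, rr$groups, config$windows)
  utils::write.table(as.data.frame(disc$filtered), p("windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_candidates_bed(disc$candidates, p("candidates.bed"))

  say("[simulate] urine cohorts (discovery + evaluation)")
  dco <- simulate_urine_cohort(config$discovery_cohort)
  eco <- simulate_urine_cohort(config$evaluation_cohort)
  write_cohort(dco$cohort, p("cohort_discovery.tsv"))
  write_cohort(eco$cohort, p("cohort_evaluation.tsv"))

  say("[calibrate] thresholds at specificity floor %.2f",
      config$calibration$specificity_floor)
  fit <- panel_fit(dco$cohort, config$rule, config$calibration)
  thr_df <- as.data.frame(fit$thresholds)
  jsonlite::write_json(thr_df, p("thresholds.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  say("[score] panel calls")
  calls_d <- predict(fit, dco$cohort)
  calls_e <- predict(fit, eco$cohort)
  utils::write.table(as.data.frame(calls_d), p("calls_discovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(calls_e), p("calls_evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- cutoff_search(calls_d$n_methylated, dco$cohort$group == "case",
                      n_markers = config$rule$n_markers)
  utils::write.table(cs$table, p("cutoff_search.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  say("[evaluate] diagnostic summaries")
  sum_d <- diagnostic_summary(calls_d$outcome, dco$cohort$group == "case",
                              prevalence = config$prevalence)
  sum_e <- diagnostic_summary(calls_e$outcome, eco$cohort$group == "case",
                              prevalence = config$prevalence)
  sum_d$config_hash <- cfg_hash
  sum_e$config_hash <- cfg_hash
  write_report(sum_d, p("report_discovery.json"), "json")
  write_report(sum_e, p("report_evaluation.json"), "json")
  strat <- stratified_sensitivity(calls_e$outcome,
                                  eco$cohort$group == "case",
                                  eco$cohort$stage)
  utils::write.table(strat, p("stratified_sensitivity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  paths <- c(cfg_path, cov_paths, p("groups.tsv"), p("planted_dmrs.tsv"),
             p("windows.tsv"), p("candidates.bed"),
             p("cohort_discovery.tsv"), p("cohort_evaluation.tsv"),
             p("thresholds.json"), p("calls_discovery.tsv"),
             p("calls_evaluation.tsv"), p("cutoff_search.tsv"),
             p("report_discovery.json"), p("report_evaluation.json"),
             p("stratified_sensitivity.tsv"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("urometh")),
    seed = config$seed,
    config_hash = cfg_hash,
    counts = list(
      coverage_files = length(cov_paths),
      planted_dmrs = nrow(rr$truth),
      windows_scanned = nrow(disc$windows),
      windows_retained = nrow(disc$filtered),
      candidates = nrow(disc$candidates),
      discovery_samples = nrow(dco$cohort),
      evaluation_samples = nrow(eco$cohort),
      recommended_k = cs$recommended_k),
    checksums = as.list(stats::setNames(unname(tools::md5sum(paths)),
                                        basename(paths))))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
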