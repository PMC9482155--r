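# Seeded generators for the two kinds of input the pipeline consumes:
# cell-line RRBS-style methylation call tables with planted DMRs, and urine
# cohorts whose per-marker positivity follows a logit-normal latent
# "tumor shedding" model.

# Gauss-Hermite nodes/weights for N(0,1) expectations (Golub-Welsch).
.gauss_hermite <- function(n = 64L) {
  i <- seq_len(n - 1L)
  a <- sqrt(i / 2)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- a
  J[cbind(i + 1L, i)] <- a
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values * sqrt(2), w = e$vectors[1L, ]^2)
}

# Intercept a such that E[plogis(a + sigma*Z)] = p, Z ~ N(0,1).
.logit_intercept <- function(p, sigma, quad = .gauss_hermite()) {
  if (sigma == 0) return(stats::qlogis(p))
  stats::uniroot(function(a) sum(quad$w * stats::plogis(a + sigma * quad$x)) - p,
                 c(-50, 50), tol = 1e-10)$root
}

#' Configuration for the RRBS cell-line simulator
#'
#' Describes a panel of cancer cell lines split into a target-cancer group
#' and an off-target group, profiled at a shared set of CpGs with
#' negative-binomial coverage and beta-binomial methylation counts around a
#' locus-specific baseline drawn from a two-mode beta mixture (mostly
#' unmethylated loci plus a fully methylated fraction). Ground-truth DMRs
#' are planted as intervals where the two groups get different baselines.
#'
#' @param n_target_lines,n_offtarget_lines Cell lines per group (default 8
#'   and 8, an eight-line target panel against eight other-cancer lines).
#' @param n_cpgs Number of background CpGs (default 3000).
#' @param mean_gap_bp Mean distance between consecutive CpGs (default 150).
#' @param clustering Gap mixture factor; larger values concentrate CpGs in
#'   CpG-island-like clusters separated by long gaps (default 4).
#' @param coverage_mean,coverage_dispersion Negative-binomial read coverage
#'   per CpG per sample (defaults 100 and 8; typical RRBS libraries average
#'   around 100x).
#' @param beta_low,beta_high,weight_low Background baseline mixture: modes
#'   of the low/high methylation components and the weight of the low one
#'   (defaults 0.05, 0.85, 0.7, giving a genome-wide mean methylation near
#'   35%).
#' @param bb_precision Beta-binomial precision of per-sample noise around
#'   the baseline (default 30; larger = less overdispersion).
#' @param planted_dmrs Data frame with columns `span_bp`, `target_beta`,
#'   `offtarget_beta`, `n_cpgs` (one row per planted region), or `NULL` for
#'   the default of 6 regions of 500 bp / 12 CpGs at betas 0.85 vs 0.03.
#'   Use `n_planted = 0` for a null configuration.
#' @param n_planted Number of default planted regions when `planted_dmrs`
#'   is `NULL` (default 6).
#' @param chrom Chromosome name for the simulated locus set.
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `rrbs_sim_config`.
#' @export
rrbs_sim_config <- function(n_target_lines = 8L, n_offtarget_lines = 8L,
                            n_cpgs = 3000L, mean_gap_bp = 150,
                            clustering = 4, coverage_mean = 100,
                            coverage_dispersion = 8, beta_low = 0.05,
                            beta_high = 0.85, weight_low = 0.7,
                            bb_precision = 30, planted_dmrs = NULL,
                            n_planted = 6L, chrom = "chr1", seed = 1L) {
  if (is.null(planted_dmrs)) {
    planted_dmrs <- if (n_planted > 0L)
      data.frame(span_bp = 500L, target_beta = 0.85, offtarget_beta = 0.03,
                 n_cpgs = 12L)[rep(1L, n_planted), , drop = FALSE]
    else
      data.frame(span_bp = integer(), target_beta = numeric(),
                 offtarget_beta = numeric(), n_cpgs = integer())
  }
  stopifnot(n_target_lines >= 1L, n_offtarget_lines >= 1L, n_cpgs >= 1L,
            mean_gap_bp > 0, coverage_mean > 0, coverage_dispersion > 0,
            all(c(beta_low, beta_high, weight_low) >= 0),
            all(c(beta_low, beta_high, weight_low) <= 1))
  if (nrow(planted_dmrs) &&
      (any(planted_dmrs$target_beta < 0) || any(planted_dmrs$target_beta > 1) ||
       any(planted_dmrs$offtarget_beta < 0) || any(planted_dmrs$offtarget_beta > 1)))
    stop("planted DMR betas must lie in [0, 1]")
  structure(list(n_target_lines = as.integer(n_target_lines),
                 n_offtarget_lines = as.integer(n_offtarget_lines),
                 n_cpgs = as.integer(n_cpgs), mean_gap_bp = mean_gap_bp,
                 clustering = clustering, coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 beta_low = beta_low, beta_high = beta_high,
                 weight_low = weight_low, bb_precision = bb_precision,
                 planted_dmrs = planted_dmrs, chrom = chrom,
                 seed = as.integer(seed)),
            class = "rrbs_sim_config")
}

# beta-binomial draw around baseline beta with given precision
.rbetabinom <- function(n, size, beta, precision) {
  p <- ifelse(beta <= 0, 0,
       ifelse(beta >= 1, 1,
              stats::rbeta(n, beta * precision, (1 - beta) * precision)))
  stats::rbinom(n, size, p)
}

#' Simulate cell-line RRBS methylation call tables with planted DMRs
#'
#' @param config An [rrbs_sim_config()].
#' @return A list with elements `samples` (named list of
#'   [methylation_calls()] objects), `groups` (named character vector
#'   mapping sample ids to `"target"`/`"offtarget"`) and `truth` (data
#'   frame of planted regions: `chrom`, `start`, `end` 0-based half-open,
#'   `target_beta`, `offtarget_beta`, `n_cpgs`).
#' @export
simulate_rrbs <- function(config) {
  stopifnot(inherits(config, "rrbs_sim_config"))
  set.seed(config$seed)
  cfg <- config

  # background CpG positions: mixture of short intra-cluster and long
  # inter-cluster gaps with overall mean mean_gap_bp
  small <- max(2, cfg$mean_gap_bp / cfg$clustering)
  large <- max(small + 1, 2 * cfg$mean_gap_bp - small)
  use_small <- stats::runif(cfg$n_cpgs) < 0.5
  gaps <- ifelse(use_small,
                 2L + stats::rgeom(cfg$n_cpgs, 1 / small),
                 2L + stats::rgeom(cfg$n_cpgs, 1 / large))
  pos <- cumsum(gaps) + 1000L
  genome_end <- max(pos) + 5000L

  # plant regions in the occupied span, non-overlapping with 2 kb padding
  pd <- cfg$planted_dmrs
  truth <- data.frame(chrom = character(), start = integer(), end = integer(),
                      target_beta = numeric(), offtarget_beta = numeric(),
                      n_cpgs = integer())
  region_pos <- integer(0)
  region_of <- integer(0)
  if (nrow(pd)) {
    starts <- integer(0)
    for (r in seq_len(nrow(pd))) {
      ok <- FALSE
      prev_spans <- pd$span_bp[seq_along(starts)]
      for (try in 1:200) {
        s <- as.integer(stats::runif(1, 1000, genome_end - pd$span_bp[r] - 1000))
        if (!length(starts) ||
            all(s + pd$span_bp[r] + 2000L <= starts |
                s >= starts + prev_spans + 2000L)) {
          ok <- TRUE; break
        }
      }
      if (!ok) stop("could not place non-overlapping planted regions; reduce n_planted")
      starts <- c(starts, s)
      inside <- sort(sample(seq.int(s, s + pd$span_bp[r] - 1L), pd$n_cpgs[r]))
      region_pos <- c(region_pos, inside)
      region_of <- c(region_of, rep.int(r, pd$n_cpgs[r]))
      truth <- rbind(truth, data.frame(
        chrom = cfg$chrom, start = s, end = s + pd$span_bp[r],
        target_beta = pd$target_beta[r], offtarget_beta = pd$offtarget_beta[r],
        n_cpgs = pd$n_cpgs[r]))
    }
    # drop background CpGs falling inside planted regions
    in_region <- rep(FALSE, length(pos))
    for (r in seq_len(nrow(truth)))
      in_region <- in_region | (pos >= truth$start[r] & pos < truth$end[r])
    pos <- pos[!in_region]
  }

  # locus baselines: background from the two-mode mixture (shared across
  # samples), planted loci group-specific
  n_bg <- length(pos)
  low <- stats::runif(n_bg) < cfg$weight_low
  conc <- 10
  bg_beta <- ifelse(low,
                    stats::rbeta(n_bg, cfg$beta_low * conc, (1 - cfg$beta_low) * conc),
                    stats::rbeta(n_bg, cfg$beta_high * conc, (1 - cfg$beta_high) * conc))

  all_pos <- c(pos, region_pos)
  ord <- order(all_pos)
  all_pos <- all_pos[ord]
  is_planted <- c(rep(FALSE, n_bg), rep(TRUE, length(region_pos)))[ord]
  beta_target <- c(bg_beta, if (length(region_pos)) pd$target_beta[region_of])[ord]
  beta_off <- c(bg_beta, if (length(region_pos)) pd$offtarget_beta[region_of])[ord]

  ids <- c(sprintf("target_%02d", seq_len(cfg$n_target_lines)),
           sprintf("offtarget_%02d", seq_len(cfg$n_offtarget_lines)))
  groups <- stats::setNames(rep(c("target", "offtarget"),
                                c(cfg$n_target_lines, cfg$n_offtarget_lines)), ids)
  n_loci <- length(all_pos)
  samples <- vector("list", length(ids))
  names(samples) <- ids
  for (k in seq_along(ids)) {
    cov <- stats::rnbinom(n_loci, size = cfg$coverage_dispersion,
                          mu = cfg$coverage_mean)
    keep <- cov >= 1L
    beta <- if (groups[k] == "target") beta_target else beta_off
    n_meth <- .rbetabinom(sum(keep), cov[keep], beta[keep], cfg$bb_precision)
    samples[[k]] <- methylation_calls(ids[k],
                                      chrom = rep(cfg$chrom, sum(keep)),
                                      pos = all_pos[keep],
                                      n_meth = n_meth,
                                      n_unmeth = cov[keep] - n_meth)
  }
  list(samples = samples, groups = groups, truth = truth)
}

#' Configuration for the urine cohort simulator
#'
#' Two-part model for per-marker ddPCR-style methylation concentrations.
#' Each patient first gets latent binary marker states: for cases the
#' per-marker positivity probability is `plogis(a_j + u_i)` where `u_i` is
#' a patient-level normal "tumor shedding" factor and `a_j` is calibrated
#' so the marginal positivity equals `per_marker_sensitivity[j]`; controls
#' get the analogous model with a background-methylation factor calibrated
#' to `1 - per_marker_specificity[j]`. States then map to concentrations:
#' positive case markers draw from a high log-normal scaled by shedding,
#' positive control markers from a lower log-normal, and negative markers
#' are mostly exact zeros with occasional trace background.
#'
#' @param n_cases,n_controls_healthy,n_controls_other Group sizes.
#' @param per_marker_sensitivity Marginal positivity among cases, one value
#'   per marker (default 8 markers evenly spaced 0.54–0.73).
#' @param per_marker_specificity Marginal specificity among healthy
#'   controls (default evenly spaced 0.95–0.96).
#' @param shedding_sd Logit-scale SD of the case shedding factor (default
#'   2.0; chosen so the 2-of-8 panel rule attains conclusive-only
#'   sensitivity near 0.93 with the default marker sensitivities).
#' @param control_background_sd Logit-scale SD of the control background
#'   factor (default 3.0; concentrates control false positives in few
#'   patients, keeping the inconclusive rate realistic).
#' @param other_cancer_fp_odds Odds multiplier on false positives for
#'   other-urological-cancer controls relative to healthy (default 2).
#' @param stage_shedding_delta Optional shift of the shedding mean per unit
#'   of stage rank (Ta=0 ... T4=4, CIS=1); default 0 (stage independent of
#'   shedding).
#' @param conc_case_meanlog,conc_case_sdlog Log-normal concentration of a
#'   positive case marker (defaults 3, 0.8); the patient's shedding factor
#'   additionally shifts the log-mean by `0.25 * u_i`.
#' @param conc_control_meanlog,conc_control_sdlog Log-normal concentration
#'   of a positive control marker (defaults 0.5, 0.6).
#' @param background_zero_prob,background_meanlog,background_sdlog
#'   Zero-inflated trace background of negative markers (defaults 0.85,
#'   -1.5, 0.6).
#' @param prevalence_target Assumed population disease prevalence carried
#'   along for predictive-value calculations (default 0.20).
#' @param stage_probs,grade_probs Named sampling probabilities for case
#'   stage and grade (defaults mirror a gross-hematuria case mix).
#' @param grade_missing_prob Probability a case's grade is missing.
#' @param preset `"custom"`, `"discovery"` (112 samples: 26 cases, 56
#'   healthy, 30 other-cancer controls) or `"hematuria"` (273 samples, 93
#'   cases).
#' @param seed Integer seed.
#' @return A list of class `urine_sim_config`.
#' @export
urine_sim_config <- function(n_cases = 93L, n_controls_healthy = 180L,
                             n_controls_other = 0L,
                             per_marker_sensitivity = seq(0.54, 0.73, length.out = 8),
                             per_marker_specificity = seq(0.95, 0.96, length.out = 8),
                             shedding_sd = 2.0, control_background_sd = 3.0,
                             other_cancer_fp_odds = 2.0,
                             stage_shedding_delta = 0,
                             conc_case_meanlog = 3, conc_case_sdlog = 0.8,
                             conc_control_meanlog = 0.5, conc_control_sdlog = 0.6,
                             background_zero_prob = 0.85,
                             background_meanlog = -1.5, background_sdlog = 0.6,
                             prevalence_target = 0.20,
                             stage_probs = c(Ta = 0.46, T1 = 0.33, T2 = 0.10,
                                             T3 = 0.01, T4 = 0.02, CIS = 0.08),
                             grade_probs = c(low = 0.32, high = 0.68),
                             grade_missing_prob = 0.02,
                             preset = c("custom", "discovery", "hematuria"),
                             seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "discovery") {
    n_cases <- 26L; n_controls_healthy <- 56L; n_controls_other <- 30L
  } else if (preset == "hematuria") {
    n_cases <- 93L; n_controls_healthy <- 180L; n_controls_other <- 0L
  }
  if (length(per_marker_specificity) != length(per_marker_sensitivity))
    stop("sensitivity and specificity vectors must have equal length")
  if (any(per_marker_sensitivity <= 0) || any(per_marker_sensitivity >= 1) ||
      any(per_marker_specificity <= 0) || any(per_marker_specificity >= 1))
    stop("per-marker sensitivities and specificities must lie strictly in (0, 1)")
  stopifnot(shedding_sd >= 0, control_background_sd >= 0,
            prevalence_target > 0, prevalence_target < 1)
  stage_probs <- stage_probs / sum(stage_probs)
  grade_probs <- grade_probs / sum(grade_probs)
  structure(list(n_cases = as.integer(n_cases),
                 n_controls_healthy = as.integer(n_controls_healthy),
                 n_controls_other = as.integer(n_controls_other),
                 per_marker_sensitivity = per_marker_sensitivity,
                 per_marker_specificity = per_marker_specificity,
                 shedding_sd = shedding_sd,
                 control_background_sd = control_background_sd,
                 other_cancer_fp_odds = other_cancer_fp_odds,
                 stage_shedding_delta = stage_shedding_delta,
                 conc_case_meanlog = conc_case_meanlog,
                 conc_case_sdlog = conc_case_sdlog,
                 conc_control_meanlog = conc_control_meanlog,
                 conc_control_sdlog = conc_control_sdlog,
                 background_zero_prob = background_zero_prob,
                 background_meanlog = background_meanlog,
                 background_sdlog = background_sdlog,
                 prevalence_target = prevalence_target,
                 stage_probs = stage_probs, grade_probs = grade_probs,
                 grade_missing_prob = grade_missing_prob,
                 preset = preset, seed = as.integer(seed)),
            class = "urine_sim_config")
}

#' Simulate a urine biomarker cohort
#'
#' @param config A [urine_sim_config()].
#' @return A list with `cohort` (a `cohort_table` with one concentration
#'   column per marker, `marker_1` ... ) and `truth` (per-patient latent
#'   shedding factor and the true binary marker states as a matrix).
#' @export
simulate_urine_cohort <- function(config) {
  stopifnot(inherits(config, "urine_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  J <- length(cfg$per_marker_sensitivity)
  quad <- .gauss_hermite()
  a_case <- vapply(cfg$per_marker_sensitivity, .logit_intercept, 0,
                   sigma = cfg$shedding_sd, quad = quad)
  a_ctrl <- vapply(1 - cfg$per_marker_specificity, .logit_intercept, 0,
                   sigma = cfg$control_background_sd, quad = quad)

  groups <- rep(c("case", "control_healthy", "control_other_cancer"),
                c(cfg$n_cases, cfg$n_controls_healthy, cfg$n_controls_other))
  n <- length(groups)
  sample_id <- sprintf("S%04d", seq_len(n))

  stage <- rep(NA_character_, n)
  grade <- rep(NA_character_, n)
  is_case <- groups == "case"
  if (any(is_case)) {
    stage[is_case] <- sample(names(cfg$stage_probs), sum(is_case),
                             replace = TRUE, prob = cfg$stage_probs)
    grade[is_case] <- sample(names(cfg$grade_probs), sum(is_case),
                             replace = TRUE, prob = cfg$grade_probs)
    grade[is_case][stats::runif(sum(is_case)) < cfg$grade_missing_prob] <- NA
  }
  age <- round(stats::rnorm(n, mean = ifelse(is_case, 70, 63), sd = 10))

  stage_rank <- c(Ta = 0, T1 = 1, T2 = 2, T3 = 3, T4 = 4, CIS = 1)
  latent <- stats::rnorm(n) *
    ifelse(is_case, cfg$shedding_sd, cfg$control_background_sd)
  if (cfg$stage_shedding_delta != 0 && any(is_case))
    latent[is_case] <- latent[is_case] +
      cfg$stage_shedding_delta * stage_rank[stage[is_case]]

  fp_shift <- ifelse(groups == "control_other_cancer",
                     log(cfg$other_cancer_fp_odds), 0)

  state <- matrix(FALSE, n, J)
  conc <- matrix(0, n, J)
  for (j in seq_len(J)) {
    eta <- ifelse(is_case, a_case[j], a_ctrl[j] + fp_shift) + latent
    state[, j] <- stats::runif(n) < stats::plogis(eta)
    pos <- state[, j]
    # positive markers: high signal for cases (scaled by shedding), lower
    # background-driven signal for control false positives
    conc[pos & is_case, j] <- stats::rlnorm(sum(pos & is_case),
      meanlog = cfg$conc_case_meanlog + 0.25 * latent[pos & is_case],
      sdlog = cfg$conc_case_sdlog)
    conc[pos & !is_case, j] <- stats::rlnorm(sum(pos & !is_case),
      meanlog = cfg$conc_control_meanlog, sdlog = cfg$conc_control_sdlog)
    # negative markers: mostly exact zeros plus trace background
    neg <- !pos
    trace <- neg & (stats::runif(n) >= cfg$background_zero_prob)
    conc[trace, j] <- stats::rlnorm(sum(trace), cfg$background_meanlog,
                                    cfg$background_sdlog)
  }
  markers <- sprintf("marker_%d", seq_len(J))
  colnames(conc) <- markers
  df <- data.frame(sample_id = sample_id, group = groups, stage = stage,
                   grade = grade, age = age, stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(conc))
  cohort <- as_cohort_table(df, markers = markers)
  truth <- list(sample_id = sample_id, shedding = latent,
                state = `dimnames<-`(state, list(sample_id, markers)),
                case_intercepts = a_case, control_intercepts = a_ctrl)
  list(cohort = cohort, truth = truth)
}
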