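# Window-based DMR discovery: tile the genome at two scales, compute
# per-sample window methylation, filter by group-level criteria, merge
# overlapping windows into candidates and annotate TSS distality.

#' Window scan configuration
#'
#' @param window_sizes Window sizes in bp (default `c(200, 1000)`; the two
#'   scales are scanned independently and merged downstream).
#' @param step Step per window size in bp; defaults to the window size
#'   itself, i.e. non-overlapping tiling. A single value is recycled.
#' @param min_cpgs_per_window Minimum qualifying CpGs required inside a
#'   window in **every** sample (default 4).
#' @param min_coverage_per_cpg Minimum read coverage for a CpG to qualify
#'   (default 10).
#' @param min_target_beta Window-mean methylation a target sample must
#'   reach to count as methylated (default 0.4).
#' @param max_offtarget_beta Window-mean methylation above which an
#'   off-target sample counts as methylated (default 0.1).
#' @param min_target_fraction Minimum fraction of target samples at or
#'   above `min_target_beta` (default 0.75).
#' @param max_offtarget_fraction Maximum tolerated fraction of off-target
#'   samples above `max_offtarget_beta` (default 0, i.e. none).
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_sizes = c(200L, 1000L), step = NULL,
                          min_cpgs_per_window = 4L, min_coverage_per_cpg = 10L,
                          min_target_beta = 0.4, max_offtarget_beta = 0.1,
                          min_target_fraction = 0.75,
                          max_offtarget_fraction = 0) {
  window_sizes <- as.integer(window_sizes)
  if (any(window_sizes <= 0L)) stop("window sizes must be positive")
  if (is.null(step)) step <- window_sizes
  step <- as.integer(rep_len(step, length(window_sizes)))
  if (any(step <= 0L)) stop("step must be positive")
  thr <- c(min_target_beta, max_offtarget_beta, min_target_fraction,
           max_offtarget_fraction)
  if (any(thr < 0) || any(thr > 1)) stop("thresholds must lie in [0, 1]")
  structure(list(window_sizes = window_sizes, step = step,
                 min_cpgs_per_window = as.integer(min_cpgs_per_window),
                 min_coverage_per_cpg = as.integer(min_coverage_per_cpg),
                 min_target_beta = min_target_beta,
                 max_offtarget_beta = max_offtarget_beta,
                 min_target_fraction = min_target_fraction,
                 max_offtarget_fraction = max_offtarget_fraction),
            class = "window_config")
}

#' Scan samples with tiled windows and compute per-window methylation
#'
#' For each window size and chromosome, windows are placed on a regular
#' grid (`start = k * step`). A window is emitted only if every sample has
#' at least `min_cpgs_per_window` CpGs with coverage at or above
#' `min_coverage_per_cpg` inside it. The per-sample window beta is the
#' unweighted mean of that sample's qualifying per-CpG betas, and group
#' means are unweighted means over samples.
#'
#' @param samples Named list of [methylation_calls()] objects.
#' @param groups Named character vector mapping each sample id to
#'   `"target"` or `"offtarget"`; both groups must be non-empty.
#' @param config A [window_config()].
#' @return A data frame of class `window_stats`: `chrom`, `start`, `end`
#'   (0-based half-open), `window_size`, `n_cpgs` (minimum qualifying CpGs
#'   across samples), `target_mean`, `offtarget_mean`, `delta`, plus one
#'   `beta.<sample>` column per sample.
#' @export
scan_windows <- function(samples, groups, config = window_config()) {
  stopifnot(inherits(config, "window_config"), length(samples) >= 1L)
  ids <- names(samples)
  if (is.null(ids) || !all(ids %in% names(groups)))
    stop("every sample needs a group assignment")
  grp <- groups[ids]
  if (!all(grp %in% c("target", "offtarget")))
    stop("groups must be 'target' or 'offtarget'")
  if (!any(grp == "target") || !any(grp == "offtarget"))
    stop("both target and off-target groups must be non-empty")

  # pool qualifying CpGs across samples, tagged by sample index
  recs <- lapply(seq_along(samples), function(k) {
    r <- samples[[k]]$records
    cov <- r$n_meth + r$n_unmeth
    keep <- cov >= config$min_coverage_per_cpg
    data.frame(sample = k, chrom = r$chrom[keep], pos = r$pos[keep],
               beta = (r$n_meth / cov)[keep], stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  n_samp <- length(samples)
  out <- list()

  for (si in seq_along(config$window_sizes)) {
    size <- config$window_sizes[si]
    step <- config$step[si]
    for (chr in unique(recs$chrom)) {
      rc <- recs[recs$chrom == chr, , drop = FALSE]
      if (!nrow(rc)) next
      # window starts on the step grid that contain >= 1 pooled CpG
      k_lo <- ceiling((rc$pos - size + 1) / step)
      k_hi <- floor(rc$pos / step)
      ks <- unique(unlist(mapply(function(a, b) if (a <= b) a:b else integer(0),
                                 pmax(k_lo, 0L), k_hi, SIMPLIFY = FALSE)))
      if (!length(ks)) next
      win <- IRanges::IRanges(start = sort(ks) * step + 1L, width = size)
      cpg <- IRanges::IRanges(start = rc$pos + 1L, width = 1L)
      hits <- IRanges::findOverlaps(cpg, win)
      if (!length(hits)) next
      qh <- S4Vectors::queryHits(hits)
      sh <- S4Vectors::subjectHits(hits)
      nwin <- length(win)
      key <- (rc$sample[qh] - 1L) * nwin + sh  # (window, sample) cell index
      n_mat <- matrix(tabulate(key, nbins = nwin * n_samp), nwin, n_samp)
      bsum <- rowsum(rc$beta[qh], group = key)
      bvec <- numeric(nwin * n_samp)
      bvec[as.integer(rownames(bsum))] <- bsum[, 1L]
      b_mat <- matrix(bvec, nwin, n_samp) / ifelse(n_mat > 0L, n_mat, NA)
      ok <- apply(n_mat, 1L, min) >= config$min_cpgs_per_window
      if (!any(ok)) next
      betas <- b_mat[ok, , drop = FALSE]
      colnames(betas) <- paste0("beta.", ids)
      tmean <- rowMeans(betas[, grp == "target", drop = FALSE])
      omean <- rowMeans(betas[, grp == "offtarget", drop = FALSE])
      df <- data.frame(chrom = chr,
                       start = BiocGenerics::start(win)[ok] - 1L,
                       end = BiocGenerics::start(win)[ok] - 1L + size,
                       window_size = size,
                       n_cpgs = apply(n_mat[ok, , drop = FALSE], 1L, min),
                       target_mean = tmean, offtarget_mean = omean,
                       delta = tmean - omean, stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- cbind(df, betas)
    }
  }
  if (!length(out)) {
    res <- data.frame(chrom = character(), start = integer(), end = integer(),
                      window_size = integer(), n_cpgs = integer(),
                      target_mean = numeric(), offtarget_mean = numeric(),
                      delta = numeric())
    for (id in ids) res[[paste0("beta.", id)]] <- numeric()
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$start, res$window_size), , drop = FALSE]
    rownames(res) <- NULL
  }
  attr(res, "sample_ids") <- ids
  attr(res, "groups") <- grp
  class(res) <- c("window_stats", "data.frame")
  res
}

#' Filter scanned windows by group methylation criteria
#'
#' Retains windows where at least `min_target_fraction` of target samples
#' have window beta at or above `min_target_beta`, and at most
#' `max_offtarget_fraction` of off-target samples exceed
#' `max_offtarget_beta`.
#'
#' @param windows A `window_stats` data frame from [scan_windows()].
#' @param config The [window_config()] holding the thresholds.
#' @return The retained subset, same class and columns.
#' @export
filter_windows <- function(windows, config = window_config()) {
  stopifnot(inherits(windows, "window_stats"))
  grp <- attr(windows, "groups")
  ids <- attr(windows, "sample_ids")
  bt <- as.matrix(windows[, paste0("beta.", ids[grp == "target"]), drop = FALSE])
  bo <- as.matrix(windows[, paste0("beta.", ids[grp == "offtarget"]), drop = FALSE])
  frac_t <- rowMeans(bt >= config$min_target_beta)
  frac_o <- rowMeans(bo > config$max_offtarget_beta)
  keep <- frac_t >= config$min_target_fraction &
          frac_o <= config$max_offtarget_fraction
  if (!nrow(windows)) keep <- logical(0)
  out <- windows[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sample_ids") <- ids
  attr(out, "groups") <- grp
  class(out) <- class(windows)
  out
}

#' Merge overlapping windows into biomarker candidates
#'
#' Windows from all scales that overlap by at least 1 bp on the same
#' chromosome are unioned into a single candidate; abutting half-open
#' intervals do not merge. Output is sorted by `(chrom, start)`.
#'
#' @param windows A `window_stats` data frame (typically filtered).
#' @return A data frame of class `dmr_candidates` with columns
#'   `candidate_id`, `chrom`, `start`, `end`, `n_windows`,
#'   `mean_delta`, and a list column `source_windows` holding the row
#'   indices of the contributing windows.
#' @export
merge_candidates <- function(windows) {
  stopifnot(is.data.frame(windows),
            all(c("chrom", "start", "end") %in% names(windows)))
  empty <- data.frame(candidate_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_windows = integer(), mean_delta = numeric())
  if (!nrow(windows)) {
    empty$source_windows <- list()
    class(empty) <- c("dmr_candidates", "data.frame")
    return(empty)
  }
  out <- list()
  for (chr in sort(unique(windows$chrom))) {
    idx <- which(windows$chrom == chr)
    ir <- IRanges::IRanges(start = windows$start[idx] + 1L,
                           end = windows$end[idx])  # 1-based closed
    red <- IRanges::reduce(ir, min.gapwidth = 0L)   # strict overlap only
    ov <- IRanges::findOverlaps(ir, red)
    for (k in seq_along(red)) {
      src <- idx[S4Vectors::queryHits(ov)[S4Vectors::subjectHits(ov) == k]]
      out[[length(out) + 1L]] <- list(
        chrom = chr,
        start = BiocGenerics::start(red)[k] - 1L,
        end = BiocGenerics::end(red)[k],
        n_windows = length(src),
        mean_delta = if ("delta" %in% names(windows))
          mean(windows$delta[src]) else NA_real_,
        source_windows = src)
    }
  }
  res <- data.frame(
    candidate_id = sprintf("candidate_%03d", seq_along(out)),
    chrom = vapply(out, `[[`, character(1L), "chrom"),
    start = vapply(out, `[[`, integer(1L), "start"),
    end = vapply(out, `[[`, integer(1L), "end"),
    n_windows = vapply(out, `[[`, integer(1L), "n_windows"),
    mean_delta = vapply(out, `[[`, numeric(1L), "mean_delta"),
    stringsAsFactors = FALSE)
  res$source_windows <- lapply(out, `[[`, "source_windows")
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$candidate_id <- sprintf("candidate_%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  class(res) <- c("dmr_candidates", "data.frame")
  res
}

#' Annotate candidates with distance to the nearest TSS
#'
#' Distance is 0 when a TSS falls inside the half-open candidate interval;
#' otherwise the gap to the nearest interval edge. Candidates farther than
#' `distal_cutoff` (strictly) are flagged distal. Candidates on
#' chromosomes absent from the annotation get `NA` distance and flag.
#'
#' @param candidates A `dmr_candidates` data frame.
#' @param tss A `tss_annotation` data frame from [read_tss()], or any data
#'   frame with `chrom` and `tss_pos` (0-based).
#' @param distal_cutoff Distality cutoff in bp (default 1500).
#' @return `candidates` with added `tss_distance`, `nearest_gene` and
#'   `distal_flag` columns.
#' @export
annotate_tss <- function(candidates, tss, distal_cutoff = 1500) {
  stopifnot(is.data.frame(candidates), is.data.frame(tss),
            all(c("chrom", "tss_pos") %in% names(tss)))
  n <- nrow(candidates)
  dist <- rep(NA_real_, n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    t <- tss[tss$chrom == candidates$chrom[i], , drop = FALSE]
    if (!nrow(t)) next
    s <- candidates$start[i]; e <- candidates$end[i]
    d <- ifelse(t$tss_pos >= s & t$tss_pos < e, 0,
         ifelse(t$tss_pos < s, s - t$tss_pos, t$tss_pos - e))
    k <- which.min(d)
    dist[i] <- d[k]
    gene[i] <- if ("gene_id" %in% names(t)) t$gene_id[k] else NA_character_
  }
  candidates$tss_distance <- dist
  candidates$nearest_gene <- gene
  candidates$distal_flag <- ifelse(is.na(dist), NA, dist > distal_cutoff)
  candidates
}

#' Full discovery pass: scan, filter, merge (and optionally annotate)
#'
#' @inheritParams scan_windows
#' @param tss Optional TSS annotation for [annotate_tss()].
#' @param distal_cutoff Passed to [annotate_tss()].
#' @return A list with `windows` (all scanned), `filtered` and
#'   `candidates`.
#' @export
discover_dmrs <- function(samples, groups, config = window_config(),
                          tss = NULL, distal_cutoff = 1500) {
  w <- scan_windows(samples, groups, config)
  f <- filter_windows(w, config)
  cand <- merge_candidates(f)
  if (!is.null(tss)) cand <- annotate_tss(cand, tss, distal_cutoff)
  list(windows = w, filtered = f, candidates = cand)
}
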