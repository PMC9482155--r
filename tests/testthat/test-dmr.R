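test_that("window betas are unweighted means of qualifying CpG betas", {
  # one 200-bp window, CpG betas 0.0 and 1.0 -> window beta 0.5;
  # a CpG at coverage 9 (< 10) is excluded from the count
  t1 <- make_calls("t1", pos = c(10L, 50L, 120L, 150L, 180L),
                   n_meth = c(0L, 10L, 10L, 0L, 5L),
                   n_unmeth = c(10L, 0L, 0L, 10L, 4L))  # last has coverage 9
  o1 <- make_calls("o1", pos = c(10L, 50L, 120L, 150L),
                   n_meth = c(0L, 0L, 0L, 0L),
                   n_unmeth = c(10L, 10L, 10L, 10L))
  cfg <- window_config(window_sizes = 200L, min_cpgs_per_window = 4L)
  w <- scan_windows(list(t1 = t1, o1 = o1),
                    c(t1 = "target", o1 = "offtarget"), cfg)
  expect_equal(nrow(w), 1L)
  expect_equal(w$start, 0L); expect_equal(w$end, 200L)
  expect_equal(w$n_cpgs, 4L)            # coverage-9 CpG not counted
  expect_equal(w$beta.t1, 0.5)          # mean(0,1,1,0)
  expect_equal(w$beta.o1, 0)
  expect_equal(w$delta, 0.5)
  # dropping one qualifying CpG in one sample kills the window everywhere
  cfg5 <- window_config(window_sizes = 200L, min_cpgs_per_window = 5L)
  expect_equal(nrow(scan_windows(list(t1 = t1, o1 = o1),
                                 c(t1 = "target", o1 = "offtarget"), cfg5)), 0L)
})

test_that("scan_windows validates groups", {
  t1 <- make_calls("t1", 10L, 5L, 5L)
  expect_error(scan_windows(list(t1 = t1), c(t1 = "target")),
               "non-empty")
  expect_error(scan_windows(list(t1 = t1), c(t1 = "weird")),
               "target")
})

test_that("window scan equals a brute-force recomputation on a small locus", {
  set.seed(21)
  n <- 120
  pos <- sort(sample(0:9999, n))
  mk <- function(id) {
    cov <- rpois(n, 30) + 1L
    m <- rbinom(n, cov, runif(n))
    make_calls(id, pos, m, cov - m)
  }
  samples <- list(a = mk("a"), b = mk("b"), c = mk("c"), d = mk("d"))
  groups <- c(a = "target", b = "target", c = "offtarget", d = "offtarget")
  cfg <- window_config(window_sizes = c(200L, 1000L), min_cpgs_per_window = 2L,
                       min_coverage_per_cpg = 10L)
  w <- scan_windows(samples, groups, cfg)

  # brute force: every tiling window, recomputed per sample from scratch
  brute <- list()
  for (size in c(200L, 1000L)) for (s0 in seq(0L, 9999L, by = size)) {
    betas <- sapply(samples, function(smp) {
      r <- smp$records
      cov <- r$n_meth + r$n_unmeth
      i <- r$pos >= s0 & r$pos < s0 + size & cov >= 10L
      if (sum(i) < 2L) return(NA_real_)
      mean(r$n_meth[i] / cov[i])
    })
    if (anyNA(betas)) next
    brute[[length(brute) + 1L]] <- data.frame(
      start = s0, size = size,
      tmean = mean(betas[c("a", "b")]), omean = mean(betas[c("c", "d")]))
  }
  brute <- do.call(rbind, brute)
  brute <- brute[order(brute$start, brute$size), ]
  ww <- w[order(w$start, w$window_size), ]
  expect_equal(nrow(ww), nrow(brute))
  expect_equal(ww$start, brute$start)
  expect_equal(ww$target_mean, brute$tmean)
  expect_equal(ww$offtarget_mean, brute$omean)
})

test_that("filter_windows applies the group criteria row by row", {
  set.seed(31)
  n <- 100
  ids <- c(paste0("t", 1:8), paste0("o", 1:8))
  grp <- setNames(rep(c("target", "offtarget"), each = 8), ids)
  betas <- matrix(runif(n * 16), n, 16, dimnames = list(NULL, paste0("beta.", ids)))
  w <- data.frame(chrom = "chr1", start = seq_len(n) * 200L,
                  end = seq_len(n) * 200L + 200L, window_size = 200L,
                  n_cpgs = 4L,
                  target_mean = rowMeans(betas[, 1:8]),
                  offtarget_mean = rowMeans(betas[, 9:16]),
                  delta = rowMeans(betas[, 1:8]) - rowMeans(betas[, 9:16]))
  w <- cbind(w, as.data.frame(betas))
  attr(w, "sample_ids") <- ids; attr(w, "groups") <- grp
  class(w) <- c("window_stats", "data.frame")
  cfg <- window_config()
  got <- filter_windows(w, cfg)
  keep <- vapply(seq_len(n), function(i) {
    bt <- betas[i, 1:8]; bo <- betas[i, 9:16]
    mean(bt >= 0.4) >= 0.75 && mean(bo > 0.1) <= 0
  }, TRUE)
  expect_equal(got$start, w$start[keep])

  # boundary behavior: clean separation retained, one hot off-target rejects
  clean <- w[1, ]
  clean[paste0("beta.", ids)] <- c(rep(0.8, 8), rep(0.02, 8))
  attr(clean, "sample_ids") <- ids; attr(clean, "groups") <- grp
  class(clean) <- class(w)
  expect_equal(nrow(filter_windows(clean, cfg)), 1L)
  clean[["beta.o3"]] <- 0.5
  expect_equal(nrow(filter_windows(clean, cfg)), 0L)
})

test_that("overlap merging unions across scales but not abutting intervals", {
  w <- data.frame(chrom = "chr1", start = c(100L, 200L), end = c(300L, 1200L),
                  delta = c(0.5, 0.6))
  m <- merge_candidates(w)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 100L); expect_equal(m$end, 1200L)
  w2 <- data.frame(chrom = "chr1", start = c(100L, 300L), end = c(300L, 500L),
                   delta = c(0.5, 0.6))
  expect_equal(nrow(merge_candidates(w2)), 2L)  # touching, half-open
})

test_that("merging matches the union-find oracle, idempotently and order-invariantly", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(2:50, 1)
    start <- sample(0:2000, n, replace = TRUE)
    w <- data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    start = start, end = start + sample(1:400, n, TRUE),
                    delta = runif(n))
    m <- merge_candidates(w)
    o <- oracle_merge(w$chrom, w$start, w$end)
    expect_equal(m$start, o$start)
    expect_equal(m$end, o$end)
    expect_equal(m$chrom, o$chrom)
    # shuffling input yields identical candidates
    m2 <- merge_candidates(w[sample(n), ])
    expect_equal(m2[c("chrom", "start", "end")], m[c("chrom", "start", "end")])
    # idempotent
    m3 <- merge_candidates(m[c("chrom", "start", "end")])
    expect_equal(m3$start, m$start)
    expect_equal(m3$end, m$end)
    # every source window overlaps its candidate
    for (i in seq_len(nrow(m))) {
      src <- m$source_windows[[i]]
      expect_true(all(w$start[src] < m$end[i] & w$end[src] > m$start[i]))
    }
  }
})

test_that("TSS distance uses edge distance with inside = 0 and strict distality", {
  cand <- data.frame(candidate_id = "c1", chrom = "chr1",
                     start = 5000L, end = 5200L)
  tss <- data.frame(chrom = "chr1", tss_pos = 3000L, gene_id = "g1")
  a <- annotate_tss(cand, tss)
  expect_equal(a$tss_distance, 2000)
  expect_true(a$distal_flag)
  a <- annotate_tss(cand, data.frame(chrom = "chr1", tss_pos = 5100L, gene_id = "g"))
  expect_equal(a$tss_distance, 0)
  expect_false(a$distal_flag)
  a <- annotate_tss(cand, data.frame(chrom = "chr1", tss_pos = 6700L, gene_id = "g"))
  expect_equal(a$tss_distance, 1500)
  expect_false(a$distal_flag)  # strictly greater than 1500 required
  a <- annotate_tss(cand, data.frame(chrom = "chr9", tss_pos = 1L, gene_id = "g"))
  expect_true(is.na(a$tss_distance))
  expect_true(is.na(a$distal_flag))
})

test_that("QC summary matches direct recomputation", {
  mc <- make_calls("s", pos = c(5L, 9L), n_meth = c(5L, 10L),
                   n_unmeth = c(5L, 0L))
  qc <- sample_qc_summary(mc)
  expect_equal(qc$mean_coverage, 10)
  expect_equal(qc$mean_beta, 0.75)
  mc0 <- make_calls("s", pos = c(1L, 2L), n_meth = c(0L, 0L),
                    n_unmeth = c(4L, 6L))
  expect_equal(sample_qc_summary(mc0)$mean_beta, 0)
  set.seed(51)
  cov <- rpois(1000, 40) + 1L
  m <- rbinom(1000, cov, 0.3)
  mc1 <- make_calls("s", pos = seq_len(1000) * 10L, n_meth = m, n_unmeth = cov - m)
  qc1 <- sample_qc_summary(mc1)
  expect_equal(qc1$mean_coverage, sum(cov) / 1000)
  expect_equal(qc1$mean_beta, mean(m / cov))
})

test_that("a planted DMR is flagged by exactly the windows overlapping it", {
  cfg <- rrbs_sim_config(n_cpgs = 800L, coverage_mean = 60,
                         planted_dmrs = data.frame(span_bp = 500L,
                                                   target_beta = 0.9,
                                                   offtarget_beta = 0.05,
                                                   n_cpgs = 12L),
                         seed = 13L)
  rr <- simulate_rrbs(cfg)
  w <- scan_windows(rr$samples, rr$groups)
  hot <- w$delta > 0.7
  overlaps <- w$start < rr$truth$end & w$end > rr$truth$start
  expect_true(any(hot))
  expect_equal(which(hot), which(overlaps))
})
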