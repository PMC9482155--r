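# Independent brute-force oracles used by the property tests. These are
# deliberately naive re-implementations, kept separate from the package
# internals so they can disagree with them.

# O(n^2) transitive-closure merge of intervals (0-based half-open).
oracle_merge <- function(chrom, start, end) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && chrom[i] == chrom[j] &&
        start[i] < end[j] && start[j] < end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  # path-compress
  root <- vapply(seq_len(n), find, integer(1L))
  comp <- split(seq_len(n), root)
  out <- do.call(rbind, lapply(comp, function(idx)
    data.frame(chrom = chrom[idx[1L]], start = min(start[idx]),
               end = max(end[idx]), stringsAsFactors = FALSE)))
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# AUC by exhaustive pair counting (wins + half ties).
oracle_auc <- function(cases, controls) {
  wins <- 0
  for (x in cases) for (y in controls)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(cases) * length(controls))
}

# Exhaustive threshold search: midpoints between distinct pooled values
# plus extremes; positive means value > t; spec strictly above floor;
# maximize sensitivity, ties by spec then by threshold.
oracle_calibrate <- function(cases, controls, floor = 0.95) {
  v <- sort(unique(c(cases, controls)))
  cand <- c(v[1] - 1, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, v[length(v)])
  best <- NULL
  for (t in cand) {
    spec <- mean(controls <= t)
    if (spec <= floor) next
    sens <- mean(cases > t)
    if (is.null(best) || sens > best$sens ||
        (sens == best$sens && spec > best$spec) ||
        (sens == best$sens && spec == best$spec && t > best$t))
      best <- list(t = t, sens = sens, spec = spec)
  }
  best
}

# Hand-count diagnostic summary on a small fixture.
oracle_summary <- function(outcomes, is_case) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(outcomes)) {
    o <- as.character(outcomes[i])
    if (o == "INCONCLUSIVE") next
    if (is_case[i] && o == "POSITIVE") tp <- tp + 1L
    if (is_case[i] && o == "NEGATIVE") fn <- fn + 1L
    if (!is_case[i] && o == "POSITIVE") fp <- fp + 1L
    if (!is_case[i] && o == "NEGATIVE") tn <- tn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Tiny two-sample methylation fixture: CpGs at known positions with exact
# counts, for window-scan arithmetic.
make_calls <- function(id, pos, n_meth, n_unmeth, chrom = "chr1") {
  methylation_calls(id, rep(chrom, length(pos)), pos, n_meth, n_unmeth)
}

# Synthetic panel outcome vector from planted confusion counts: cases
# first, then controls. Counts are conclusive-only; inconclusive added on
# top.
planted_outcomes <- function(tp, fn, tn, fp, incon_cases = 0L, incon_controls = 0L) {
  outcomes <- c(rep("POSITIVE", tp), rep("NEGATIVE", fn),
                rep("INCONCLUSIVE", incon_cases),
                rep("NEGATIVE", tn), rep("POSITIVE", fp),
                rep("INCONCLUSIVE", incon_controls))
  is_case <- c(rep(TRUE, tp + fn + incon_cases),
               rep(FALSE, tn + fp + incon_controls))
  list(outcomes = outcomes, is_case = is_case)
}
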