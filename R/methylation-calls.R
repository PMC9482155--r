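#' Per-CpG methylation calls for one sample
#'
#' Container for the per-CpG methylated/unmethylated counts of a single
#' sample, the substrate of window-based DMR discovery. Positions are
#' 0-based cytosine coordinates; all internal coordinates in this package
#' are 0-based half-open, and conversions happen only at I/O boundaries.
#'
#' @param sample_id Single character sample identifier.
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 0-based CpG positions.
#' @param n_meth,n_unmeth Non-negative integer count vectors (methylated /
#'   unmethylated read support). `n_meth + n_unmeth` must be at least 1 for
#'   every record.
#'
#' @return An object of class `methylation_calls`: a list with elements
#'   `sample_id` and `records` (a data frame with columns `chrom`, `pos`,
#'   `n_meth`, `n_unmeth`, sorted by `(chrom, pos)`, duplicate positions
#'   merged by summing counts).
#' @seealso [read_coverage_file()], [sample_qc_summary()]
#' @export
#' @examples
#' mc <- methylation_calls("s1", c("chr1", "chr1"), c(100L, 250L),
#'                         n_meth = c(5L, 0L), n_unmeth = c(5L, 10L))
#' beta_values(mc)
methylation_calls <- function(sample_id, chrom, pos, n_meth, n_unmeth) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  n <- length(chrom)
  if (length(pos) != n || length(n_meth) != n || length(n_unmeth) != n)
    stop("chrom, pos, n_meth and n_unmeth must have equal length")
  pos <- as.integer(pos)
  n_meth <- as.integer(n_meth)
  n_unmeth <- as.integer(n_unmeth)
  if (any(is.na(pos)) || any(pos < 0L))
    stop("positions must be non-negative 0-based coordinates")
  if (any(is.na(n_meth)) || any(is.na(n_unmeth)) ||
      any(n_meth < 0L) || any(n_unmeth < 0L))
    stop("methylated/unmethylated counts must be non-negative integers")

  rec <- data.frame(chrom = as.character(chrom), pos = pos,
                    n_meth = n_meth, n_unmeth = n_unmeth,
                    stringsAsFactors = FALSE)
  # merge duplicate (chrom, pos) by summing counts: strand-split extractor
  # outputs collapse onto the cytosine position
  key <- paste(rec$chrom, rec$pos, sep = "\r")
  if (anyDuplicated(key)) {
    rec <- data.frame(
      chrom = tapply(rec$chrom, key, `[`, 1L),
      pos = as.integer(tapply(rec$pos, key, `[`, 1L)),
      n_meth = as.integer(tapply(rec$n_meth, key, sum)),
      n_unmeth = as.integer(tapply(rec$n_unmeth, key, sum)),
      stringsAsFactors = FALSE)
    rownames(rec) <- NULL
  }
  if (any(rec$n_meth + rec$n_unmeth < 1L))
    stop("every retained CpG record needs coverage >= 1")
  rec <- rec[order(rec$chrom, rec$pos), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(sample_id = sample_id, records = rec),
            class = "methylation_calls")
}

#' @export
print.methylation_calls <- function(x, ...) {
  r <- x$records
  cat(sprintf("<methylation_calls> sample '%s': %d CpGs on %d chromosome(s)\n",
              x$sample_id, nrow(r), length(unique(r$chrom))))
  if (nrow(r)) {
    qc <- sample_qc_summary(x)
    cat(sprintf("  mean coverage %.1fx, mean methylation %.1f%%\n",
                qc$mean_coverage, 100 * qc$mean_beta))
  }
  invisible(x)
}

#' Per-CpG methylation fractions (beta values)
#'
#' @param x A [methylation_calls()] object.
#' @return Numeric vector `n_meth / (n_meth + n_unmeth)`, one per record.
#' @export
beta_values <- function(x) {
  stopifnot(inherits(x, "methylation_calls"))
  with(x$records, n_meth / (n_meth + n_unmeth))
}

#' Coverage and methylation QC summary for one sample
#'
#' Mean read coverage, unweighted mean beta value and CpG count, the
#' per-sample quality numbers usually reported for an RRBS library.
#'
#' @param sample A [methylation_calls()] object with at least one record.
#' @return A list with `mean_coverage`, `mean_beta` and `n_cpgs`.
#' @export
sample_qc_summary <- function(sample) {
  stopifnot(inherits(sample, "methylation_calls"))
  r <- sample$records
  if (nrow(r) == 0L) stop("sample has no CpG records")
  cov <- r$n_meth + r$n_unmeth
  list(mean_coverage = mean(cov),
       mean_beta = mean(r$n_meth / cov),
       n_cpgs = nrow(r))
}
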