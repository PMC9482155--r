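#' Read a bismark-style coverage file
#'
#' Parses the tab-separated per-CpG coverage format emitted by common
#' bisulfite methylation extractors (`chrom, start, end, meth%, count_M,
#' count_U`; 1-based inclusive coordinates, optionally gzipped). The
#' methylation percentage column is ignored in favour of the counts.
#' Coordinates are converted to the package-internal 0-based convention and
#' duplicate positions are merged by summing counts.
#'
#' @param path Path to the coverage file (plain text or `.gz`).
#' @param sample_id Sample identifier; defaults to the file name without
#'   extensions.
#' @param dialect Input dialect; only `"bismark_cov"` is supported.
#' @return A [methylation_calls()] object.
#' @export
read_coverage_file <- function(path, sample_id = NULL,
                               dialect = c("bismark_cov")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("coverage file not found: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.(cov|txt|tsv)(\\.gz)?$", "", basename(path))

  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("coverage file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L))
    stop(sprintf("malformed coverage line %d in %s: expected 6 tab-separated fields",
                 which(nf < 6L)[1L], path))
  m <- matrix(unlist(lapply(fields, `[`, 1:6)), ncol = 6L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 2L]))
  n_meth <- suppressWarnings(as.integer(m[, 5L]))
  n_unmeth <- suppressWarnings(as.integer(m[, 6L]))
  bad <- which(is.na(start) | is.na(n_meth) | is.na(n_unmeth))
  if (length(bad))
    stop(sprintf("malformed coverage line %d in %s: non-numeric coordinate or count",
                 bad[1L], path))
  neg <- which(n_meth < 0L | n_unmeth < 0L)
  if (length(neg))
    stop(sprintf("invalid coverage line %d in %s: negative count", neg[1L], path))
  # bismark coverage is 1-based inclusive; internal is 0-based
  methylation_calls(sample_id, chrom = m[, 1L], pos = start - 1L,
                    n_meth = n_meth, n_unmeth = n_unmeth)
}

#' Write methylation calls as a bismark-style coverage file
#'
#' Inverse of [read_coverage_file()]: 1-based inclusive coordinates, six
#' tab-separated columns with the methylation percentage recomputed from
#' counts.
#'
#' @param x A [methylation_calls()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coverage_file <- function(x, path) {
  stopifnot(inherits(x, "methylation_calls"))
  r <- x$records
  pct <- 100 * r$n_meth / (r$n_meth + r$n_unmeth)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%d", r$chrom, r$pos + 1L, r$pos + 1L,
                   format(pct, trim = TRUE, digits = 7), r$n_meth, r$n_unmeth)
  writeLines(lines, path)
  invisible(path)
}

#' Read transcription start sites from BED6 or GFF3
#'
#' Extracts one strand-resolved TSS per feature: the feature start on the
#' plus strand, the last base on the minus strand. Returned positions are
#' 0-based.
#'
#' @param path Path to a BED6 or GFF3 file.
#' @param format `"BED6"` or `"GFF3"` (default guessed from the extension).
#' @return A data frame of class `tss_annotation` with columns `chrom`,
#'   `tss_pos` (0-based), `strand` and `gene_id`.
#' @export
read_tss <- function(path, format = c("auto", "BED6", "GFF3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(gff3?|gff)(\\.gz)?$", path, ignore.case = TRUE))
      "GFF3" else "BED6"
  gr <- if (format == "BED6") rtracklayer::import(path, format = "BED")
        else rtracklayer::import(path, format = "GFF3")
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    stop("feature(s) without strand: TSS is undefined")
  # GRanges are 1-based closed; 0-based TSS is start-1 (+) or end-1 (-)
  tss0 <- ifelse(strand == "+",
                 BiocGenerics::start(gr) - 1L,
                 BiocGenerics::end(gr) - 1L)
  mc <- S4Vectors::mcols(gr)
  gene_id <- if ("name" %in% names(mc)) as.character(mc$name)
             else if ("ID" %in% names(mc)) as.character(mc$ID)
             else if ("Name" %in% names(mc)) as.character(mc$Name)
             else paste0("feature_", seq_along(gr))
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    tss_pos = as.integer(tss0), strand = strand,
                    gene_id = gene_id, stringsAsFactors = FALSE)
  class(out) <- c("tss_annotation", "data.frame")
  out
}

.group_levels <- c("case", "control_healthy", "control_other_cancer")
.stage_levels <- c("Ta", "T1", "T2", "T3", "T4", "CIS")
.grade_levels <- c("low", "high")

#' Read a patient cohort table
#'
#' Reads a delimited table with header columns `sample_id`, `group`,
#' `stage`, `grade`, `age` and one column per panel marker (any further
#' columns are treated as marker methylation concentrations, in input
#' order). Groups must be one of `case`, `control_healthy`,
#' `control_other_cancer`; stages `Ta/T1/T2/T3/T4/CIS` and grades
#' `low/high` may only be present for cases. Missing values are `NA`
#' (empty field or literal `NA`), never silent zeros.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator (default tab).
#' @return A data frame of class `cohort_table` with attribute `markers`
#'   naming the marker columns.
#' @export
read_cohort <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  required <- c("sample_id", "group", "stage", "grade", "age")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort table lacks required column(s): ", paste(miss, collapse = ", "))
  markers <- setdiff(names(df), required)
  if (length(markers) == 0L) stop("cohort table has no marker columns")
  as_cohort_table(df, markers = markers)
}

#' Validate and classify a cohort data frame
#'
#' @param df Data frame with the [read_cohort()] column contract.
#' @param markers Character vector naming the marker concentration columns.
#' @return The validated data frame with class `cohort_table`.
#' @export
as_cohort_table <- function(df, markers) {
  stopifnot(is.data.frame(df), all(markers %in% names(df)))
  bad <- which(!df$group %in% .group_levels)
  if (length(bad))
    stop("unknown group label in row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(df$group[bad]), collapse = ", "))
  bad <- which(!is.na(df$stage) & !df$stage %in% .stage_levels)
  if (length(bad))
    stop("unknown stage label in row(s) ", paste(bad, collapse = ", "))
  bad <- which(!is.na(df$grade) & !df$grade %in% .grade_levels)
  if (length(bad))
    stop("unknown grade label in row(s) ", paste(bad, collapse = ", "))
  bad <- which(df$group != "case" & (!is.na(df$stage) | !is.na(df$grade)))
  if (length(bad))
    stop("stage/grade present for non-case row(s) ", paste(bad, collapse = ", "))
  for (mk in markers) {
    v <- df[[mk]]
    if (!is.numeric(v)) stop("marker column '", mk, "' is not numeric")
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in marker column '", mk, "'")
  }
  df$age <- as.numeric(df$age)
  attr(df, "markers") <- markers
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d samples (%d cases), %d markers\n",
              nrow(x), sum(x$group == "case"), length(attr(x, "markers"))))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Write a cohort table
#'
#' Writes the delimited format read back by [read_cohort()]
#' (tab-separated, header, `NA` for missing).
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write DMR candidates as BED
#'
#' BED output is 0-based half-open, matching the package-internal
#' convention, so intervals are written verbatim.
#'
#' @param candidates A `dmr_candidates` data frame from
#'   [merge_candidates()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_candidates_bed <- function(candidates, path) {
  stopifnot(is.data.frame(candidates),
            all(c("chrom", "start", "end") %in% names(candidates)))
  name <- if ("candidate_id" %in% names(candidates)) candidates$candidate_id
          else sprintf("candidate_%03d", seq_len(nrow(candidates)))
  lines <- sprintf("%s\t%d\t%d\t%s", candidates$chrom,
                   candidates$start, candidates$end, name)
  writeLines(lines, path)
  invisible(path)
}

#' Read a candidates BED file written by [write_candidates_bed()]
#'
#' @param path BED path (0-based half-open).
#' @return Data frame with `chrom`, `start`, `end`, `candidate_id`.
#' @export
read_candidates_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4L) names(df)[4L] <- "candidate_id"
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Write an analysis report
#'
#' Serializes a diagnostic summary (or any list/data frame of results) as
#' JSON or TSV. Confusion counts are written as integers.
#'
#' @param summary Object to serialize (e.g. a `diagnostic_summary`).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(summary, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  x <- unclass(summary)
  if (format == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  } else {
    flat <- x[!vapply(x, is.list, logical(1L))]
    df <- data.frame(field = names(flat),
                     value = vapply(flat, function(v)
                       paste(format(v, digits = 12), collapse = ","),
                       character(1L)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
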