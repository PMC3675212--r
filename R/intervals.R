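#' Harmonize chromosome names
#'
#' miRBase and Ensembl annotation releases disagree on chromosome naming
#' (\code{chr1} vs \code{1}). Harmonization strips a leading \code{chr}
#' prefix (case-insensitively) and then applies an optional user alias
#' table, after which names are compared by exact string match.
#'
#' @param x character vector of chromosome names.
#' @param aliases optional named character vector mapping source names to
#'   harmonized names, applied after prefix stripping.
#' @return character vector of harmonized names.
#' @export
#' @examples
#' harmonize_chrom(c("chr1", "1", "chrX"))
harmonize_chrom <- function(x, aliases = NULL) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    x[hit] <- unname(aliases[x[hit]])
  }
  if (any(!nzchar(x))) stop("empty chromosome name after harmonization")
  x
}

#' Construct a genomic interval
#'
#' Coordinates are 1-based and inclusive at both ends, the native
#' convention of GFF/GTF files and of IRanges; the same convention is used
#' internally throughout the package so no coordinate shifting ever occurs.
#'
#' @param chrom chromosome name (harmonized).
#' @param start,end integer coordinates, 1-based inclusive, start <= end.
#' @param strand \code{"+"} or \code{"-"}.
#' @return a list with class \code{genomic_interval}.
#' @export
genomic_interval <- function(chrom, start, end, strand) {
  start <- as.integer(start); end <- as.integer(end)
  if (!nzchar(chrom)) stop("chrom must be non-empty")
  if (is.na(start) || start < 1L) stop("start must be >= 1")
  if (is.na(end) || start > end) stop("start must be <= end")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(chrom = as.character(chrom), start = start, end = end,
                 strand = strand),
            class = "genomic_interval")
}

interval_width <- function(x) x$end - x$start + 1L

# containment of b inside a, strand-blind; both are genomic_interval-like
# lists or one-row data.frames with chrom/start/end fields
interval_contains <- function(a, b) {
  a$chrom == b$chrom && a$start <= b$start && b$end <= a$end
}

# validate a data.frame of intervals (columns chrom, start, end, strand)
check_interval_frame <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(df$start < 1L | df$start > df$end)
  if (length(bad)) {
    stop(sprintf("%s rows with invalid coordinates: %s", what,
                 paste(utils::head(bad, 5L), collapse = ", ")))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    stop(sprintf("%s rows with strand outside {+, -}", what))
  }
  if (any(!nzchar(df$chrom))) stop(sprintf("%s rows with empty chrom", what))
  invisible(df)
}

# GRanges from a chrom/start/end(/strand) data.frame; strand optional
as_granges <- function(df, use_strand = TRUE) {
  strand <- if (use_strand && "strand" %in% names(df)) df$strand else "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = strand
  )
}

# one-decimal truncation; the convention behind printed fractions like
# 53.0% for 849/1600 (= 53.0625%), which rounding would turn into 53.1
trunc_one_decimal <- function(x) floor(x * 10 + 1e-9) / 10

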