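# Mature miRNA seed regions and their overlap with variants.

#' Seed-region definition
#'
#' The seed is the stretch of consecutive nucleotides counted 1-based
#' from the mature miRNA's 5' end that dominates target recognition;
#' positions 2-8 by default, 2-7 being the alternative convention (a
#' subset of 2-8).
#'
#' @param first,last 1-based positions from the mature 5' end,
#'   \code{1 <= first < last <= 10}.
#' @return list of class \code{seed_definition}.
#' @export
seed_definition <- function(first = 2L, last = 8L) {
  first <- as.integer(first); last <- as.integer(last)
  if (is.na(first) || is.na(last) || first < 1L || first >= last ||
      last > 10L) {
    stop("seed must satisfy 1 <= first < last <= 10")
  }
  structure(list(first = first, last = last), class = "seed_definition")
}

#' Project a mature miRNA seed to genomic coordinates
#'
#' On the plus strand the mature 5' end is its genomic start, so seed
#' positions first..last map to
#' \code{[start + first - 1, start + last - 1]}; on the minus strand the
#' 5' end is the genomic end, giving
#' \code{[end - last + 1, end - first + 1]}.
#'
#' @param mature one mature record: list/one-row data.frame with
#'   \code{mature_id}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}.
#' @param seed a \code{\link{seed_definition}}.
#' @return a \code{\link{genomic_interval}} of width
#'   \code{last - first + 1} contained in the mature interval.
#' @export
project_seed <- function(mature, seed = seed_definition()) {
  len <- mature$end - mature$start + 1L
  if (len < seed$last) {
    stop("mature ", mature$mature_id, " shorter than seed position ",
         seed$last)
  }
  if (mature$strand == "+") {
    genomic_interval(mature$chrom, mature$start + seed$first - 1L,
                     mature$start + seed$last - 1L, "+")
  } else {
    genomic_interval(mature$chrom, mature$end - seed$last + 1L,
                     mature$end - seed$first + 1L, "-")
  }
}

#' Overlap variants with mature miRNA seed regions
#'
#' A hit is recorded for every variant whose reference span (position
#' through position + nchar(ref) - 1, so an indel's whole reference
#' footprint counts) overlaps any base of a projected seed.
#' Multi-allelic records count once. The reported \code{offset} is the
#' seed position (1 = seed base closest to the mature 5' end) of the
#' overlapping base nearest the 5' end.
#'
#' @param mirnas a \code{\link{mirna_set}} (matures are screened).
#' @param variants data.frame from \code{\link{read_variant_table}}.
#' @param seed a \code{\link{seed_definition}}.
#' @return data.frame with columns \code{mature_id}, \code{precursor_id},
#'   \code{variant_id}, \code{offset}, \code{seed_start},
#'   \code{seed_end}; sorted by (mature_id, variant_id).
#' @export
find_seed_variants <- function(mirnas, variants,
                               seed = seed_definition()) {
  mat <- mirnas$matures
  empty <- data.frame(mature_id = character(), precursor_id = character(),
                      variant_id = character(), offset = integer(),
                      seed_start = integer(), seed_end = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(mat) == 0L || is.null(variants) || nrow(variants) == 0L) {
    return(empty)
  }
  rows <- list()
  var_end <- variants$pos + nchar(variants$ref_allele) - 1L
  for (i in seq_len(nrow(mat))) {
    m <- mat[i, ]
    if (m$end - m$start + 1L < seed$last) next
    sd <- project_seed(m, seed)
    hit <- variants$chrom == sd$chrom & variants$pos <= sd$end &
      var_end >= sd$start
    if (!any(hit)) next
    vh <- variants[hit, , drop = FALSE]
    vh_end <- var_end[hit]
    offset <- if (m$strand == "+") {
      pmax(vh$pos, sd$start) - sd$start + 1L
    } else {
      sd$end - pmin(vh_end, sd$end) + 1L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mature_id = m$mature_id, precursor_id = m$derives_from,
      variant_id = vh$variant_id, offset = as.integer(offset),
      seed_start = sd$start, seed_end = sd$end, stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$mature_id, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize seed polymorphism over a catalog
#'
#' A precursor counts as polymorphic if any of its matures has at least
#' one seed-variant hit; the denominator is the set of distinct
#' intragenic precursors in the catalog.
#'
#' @param catalog a \code{catalog}.
#' @param hits output of \code{\link{find_seed_variants}}.
#' @return list with \code{intragenic_count}, \code{polymorphic_count},
#'   \code{percent} (truncated to one decimal; NA when no intragenic
#'   miRNAs).
#' @export
seed_polymorphism_summary <- function(catalog, hits) {
  intra <- unique(catalog$assignments$precursor_id)
  poly <- intersect(unique(hits$precursor_id), intra)
  pct <- if (length(intra)) {
    trunc_one_decimal(100 * length(poly) / length(intra))
  } else NA_real_
  list(intragenic_count = length(intra),
       polymorphic_count = length(poly), percent = pct)
}
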