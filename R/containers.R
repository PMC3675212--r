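#' miRNA gene set
#'
#' Container for miRNA precursor genes and their linked mature products.
#' Precursors correspond to miRBase \code{miRNA_primary_transcript}
#' records (the hairpin-length unit screened for host containment);
#' matures to \code{miRNA} records linked by \code{Derives_from}.
#'
#' @param mirnas data.frame with columns \code{precursor_id}, \code{name},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}.
#' @param matures data.frame with columns \code{mature_id}, \code{name},
#'   \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{derives_from}.
#' @return object of class \code{mirna_set}.
#' @export
mirna_set <- function(mirnas = empty_mirna_frame(),
                      matures = empty_mature_frame()) {
  mirnas <- as.data.frame(mirnas, stringsAsFactors = FALSE)
  matures <- as.data.frame(matures, stringsAsFactors = FALSE)
  check_interval_frame(mirnas, "precursor")
  check_interval_frame(matures, "mature")
  if (anyDuplicated(mirnas$precursor_id)) {
    stop("duplicate precursor_id in miRNA set")
  }
  if (nrow(matures)) {
    idx <- match(matures$derives_from, mirnas$precursor_id)
    if (anyNA(idx)) {
      stop("mature records with unknown Derives_from: ",
           paste(matures$mature_id[is.na(idx)], collapse = ", "))
    }
    bad_strand <- matures$strand != mirnas$strand[idx]
    if (any(bad_strand)) {
      stop("mature on a different strand than its precursor: ",
           paste(matures$mature_id[bad_strand], collapse = ", "))
    }
    contained <- matures$chrom == mirnas$chrom[idx] &
      matures$start >= mirnas$start[idx] & matures$end <= mirnas$end[idx]
    if (any(!contained)) {
      stop("mature not contained in its precursor: ",
           paste(matures$mature_id[!contained], collapse = ", "))
    }
  }
  ord <- order(mirnas$chrom, mirnas$start, mirnas$name)
  mirnas <- mirnas[ord, , drop = FALSE]
  rownames(mirnas) <- NULL
  rownames(matures) <- NULL
  structure(list(mirnas = mirnas, matures = matures), class = "mirna_set")
}

empty_mirna_frame <- function() {
  data.frame(precursor_id = character(), name = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

empty_mature_frame <- function() {
  data.frame(mature_id = character(), name = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), derives_from = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.mirna_set <- function(x, ...) {
  cat(sprintf("mirna_set: %d precursors, %d matures on %d sequence(s)\n",
              nrow(x$mirnas), nrow(x$matures),
              length(unique(x$mirnas$chrom))))
  invisible(x)
}

#' Gene model set
#'
#' Container for host-gene models: genes with biotype, their transcripts,
#' and per-transcript exon and UTR intervals. Introns are derived at
#' construction as the gaps between genomically adjacent exons of each
#' transcript; the gene span is the hull of its transcript spans.
#'
#' @param genes data.frame with columns \code{gene_id}, \code{symbol},
#'   \code{biotype}, \code{chrom}, \code{strand} (span start/end derived).
#' @param transcripts data.frame with columns \code{transcript_id},
#'   \code{gene_id} (span and strand derived from exons).
#' @param exons data.frame with columns \code{transcript_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @param five_utr,three_utr data.frames with the same columns as
#'   \code{exons}; possibly empty.
#' @return object of class \code{gene_set}.
#' @export
gene_set <- function(genes, transcripts, exons,
                     five_utr = empty_feature_frame(),
                     three_utr = empty_feature_frame()) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  transcripts <- as.data.frame(transcripts, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  five_utr <- as.data.frame(five_utr, stringsAsFactors = FALSE)
  three_utr <- as.data.frame(three_utr, stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene_id in gene set")
  genes$biotype <- map_biotype(genes$biotype)

  if (nrow(transcripts)) {
    no_exon <- setdiff(transcripts$transcript_id, exons$transcript_id)
    if (length(no_exon)) {
      stop("transcript with zero exons: ", paste(no_exon, collapse = ", "))
    }
  }
  check_interval_frame(exons, "exon")

  # order exons genomically within transcript, check pairwise disjoint and
  # single chrom/strand
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  introns <- empty_feature_frame()
  tx_span <- NULL
  if (nrow(exons)) {
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    intron_rows <- vector("list", length(by_tx))
    span_rows <- vector("list", length(by_tx))
    for (i in seq_along(by_tx)) {
      rows <- by_tx[[i]]
      tid <- exons$transcript_id[rows[1L]]
      if (length(unique(exons$chrom[rows])) > 1L ||
          length(unique(exons$strand[rows])) > 1L) {
        stop("exons of transcript ", tid, " span multiple chrom/strand")
      }
      s <- exons$start[rows]; e <- exons$end[rows]
      if (length(rows) > 1L && any(s[-1L] <= e[-length(e)])) {
        stop("overlapping exons in transcript ", tid)
      }
      span_rows[[i]] <- data.frame(
        transcript_id = tid, chrom = exons$chrom[rows[1L]],
        start = s[1L], end = e[length(e)],
        strand = exons$strand[rows[1L]], stringsAsFactors = FALSE)
      if (length(rows) > 1L) {
        intron_rows[[i]] <- data.frame(
          transcript_id = tid, chrom = exons$chrom[rows[1L]],
          start = e[-length(e)] + 1L, end = s[-1L] - 1L,
          strand = exons$strand[rows[1L]], stringsAsFactors = FALSE)
      }
    }
    introns <- do.call(rbind, c(intron_rows[!vapply(intron_rows, is.null,
                                                    logical(1L))],
                                list(empty_feature_frame())))
    tx_span <- do.call(rbind, span_rows)
  }

  # transcript table gains chrom/strand/span from exons
  if (nrow(transcripts)) {
    idx <- match(transcripts$transcript_id, tx_span$transcript_id)
    transcripts$chrom <- tx_span$chrom[idx]
    transcripts$start <- tx_span$start[idx]
    transcripts$end <- tx_span$end[idx]
    transcripts$strand <- tx_span$strand[idx]
  } else {
    transcripts <- data.frame(transcript_id = character(),
                              gene_id = character(), chrom = character(),
                              start = integer(), end = integer(),
                              strand = character(), stringsAsFactors = FALSE)
  }

  # UTR intervals must sit inside the exon union of their transcript
  for (utr in list(`5'-UTR` = five_utr, `3'-UTR` = three_utr)) {
    if (!nrow(utr)) next
    check_interval_frame(utr, "UTR")
    for (k in seq_len(nrow(utr))) {
      rows <- exons$transcript_id == utr$transcript_id[k]
      covered <- any(exons$start[rows] <= utr$start[k] &
                     utr$end[k] <= exons$end[rows])
      if (!covered) {
        stop("UTR interval outside exons of transcript ",
             utr$transcript_id[k])
      }
    }
  }

  # gene span = hull of transcript spans
  genes$start <- rep(NA_integer_, nrow(genes))
  genes$end <- rep(NA_integer_, nrow(genes))
  if (nrow(transcripts)) {
    sp <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
    gi <- match(names(sp), genes$gene_id)
    if (anyNA(gi)) stop("transcript with unknown gene_id: ",
                        paste(names(sp)[is.na(gi)], collapse = ", "))
    for (i in seq_along(sp)) {
      rows <- sp[[i]]
      genes$start[gi[i]] <- min(transcripts$start[rows])
      genes$end[gi[i]] <- max(transcripts$end[rows])
      genes$chrom[gi[i]] <- transcripts$chrom[rows[1L]]
      genes$strand[gi[i]] <- transcripts$strand[rows[1L]]
    }
  }
  genes <- genes[!is.na(genes$start), , drop = FALSE]
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  rownames(transcripts) <- NULL
  rownames(introns) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 introns = introns, five_utr = five_utr,
                 three_utr = three_utr),
            class = "gene_set")
}

empty_feature_frame <- function() {
  data.frame(transcript_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

empty_gene_set <- function() {
  gene_set(
    genes = data.frame(gene_id = character(), symbol = character(),
                       biotype = character(), chrom = character(),
                       strand = character(), stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = character(),
                             gene_id = character(), stringsAsFactors = FALSE),
    exons = empty_feature_frame())
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set: %d genes, %d transcripts, %d exons\n",
              nrow(x$genes), nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

BIOTYPE_LEVELS <- c("protein_coding", "lincRNA", "snoRNA", "miRNA",
                    "other_ncRNA")

map_biotype <- function(x) {
  x <- as.character(x)
  known <- x %in% BIOTYPE_LEVELS
  if (any(!known)) {
    message("unrecognized biotype(s) mapped to other_ncRNA: ",
            paste(unique(x[!known]), collapse = ", "))
    x[!known] <- "other_ncRNA"
  }
  x
}

#' Extract one transcript model from a gene set
#'
#' @param gs a \code{gene_set}.
#' @param transcript_id transcript identifier.
#' @return a list with \code{transcript_id}, \code{gene_id}, \code{chrom},
#'   \code{strand}, span \code{start}/\code{end}, and data.frames
#'   \code{exons}, \code{introns}, \code{five_utr}, \code{three_utr}
#'   (genomic order).
#' @export
get_transcript <- function(gs, transcript_id) {
  i <- match(transcript_id, gs$transcripts$transcript_id)
  if (is.na(i)) stop("unknown transcript_id: ", transcript_id)
  tx <- gs$transcripts[i, ]
  pick <- function(df) {
    out <- df[df$transcript_id == transcript_id, , drop = FALSE]
    out[order(out$start), , drop = FALSE]
  }
  list(transcript_id = transcript_id, gene_id = tx$gene_id,
       chrom = tx$chrom, strand = tx$strand, start = tx$start,
       end = tx$end, exons = pick(gs$exons), introns = pick(gs$introns),
       five_utr = pick(gs$five_utr), three_utr = pick(gs$three_utr))
}
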