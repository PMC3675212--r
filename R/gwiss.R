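# Transcript-resolved placement classification and genome-wide screen.
#
# "Located within" means full containment of the precursor interval in the
# host gene span on the same strand; antisense containments and partial
# sense overlaps are tallied but excluded from the catalog.

PLACEMENT_KINDS <- c("five_utr", "exon", "intron", "three_utr", "junction")
CATEGORY_LEVELS <- c("intron", "exon", "five_utr", "three_utr", "mixed",
                     "gene_body")

kind_display <- c(five_utr = "5'-UTR", exon = "exon", intron = "intron",
                  three_utr = "3'-UTR", junction = "junction")

# merge sorted-by-start intervals into maximal runs; returns matrix
merge_runs <- function(start, end) {
  if (length(start) == 0L) return(cbind(start = integer(), end = integer()))
  o <- order(start)
  start <- start[o]; end <- end[o]
  ms <- start[1L]; me <- end[1L]
  out_s <- integer(); out_e <- integer()
  for (i in seq_along(start)[-1L]) {
    if (start[i] <= me + 1L) {
      me <- max(me, end[i])
    } else {
      out_s <- c(out_s, ms); out_e <- c(out_e, me)
      ms <- start[i]; me <- end[i]
    }
  }
  cbind(start = c(out_s, ms), end = c(out_e, me))
}

within_union <- function(s, e, runs) {
  nrow(runs) > 0L && any(runs[, "start"] <= s & e <= runs[, "end"])
}

#' Classify an interval within one transcript
#'
#' Returns the placement of a (miRNA precursor) interval relative to one
#' transcript model: \code{five_utr} / \code{three_utr} if fully inside
#' the spliced UTR (UTR takes precedence over the exon label),
#' \code{intron k} / \code{exon k} if fully inside the k-th intron/exon,
#' or \code{junction} if it straddles an exon-intron boundary. Ordinals
#' are numbered in transcription direction, so intron 1 is the first
#' intron of the transcript on either strand. \code{NULL} if the interval
#' is not fully within the transcript span or chrom/strand differ.
#'
#' @param interval a list/one-row data.frame with \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @param transcript a transcript model, see \code{\link{get_transcript}}.
#' @return list with \code{transcript_id}, \code{kind}, \code{ordinal}
#'   (NA for UTR/junction placements), or \code{NULL}.
#' @export
classify_in_transcript <- function(interval, transcript) {
  s <- interval$start; e <- interval$end
  if (interval$chrom != transcript$chrom ||
      interval$strand != transcript$strand) return(NULL)
  if (s < transcript$start || e > transcript$end) return(NULL)
  plus <- transcript$strand == "+"
  placement <- function(kind, ordinal = NA_integer_) {
    list(transcript_id = transcript$transcript_id, kind = kind,
         ordinal = as.integer(ordinal))
  }
  if (within_union(s, e, merge_runs(transcript$five_utr$start,
                                    transcript$five_utr$end))) {
    return(placement("five_utr"))
  }
  if (within_union(s, e, merge_runs(transcript$three_utr$start,
                                    transcript$three_utr$end))) {
    return(placement("three_utr"))
  }
  ni <- nrow(transcript$introns)
  if (ni) {
    j <- which(transcript$introns$start <= s & e <= transcript$introns$end)
    if (length(j) == 1L) {
      return(placement("intron", if (plus) j else ni - j + 1L))
    }
  }
  ne <- nrow(transcript$exons)
  j <- which(transcript$exons$start <= s & e <= transcript$exons$end)
  if (length(j) == 1L) {
    return(placement("exon", if (plus) j else ne - j + 1L))
  }
  placement("junction")
}

#' Aggregate per-transcript placements into a location label and category
#'
#' Placements collected across all transcripts of one host gene for one
#' miRNA are folded into a canonical label: kind groups in the fixed order
#' 5'-UTR, exon, intron, 3'-UTR, junction, each with ascending
#' deduplicated ordinals ("exon 7; intron 4, 5, 6"). The category is the
#' single kind when only one occurs, \code{mixed} when several kinds (or
#' any junction) occur, and \code{gene_body} for an empty placement list
#' (contained in the gene span but in no transcript span).
#'
#' @param placements data.frame with columns \code{kind}, \code{ordinal},
#'   or a list of placement lists.
#' @return list with \code{location_label} and \code{category}.
#' @export
aggregate_assignment <- function(placements) {
  if (is.list(placements) && !is.data.frame(placements)) {
    placements <- do.call(rbind, lapply(placements, function(p) {
      data.frame(kind = p$kind, ordinal = p$ordinal,
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(placements) || nrow(placements) == 0L) {
    return(list(location_label = "gene-body", category = "gene_body"))
  }
  stopifnot(all(placements$kind %in% PLACEMENT_KINDS))
  groups <- character()
  for (k in PLACEMENT_KINDS) {
    rows <- placements$kind == k
    if (!any(rows)) next
    ords <- sort(unique(placements$ordinal[rows]))
    ords <- ords[!is.na(ords)]
    groups <- c(groups, if (length(ords)) {
      paste0(kind_display[[k]], " ", paste(ords, collapse = ", "))
    } else {
      kind_display[[k]]
    })
  }
  kinds <- unique(placements$kind)
  category <- if ("junction" %in% kinds || length(kinds) > 1L) {
    "mixed"
  } else {
    kinds
  }
  list(location_label = paste(groups, collapse = "; "), category = category)
}

empty_assignment_frame <- function() {
  data.frame(precursor_id = character(), mirna_name = character(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), gene_id = character(),
             gene_symbol = character(), gene_biotype = character(),
             containment = character(), location_label = character(),
             category = character(), stringsAsFactors = FALSE)
}

#' Assign miRNA precursors to host genes (genome-wide screen)
#'
#' Emits one assignment for every (miRNA, gene) pair on the same
#' chromosome and strand where the precursor interval is fully contained
#' in the gene span (closed-interval containment, so a precursor
#' coterminous with the gene boundary counts). A miRNA inside two
#' overlapping genes yields two assignments. Opposite-strand containments
#' and same-strand partial overlaps are tallied separately and excluded.
#' Each assignment is classified against every transcript of the host and
#' aggregated with \code{\link{aggregate_assignment}}.
#'
#' @param mirnas a \code{\link{mirna_set}}.
#' @param genes a \code{\link{gene_set}} from the same species/assembly.
#' @return list with \code{assignments} (data.frame sorted by chrom,
#'   start, precursor_id, gene_id), \code{placements} (per-transcript
#'   detail), \code{antisense} and \code{partial} tallies.
#' @export
assign_hosts <- function(mirnas, genes) {
  m <- mirnas$mirnas
  g <- genes$genes
  empty <- list(assignments = empty_assignment_frame(),
                placements = data.frame(precursor_id = character(),
                                        gene_id = character(),
                                        transcript_id = character(),
                                        kind = character(),
                                        ordinal = integer(),
                                        stringsAsFactors = FALSE),
                antisense = 0L, partial = 0L)
  if (nrow(m) == 0L || nrow(g) == 0L) return(empty)

  # seqinfo warning is benign when the two sets cover different
  # chromosomes (e.g. miRNAs only on a subset)
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(m, use_strand = FALSE),
                                as_granges(g, use_strand = FALSE),
                                ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  if (length(qi) == 0L) return(empty)
  same_strand <- m$strand[qi] == g$strand[si]
  within <- g$start[si] <= m$start[qi] & m$end[qi] <= g$end[si]
  antisense <- sum(!same_strand & within)
  partial <- sum(same_strand & !within)
  keep <- same_strand & within
  qi <- qi[keep]; si <- si[keep]
  if (length(qi) == 0L) {
    empty$antisense <- antisense; empty$partial <- partial
    return(empty)
  }

  # transcript models for the genes that received assignments, built once
  tx_by_gene <- split(genes$transcripts$transcript_id,
                      genes$transcripts$gene_id)
  needed_tx <- unique(unlist(tx_by_gene[unique(g$gene_id[si])],
                             use.names = FALSE))
  tx_models <- lapply(needed_tx, get_transcript, gs = genes)
  names(tx_models) <- needed_tx

  rows <- vector("list", length(qi))
  pl_rows <- vector("list", length(qi))
  for (k in seq_along(qi)) {
    mi <- m[qi[k], ]; gi <- g[si[k], ]
    pls <- list()
    for (tid in tx_by_gene[[gi$gene_id]]) {
      p <- classify_in_transcript(mi, tx_models[[tid]])
      if (!is.null(p)) pls[[length(pls) + 1L]] <- p
    }
    agg <- aggregate_assignment(pls)
    rows[[k]] <- data.frame(
      precursor_id = mi$precursor_id, mirna_name = mi$name,
      chrom = mi$chrom, start = mi$start, end = mi$end,
      strand = mi$strand, gene_id = gi$gene_id, gene_symbol = gi$symbol,
      gene_biotype = gi$biotype, containment = "full",
      location_label = agg$location_label, category = agg$category,
      stringsAsFactors = FALSE)
    if (length(pls)) {
      pl_rows[[k]] <- data.frame(
        precursor_id = mi$precursor_id, gene_id = gi$gene_id,
        transcript_id = vapply(pls, `[[`, "", "transcript_id"),
        kind = vapply(pls, `[[`, "", "kind"),
        ordinal = vapply(pls, `[[`, integer(1L), "ordinal"),
        stringsAsFactors = FALSE)
    }
  }
  a <- do.call(rbind, rows)
  ord <- order(a$chrom, a$start, a$precursor_id, a$gene_id)
  a <- a[ord, , drop = FALSE]
  rownames(a) <- NULL
  pl <- do.call(rbind, c(pl_rows[!vapply(pl_rows, is.null, logical(1L))],
                         list(empty$placements)))
  rownames(pl) <- NULL
  list(assignments = a, placements = pl, antisense = antisense,
       partial = partial)
}

#' Detect intragenic miRNA clusters
#'
#' A cluster is a host gene with two or more resident miRNA genes (the
#' polycistronic-host reading of clustering; proximity-based clustering
#' is out of scope). Cluster identifiers are \code{cluster:<gene_id>}.
#'
#' @param assignments an assignment data.frame from
#'   \code{\link{assign_hosts}} or a catalog.
#' @return list with \code{clusters} (cluster_id, gene_id, size),
#'   \code{members} (cluster_id, precursor_id, start; sorted by start
#'   within cluster), and \code{size_histogram} (named integer vector).
#' @export
detect_clusters <- function(assignments) {
  a <- assignments
  per_gene <- tapply(a$precursor_id, a$gene_id,
                     function(x) length(unique(x)))
  hosts <- names(per_gene)[per_gene >= 2L]
  hosts <- sort(as.character(hosts %||% character()))
  # paste0 recycles zero-length input to "", so guard explicitly
  cluster_tag <- function(x) {
    if (length(x)) paste0("cluster:", x) else character()
  }
  clusters <- data.frame(cluster_id = cluster_tag(hosts),
                         gene_id = hosts,
                         size = as.integer(per_gene[hosts]),
                         stringsAsFactors = FALSE)
  mem <- a[a$gene_id %in% hosts, c("gene_id", "precursor_id", "start")]
  mem <- mem[!duplicated(mem[, c("gene_id", "precursor_id")]), ,
             drop = FALSE]
  mem <- mem[order(mem$gene_id, mem$start, mem$precursor_id), ,
             drop = FALSE]
  members <- data.frame(cluster_id = cluster_tag(mem$gene_id),
                        precursor_id = mem$precursor_id,
                        start = mem$start, stringsAsFactors = FALSE)
  rownames(clusters) <- NULL; rownames(members) <- NULL
  hist <- table(factor(clusters$size))
  list(clusters = clusters, members = members,
       size_histogram = stats::setNames(as.integer(hist), names(hist)))
}

#' Partition intragenic miRNAs by host-gene biotype class
#'
#' Each distinct intragenic miRNA is counted exactly once into
#' \code{protein_coding_only}, \code{ncRNA_only} (all hosts non-coding) or
#' \code{both} (at least one host of each kind); non-coding hosting is
#' additionally subclassified by host biotype.
#'
#' @param assignments an assignment data.frame.
#' @return list of counts: \code{protein_coding_only}, \code{ncRNA_only},
#'   \code{both}, and \code{nc_by_biotype} (distinct miRNAs per non-coding
#'   host biotype).
#' @export
partition_biotypes <- function(assignments) {
  a <- assignments
  if (nrow(a) == 0L) {
    return(list(protein_coding_only = 0L, ncRNA_only = 0L, both = 0L,
                nc_by_biotype = integer()))
  }
  is_pc <- a$gene_biotype == "protein_coding"
  by_mir <- tapply(is_pc, a$precursor_id, function(x) {
    if (all(x)) "protein_coding_only" else if (all(!x)) "ncRNA_only"
    else "both"
  })
  nc <- a[!is_pc, c("precursor_id", "gene_biotype")]
  nc <- nc[!duplicated(nc), , drop = FALSE]
  nc_tab <- table(nc$gene_biotype)
  list(protein_coding_only = sum(by_mir == "protein_coding_only"),
       ncRNA_only = sum(by_mir == "ncRNA_only"),
       both = sum(by_mir == "both"),
       nc_by_biotype = stats::setNames(as.integer(nc_tab), names(nc_tab)))
}

new_catalog <- function(species, source, total_mirnas, assignments,
                        antisense = 0L, partial = 0L) {
  rownames(assignments) <- NULL
  obj <- structure(list(species = species, source = source,
                        total_mirnas = as.integer(total_mirnas),
                        assignments = assignments,
                        antisense = as.integer(antisense),
                        partial = as.integer(partial), summary = NULL),
                   class = "catalog")
  obj$summary <- summarize_catalog(obj)
  obj
}

#' Build the intragenic miRNA catalog for one species
#'
#' Runs the genome-wide screen (\code{\link{assign_hosts}}), attaches
#' cluster identifiers, and computes summary statistics.
#'
#' @param mirnas a \code{\link{mirna_set}}.
#' @param genes a \code{\link{gene_set}}.
#' @param species species tag recorded in the catalog.
#' @param source free-text label for the annotation sources.
#' @return object of class \code{catalog}.
#' @export
build_catalog <- function(mirnas, genes, species, source = "") {
  res <- assign_hosts(mirnas, genes)
  a <- res$assignments
  cl <- detect_clusters(a)
  cl_of_gene <- stats::setNames(cl$clusters$cluster_id,
                                cl$clusters$gene_id)
  a$cluster_id <- unname(cl_of_gene[a$gene_id])
  a <- cbind(data.frame(species = rep(species, nrow(a)),
                        stringsAsFactors = FALSE), a)
  new_catalog(species = species, source = source,
              total_mirnas = nrow(mirnas$mirnas), assignments = a,
              antisense = res$antisense, partial = res$partial)
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf(
    "catalog [%s]: %d/%d miRNAs intragenic (%s%%), %d assignments\n",
    x$species, x$summary$intragenic_count, x$total_mirnas,
    ifelse(is.na(x$summary$intragenic_fraction), "NA",
           format(x$summary$intragenic_fraction, nsmall = 1L)),
    nrow(x$assignments)))
  invisible(x)
}

#' Summarize an intragenic miRNA catalog
#'
#' Counts distinct intragenic miRNAs, the intragenic percentage
#' (truncated to one decimal), per-category and per-biotype-class counts
#' (one per distinct miRNA; a miRNA whose hosts disagree on category is
#' counted as \code{mixed}), host genes, clusters, multi-host miRNAs and
#' per-chromosome counts. A chromosome whitelist restricts which
#' assignments are summarized without altering the catalog.
#'
#' @param catalog a \code{catalog}.
#' @param chrom_whitelist optional character vector of chromosomes.
#' @return object of class \code{summary_stats} (a named list).
#' @export
summarize_catalog <- function(catalog, chrom_whitelist = NULL) {
  a <- catalog$assignments
  if (!is.null(chrom_whitelist)) {
    a <- a[a$chrom %in% chrom_whitelist, , drop = FALSE]
  }
  total <- catalog$total_mirnas
  intragenic <- length(unique(a$precursor_id))
  frac <- if (total > 0L) trunc_one_decimal(100 * intragenic / total)
          else NA_real_
  cat_by_mir <- if (nrow(a)) {
    tapply(a$category, a$precursor_id, function(x) {
      u <- unique(x)
      if (length(u) == 1L) u else "mixed"
    })
  } else character()
  category_counts <- vapply(CATEGORY_LEVELS,
                            function(k) sum(cat_by_mir == k), integer(1L))
  bio <- partition_biotypes(a)
  cl <- detect_clusters(a)
  multi_host <- if (nrow(a)) {
    sum(tapply(a$gene_id, a$precursor_id,
               function(x) length(unique(x))) >= 2L)
  } else 0L
  per_chrom <- if (nrow(a)) {
    u <- a[!duplicated(a$precursor_id), ]
    tab <- table(u$chrom)
    stats::setNames(as.integer(tab), names(tab))
  } else integer()
  structure(list(
    total_mirnas = total, intragenic_count = intragenic,
    intragenic_fraction = frac, category_counts = category_counts,
    biotype_classes = c(protein_coding_only = bio$protein_coding_only,
                        ncRNA_only = bio$ncRNA_only, both = bio$both),
    nc_by_biotype = bio$nc_by_biotype,
    host_gene_count = length(unique(a$gene_id)),
    cluster_count = nrow(cl$clusters),
    cluster_size_histogram = cl$size_histogram,
    multi_host_count = as.integer(multi_host),
    per_chromosome = per_chrom), class = "summary_stats")
}
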