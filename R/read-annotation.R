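# light pre-validation so malformed rows are reported with line numbers,
# which rtracklayer does not do
validate_tab9 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(nzchar(lines) & !startsWith(lines, "#"))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) != 9L) {
      stop(sprintf("%s line %d: expected 9 tab-separated columns, found %d",
                   basename(path), i, length(fields)))
    }
  }
  length(body)
}

#' Read a miRBase-dialect miRNA annotation (GFF3)
#'
#' Parses precursor records (feature type
#' \code{miRNA_primary_transcript}) and mature records (feature type
#' \code{miRNA}, linked to their precursor via the \code{Derives_from}
#' attribute). Chromosome names are harmonized with
#' \code{\link{harmonize_chrom}}. Precursors with no annotated matures are
#' retained. Matures whose \code{Derives_from} names no precursor in the
#' file are dropped with a warning that lists their ids (also attached as
#' attribute \code{orphans} on the result).
#'
#' @param path path to a GFF3 file.
#' @param dialect only \code{"gff3"} is supported.
#' @param aliases optional chromosome alias table, see
#'   \code{\link{harmonize_chrom}}.
#' @return a \code{\link{mirna_set}}, precursors sorted by
#'   (chrom, start, name).
#' @export
read_mirna_annotation <- function(path, dialect = "gff3", aliases = NULL) {
  dialect <- match.arg(dialect, "gff3")
  if (!file.exists(path)) stop("no such file: ", path)
  if (validate_tab9(path) == 0L) return(mirna_set())
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- harmonize_chrom(df$seqnames, aliases)
  get_attr <- function(d, nm) {
    if (nm %in% names(d)) as.character(d[[nm]]) else rep(NA_character_,
                                                         nrow(d))
  }
  pre <- df[df$type == "miRNA_primary_transcript", , drop = FALSE]
  mat <- df[df$type == "miRNA", , drop = FALSE]
  mirnas <- data.frame(
    precursor_id = get_attr(pre, "ID"), name = get_attr(pre, "Name"),
    chrom = as.character(pre$seqnames), start = pre$start, end = pre$end,
    strand = as.character(pre$strand), stringsAsFactors = FALSE)
  matures <- data.frame(
    mature_id = get_attr(mat, "ID"), name = get_attr(mat, "Name"),
    chrom = as.character(mat$seqnames), start = mat$start, end = mat$end,
    strand = as.character(mat$strand),
    derives_from = get_attr(mat, "Derives_from"), stringsAsFactors = FALSE)
  orphan <- !(matures$derives_from %in% mirnas$precursor_id)
  orphans <- matures$mature_id[orphan]
  if (length(orphans)) {
    warning("mature record(s) whose Derives_from names no precursor: ",
            paste(orphans, collapse = ", "))
    matures <- matures[!orphan, , drop = FALSE]
  }
  out <- mirna_set(mirnas, matures)
  attr(out, "orphans") <- orphans
  out
}

# Ensembl GTF/GFF3 feature-type vocabularies
GENE_TYPES <- c("gene")
TX_TYPES <- c("transcript", "mRNA", "lnc_RNA", "ncRNA", "snoRNA", "miRNA")
UTR5_TYPES <- c("five_prime_utr", "five_prime_UTR")
UTR3_TYPES <- c("three_prime_utr", "three_prime_UTR")

#' Read a gene annotation in Ensembl-dialect GTF or GFF3
#'
#' Builds \code{\link{gene_set}} gene models from gene/transcript/exon
#' records, with optional UTR records. Introns are derived per transcript,
#' the gene span is the hull of its transcript spans, and the
#' \code{gene_biotype} (GTF) or \code{biotype} (GFF3) attribute is mapped
#' onto \code{protein_coding}, \code{lincRNA}, \code{snoRNA}, \code{miRNA};
#' anything else becomes \code{other_ncRNA} with a logged note.
#'
#' @param path path to the annotation file.
#' @param dialect \code{"gtf"} or \code{"gff3"}.
#' @param aliases optional chromosome alias table.
#' @return a \code{\link{gene_set}}.
#' @export
read_gene_annotation <- function(path, dialect = c("gtf", "gff3"),
                                 aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (validate_tab9(path) == 0L) return(empty_gene_set())
  gr <- rtracklayer::import(path, format = dialect)
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- harmonize_chrom(df$seqnames, aliases)
  df$type <- as.character(df$type)
  col <- function(d, nm) {
    if (nm %in% names(d)) as.character(d[[nm]]) else rep(NA_character_,
                                                         nrow(d))
  }
  if (dialect == "gtf") {
    gene_id <- col(df, "gene_id")
    tx_id <- col(df, "transcript_id")
    biotype <- col(df, "gene_biotype")
    symbol <- col(df, "gene_name")
  } else {
    # GFF3: hierarchy via ID/Parent; ids may carry "gene:"/"transcript:"
    # prefixes as in Ensembl dumps
    strip_pfx <- function(x) sub("^(gene|transcript):", "", x)
    id <- strip_pfx(col(df, "ID"))
    parent <- col(df, "Parent")
    parent[parent == "character(0)"] <- NA_character_
    parent <- strip_pfx(parent)
    is_gene <- df$type %in% GENE_TYPES
    is_tx <- df$type %in% TX_TYPES & !is_gene
    gene_id <- ifelse(is_gene, id, NA_character_)
    gene_id[is_tx] <- parent[is_tx]
    tx_id <- ifelse(is_tx, id, NA_character_)
    sub_feat <- df$type %in% c("exon", UTR5_TYPES, UTR3_TYPES)
    tx_id[sub_feat] <- parent[sub_feat]
    # resolve gene of sub-features through their transcript
    tx_gene <- stats::setNames(gene_id[is_tx], tx_id[is_tx])
    gene_id[sub_feat] <- unname(tx_gene[tx_id[sub_feat]])
    biotype <- col(df, "biotype")
    symbol <- col(df, "Name")
  }

  g_rows <- df$type %in% GENE_TYPES
  genes <- data.frame(
    gene_id = gene_id[g_rows],
    symbol = ifelse(is.na(symbol[g_rows]), gene_id[g_rows], symbol[g_rows]),
    biotype = ifelse(is.na(biotype[g_rows]), "other_ncRNA", biotype[g_rows]),
    chrom = as.character(df$seqnames[g_rows]),
    strand = as.character(df$strand[g_rows]), stringsAsFactors = FALSE)

  t_rows <- if (dialect == "gtf") df$type == "transcript" else
    df$type %in% TX_TYPES & !(df$type %in% GENE_TYPES)
  transcripts <- data.frame(transcript_id = tx_id[t_rows],
                            gene_id = gene_id[t_rows],
                            stringsAsFactors = FALSE)

  feat <- function(types) {
    rows <- df$type %in% types
    data.frame(transcript_id = tx_id[rows],
               chrom = as.character(df$seqnames[rows]),
               start = df$start[rows], end = df$end[rows],
               strand = as.character(df$strand[rows]),
               stringsAsFactors = FALSE)
  }
  gene_set(genes, transcripts, feat("exon"), feat(UTR5_TYPES),
           feat(UTR3_TYPES))
}
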