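# Independent oracles and small fixture builders. These deliberately do
# not share code with the package: the brute-force scan and the per-base
# walk are the reference implementations the fast paths are checked
# against.

# all-pairs brute-force sense-containment scan; returns sorted
# "precursor|gene" keys
brute_assign_keys <- function(mirnas_df, genes_df) {
  keys <- character()
  for (i in seq_len(nrow(mirnas_df))) {
    for (j in seq_len(nrow(genes_df))) {
      if (mirnas_df$chrom[i] == genes_df$chrom[j] &&
          mirnas_df$strand[i] == genes_df$strand[j] &&
          genes_df$start[j] <= mirnas_df$start[i] &&
          mirnas_df$end[i] <= genes_df$end[j]) {
        keys <- c(keys, paste(mirnas_df$precursor_id[i],
                              genes_df$gene_id[j], sep = "|"))
      }
    }
  }
  sort(keys)
}

# per-base labelling of an interval against one transcript: walks the
# transcript base by base and assigns each covered position to UTR,
# exon or intron before deciding the placement
oracle_placement <- function(iv, tx) {
  if (iv$chrom != tx$chrom || iv$strand != tx$strand) return(NULL)
  pos <- seq(iv$start, iv$end)
  if (any(pos < tx$start | pos > tx$end)) return(NULL)
  covered <- function(df, p) {
    nrow(df) > 0L && any(df$start <= p & p <= df$end)
  }
  if (all(vapply(pos, function(p) covered(tx$five_utr, p), TRUE))) {
    return(list(kind = "five_utr", ordinal = NA_integer_))
  }
  if (all(vapply(pos, function(p) covered(tx$three_utr, p), TRUE))) {
    return(list(kind = "three_utr", ordinal = NA_integer_))
  }
  feat_idx <- function(df, p) {
    w <- which(df$start <= p & p <= df$end)
    if (length(w)) w else NA_integer_
  }
  ii <- vapply(pos, function(p) feat_idx(tx$introns, p), 1L)
  if (!anyNA(ii) && length(unique(ii)) == 1L) {
    k <- if (tx$strand == "+") ii[1L] else nrow(tx$introns) - ii[1L] + 1L
    return(list(kind = "intron", ordinal = k))
  }
  ei <- vapply(pos, function(p) feat_idx(tx$exons, p), 1L)
  if (!anyNA(ei) && length(unique(ei)) == 1L) {
    k <- if (tx$strand == "+") ei[1L] else nrow(tx$exons) - ei[1L] + 1L
    return(list(kind = "exon", ordinal = k))
  }
  list(kind = "junction", ordinal = NA_integer_)
}

# random (mirna_set, gene_set) instance for oracle-equivalence checks;
# genes are single-exon so spans are exact, intervals may overlap freely
random_instance <- function(n_mir, n_gene, n_chrom = 2L) {
  g_start <- sample.int(5000L, n_gene, replace = TRUE)
  g_len <- sample(200:3000, n_gene, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("G%03d", seq_len(n_gene)),
    symbol = sprintf("S%03d", seq_len(n_gene)),
    biotype = sample(c("protein_coding", "lincRNA"), n_gene,
                     replace = TRUE),
    chrom = as.character(sample.int(n_chrom, n_gene, replace = TRUE)),
    strand = sample(c("+", "-"), n_gene, replace = TRUE),
    stringsAsFactors = FALSE)
  transcripts <- data.frame(
    transcript_id = paste0(genes$gene_id, ".t1"),
    gene_id = genes$gene_id, stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = transcripts$transcript_id, chrom = genes$chrom,
    start = g_start, end = g_start + g_len - 1L, strand = genes$strand,
    stringsAsFactors = FALSE)
  m_start <- sample.int(8000L, n_mir, replace = TRUE)
  m_len <- sample(60:120, n_mir, replace = TRUE)
  mirnas <- data.frame(
    precursor_id = sprintf("MI%03d", seq_len(n_mir)),
    name = sprintf("syn-mir-%d", seq_len(n_mir)),
    chrom = as.character(sample.int(n_chrom, n_mir, replace = TRUE)),
    start = m_start, end = m_start + m_len - 1L,
    strand = sample(c("+", "-"), n_mir, replace = TRUE),
    stringsAsFactors = FALSE)
  list(mirnas = mirna_set(mirnas),
       genes = gene_set(genes, transcripts, exons))
}

# reflect a coordinate frame about a fixed point and flip strands
reflect_frame <- function(df, m = 10000000L) {
  new_start <- m - df$end
  new_end <- m - df$start
  df$start <- new_start
  df$end <- new_end
  df$strand <- ifelse(df$strand == "+", "-", "+")
  df
}

reflect_gene_set <- function(gs, m = 10000000L) {
  flip <- function(df) if (nrow(df)) reflect_frame(df, m) else df
  genes <- gs$genes[, c("gene_id", "symbol", "biotype", "chrom",
                        "strand")]
  genes$strand <- ifelse(genes$strand == "+", "-", "+")
  gene_set(genes,
           gs$transcripts[, c("transcript_id", "gene_id")],
           flip(gs$exons), flip(gs$five_utr), flip(gs$three_utr))
}

reflect_mirna_set <- function(ms, m = 10000000L) {
  mirna_set(reflect_frame(ms$mirnas, m),
            if (nrow(ms$matures)) reflect_frame(ms$matures, m)
            else ms$matures)
}

# minimal single-gene / single-transcript model for classification tests
toy_transcript <- function(exons, strand = "+", chrom = "1",
                           five_utr = NULL, three_utr = NULL,
                           gene_id = "G1", biotype = "protein_coding",
                           symbol = "SYM") {
  exdf <- data.frame(transcript_id = "T1", chrom = chrom,
                     start = exons[, 1L], end = exons[, 2L],
                     strand = strand, stringsAsFactors = FALSE)
  utr <- function(x) {
    if (is.null(x)) return(NULL)
    data.frame(transcript_id = "T1", chrom = chrom, start = x[, 1L],
               end = x[, 2L], strand = strand, stringsAsFactors = FALSE)
  }
  gs <- gene_set(
    genes = data.frame(gene_id = gene_id, symbol = symbol,
                       biotype = biotype, chrom = chrom, strand = strand,
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = "T1", gene_id = gene_id,
                             stringsAsFactors = FALSE),
    exons = exdf,
    five_utr = utr(five_utr) %||% empty_feature_frame(),
    three_utr = utr(three_utr) %||% empty_feature_frame())
  get_transcript(gs, "T1")
}

# one-species, one-gene catalog for conservation-screen fixtures
tiny_species_catalog <- function(species, mirna_name, gene_id, symbol,
                                 biotype = "protein_coding") {
  gs <- gene_set(
    genes = data.frame(gene_id = gene_id, symbol = symbol,
                       biotype = biotype, chrom = "1", strand = "+",
                       stringsAsFactors = FALSE),
    transcripts = data.frame(transcript_id = paste0(gene_id, ".t1"),
                             gene_id = gene_id, stringsAsFactors = FALSE),
    exons = data.frame(transcript_id = paste0(gene_id, ".t1"),
                       chrom = "1", start = c(1000L, 3000L, 5000L),
                       end = c(1400L, 3400L, 5400L), strand = "+",
                       stringsAsFactors = FALSE))
  ms <- mirna_set(data.frame(
    precursor_id = paste0(toupper(species), "_MI1"), name = mirna_name,
    chrom = "1", start = 3600L, end = 3700L, strand = "+",
    stringsAsFactors = FALSE))
  build_catalog(ms, gs, species = species)
}
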