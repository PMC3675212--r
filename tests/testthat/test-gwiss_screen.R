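test_that("a miRNA inside two overlapping genes gets two assignments", {
  # mirrors the hsa-mir-10a case: one precursor inside both HOXB3 and
  # HOXB4, which overlap on the same strand
  genes <- data.frame(
    gene_id = c("HOXB3", "HOXB4"), symbol = c("HOXB3", "HOXB4"),
    biotype = "protein_coding", chrom = "17", strand = "-",
    stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = c("T3", "T4"),
                            gene_id = c("HOXB3", "HOXB4"),
                            stringsAsFactors = FALSE)
  exons <- data.frame(
    transcript_id = c("T3", "T3", "T4", "T4"), chrom = "17",
    start = c(1000L, 9000L, 7000L, 12000L),
    end = c(1500L, 9500L, 7400L, 12500L), strand = "-",
    stringsAsFactors = FALSE)
  gs <- gene_set(genes, transcripts, exons)
  ms <- mirna_set(data.frame(
    precursor_id = "MI10A", name = "hsa-mir-10a", chrom = "17",
    start = 8000L, end = 8090L, strand = "-", stringsAsFactors = FALSE))
  res <- assign_hosts(ms, gs)
  expect_equal(nrow(res$assignments), 2L)
  expect_setequal(res$assignments$gene_id, c("HOXB3", "HOXB4"))
  expect_equal(res$antisense, 0L)
})

test_that("antisense containment is tallied but never assigned", {
  genes <- data.frame(gene_id = "G1", symbol = "G1",
                      biotype = "protein_coding", chrom = "1",
                      strand = "+", stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = "T1", gene_id = "G1",
                            stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = "T1", chrom = "1", start = 100L,
                      end = 5000L, strand = "+", stringsAsFactors = FALSE)
  gs <- gene_set(genes, transcripts, exons)
  ms <- mirna_set(data.frame(
    precursor_id = "MI1", name = "syn-mir-1", chrom = "1", start = 1000L,
    end = 1090L, strand = "-", stringsAsFactors = FALSE))
  res <- assign_hosts(ms, gs)
  expect_equal(nrow(res$assignments), 0L)
  expect_equal(res$antisense, 1L)
  expect_equal(res$partial, 0L)
})

test_that("indexed host assignment equals the brute-force scan", {
  set.seed(19)
  for (rep in 1:40) {
    inst <- random_instance(sample(5:30, 1L), sample(3:15, 1L))
    res <- assign_hosts(inst$mirnas, inst$genes)
    got <- sort(paste(res$assignments$precursor_id,
                      res$assignments$gene_id, sep = "|"))
    expect_identical(got, brute_assign_keys(inst$mirnas$mirnas,
                                            inst$genes$genes))
  }
})

test_that("UTR placement takes precedence over the exon ordinal", {
  # mirrors mir-1306 inside the 5'-UTR of DGCR8
  tx <- toy_transcript(cbind(c(100L, 2000L), c(700L, 2600L)),
                       strand = "+",
                       five_utr = cbind(100L, 400L))
  p <- classify_in_transcript(
    list(chrom = "1", start = 150L, end = 240L, strand = "+"), tx)
  expect_equal(p$kind, "five_utr")
  # same interval without the UTR is exon 1
  tx2 <- toy_transcript(cbind(c(100L, 2000L), c(700L, 2600L)))
  p2 <- classify_in_transcript(
    list(chrom = "1", start = 150L, end = 240L, strand = "+"), tx2)
  expect_equal(p2$kind, "exon")
  expect_equal(p2$ordinal, 1L)
})

test_that("intron ordinals follow transcription direction", {
  exons <- cbind(seq(100L, by = 1000L, length.out = 6L),
                 seq(400L, by = 1000L, length.out = 6L))
  # plus strand: interval in the first genomic gap is intron 1
  txp <- toy_transcript(exons, strand = "+")
  p <- classify_in_transcript(
    list(chrom = "1", start = 450L, end = 530L, strand = "+"), txp)
  expect_equal(p$kind, "intron")
  expect_equal(p$ordinal, 1L)
  # minus strand, E = 5 gaps: genomic gap g is intron 6 - g; checked
  # against the independent per-base oracle
  txm <- toy_transcript(exons, strand = "-")
  for (g in 1:5) {
    iv <- list(chrom = "1", start = 410L + (g - 1L) * 1000L,
               end = 490L + (g - 1L) * 1000L, strand = "-")
    p <- classify_in_transcript(iv, txm)
    o <- oracle_placement(iv, txm)
    expect_equal(p$kind, "intron")
    expect_equal(p$ordinal, 6L - g)
    expect_equal(p[c("kind", "ordinal")], o[c("kind", "ordinal")])
  }
})

test_that("boundary-straddling intervals classify as junction", {
  tx <- toy_transcript(cbind(c(100L, 2000L), c(700L, 2600L)))
  p <- classify_in_transcript(
    list(chrom = "1", start = 650L, end = 760L, strand = "+"), tx)
  expect_equal(p$kind, "junction")
  expect_null(classify_in_transcript(
    list(chrom = "1", start = 50L, end = 160L, strand = "+"), tx))
})

test_that("aggregation produces canonical labels and categories", {
  # the multi-transcript pattern printed for mir-24-1 in C9orf3
  pl <- data.frame(
    kind = c("intron", "intron", "intron", "intron", "intron", "exon"),
    ordinal = c(4L, 5L, 6L, 14L, 15L, 7L), stringsAsFactors = FALSE)
  agg <- aggregate_assignment(pl)
  expect_equal(agg$location_label, "exon 7; intron 4, 5, 6, 14, 15")
  expect_equal(agg$category, "mixed")

  expect_equal(aggregate_assignment(
    data.frame(kind = "intron", ordinal = 2L)),
    list(location_label = "intron 2", category = "intron"))

  agg2 <- aggregate_assignment(data.frame(
    kind = c("five_utr", "intron"), ordinal = c(NA_integer_, 1L)))
  expect_equal(agg2$location_label, "5'-UTR; intron 1")
  expect_equal(agg2$category, "mixed")

  expect_equal(aggregate_assignment(data.frame(kind = character(),
                                               ordinal = integer())),
               list(location_label = "gene-body", category = "gene_body"))

  # a junction placement forces the mixed category even when alone
  expect_equal(aggregate_assignment(
    data.frame(kind = "junction", ordinal = NA_integer_))$category,
    "mixed")

  # duplicated ordinals across transcripts are deduplicated
  expect_equal(aggregate_assignment(data.frame(
    kind = c("intron", "intron"), ordinal = c(3L, 3L)))$location_label,
    "intron 3")
})

test_that("clusters are hosts with two or more resident miRNAs", {
  # mirrors the FTX lincRNA hosting hsa-mir-374a and hsa-mir-545
  genes <- data.frame(gene_id = c("FTX", "OTHER"),
                      symbol = c("FTX", "OTHER"),
                      biotype = c("lincRNA", "protein_coding"),
                      chrom = "X", strand = "+", stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = c("TF", "TO"),
                            gene_id = c("FTX", "OTHER"),
                            stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = c("TF", "TO"), chrom = "X",
                      start = c(1000L, 50000L), end = c(20000L, 60000L),
                      strand = "+", stringsAsFactors = FALSE)
  gs <- gene_set(genes, transcripts, exons)
  ms <- mirna_set(data.frame(
    precursor_id = c("MI374A", "MI545", "MI999"),
    name = c("hsa-mir-374a", "hsa-mir-545", "hsa-mir-999"),
    chrom = "X", start = c(5000L, 9000L, 52000L),
    end = c(5090L, 9090L, 52090L), strand = "+",
    stringsAsFactors = FALSE))
  res <- assign_hosts(ms, gs)
  cl <- detect_clusters(res$assignments)
  expect_equal(nrow(cl$clusters), 1L)
  expect_equal(cl$clusters$gene_id, "FTX")
  expect_equal(cl$clusters$size, 2L)
  expect_equal(cl$members$precursor_id, c("MI374A", "MI545"))
  expect_equal(cl$size_histogram, c(`2` = 1L))

  # all-singleton hosts mean zero clusters
  one_each <- res$assignments[!duplicated(res$assignments$gene_id), ]
  expect_equal(nrow(detect_clusters(one_each)$clusters), 0L)
})

test_that("cluster sizes match a group-by count on random data", {
  set.seed(23)
  for (rep in 1:10) {
    inst <- random_instance(40L, 8L)
    res <- assign_hosts(inst$mirnas, inst$genes)
    a <- res$assignments
    cl <- detect_clusters(a)
    expected <- table(tapply(a$precursor_id, a$gene_id,
                             function(x) length(unique(x))))
    expected <- expected[as.integer(names(expected)) >= 2L]
    got <- stats::setNames(cl$clusters$size, cl$clusters$gene_id)
    brute <- tapply(a$precursor_id, a$gene_id,
                    function(x) length(unique(x)))
    brute <- brute[brute >= 2L]
    expect_equal(sort(names(got)), sort(names(brute)))
    expect_equal(got[sort(names(got))],
                 stats::setNames(as.integer(brute[sort(names(brute))]),
                                 sort(names(brute))))
  }
})

test_that("biotype partition counts each miRNA once", {
  a <- data.frame(
    precursor_id = c("M1", "M1", "M2", "M3"),
    gene_id = c("GP", "GL", "GP2", "GL2"),
    gene_biotype = c("protein_coding", "lincRNA", "protein_coding",
                     "snoRNA"),
    stringsAsFactors = FALSE)
  p <- partition_biotypes(a)
  expect_equal(p$both, 1L)            # M1 sits in both kinds of host
  expect_equal(p$protein_coding_only, 1L)
  expect_equal(p$ncRNA_only, 1L)
  expect_equal(p$both + p$protein_coding_only + p$ncRNA_only,
               length(unique(a$precursor_id)))
  expect_equal(p$nc_by_biotype, c(lincRNA = 1L, snoRNA = 1L))

  empty <- partition_biotypes(a[0L, ])
  expect_equal(empty$protein_coding_only + empty$ncRNA_only + empty$both,
               0L)
})

test_that("summary statistics satisfy their conservation invariants", {
  set.seed(31)
  cfg <- generator_config(
    planted = c(intron = 15L, exon = 6L, five_utr = 4L, three_utr = 4L,
                mixed = 4L, cluster = 4L, dual_host = 3L,
                gene_body = 2L),
    decoys = c(antisense = 5L, intergenic = 5L, partial_overlap = 3L),
    background_genes = 4L, seed_variants = 0L)
  sp <- generate_species(cfg, seed = 31)
  ct <- build_catalog(sp$mirnas, sp$genes, species = "s")
  s <- ct$summary
  expect_equal(sum(s$category_counts), s$intragenic_count)
  expect_equal(sum(s$biotype_classes), s$intragenic_count)
  expect_equal(sum(s$per_chromosome), s$intragenic_count)
  expect_equal(s$intragenic_fraction,
               trunc_one_decimal(100 * s$intragenic_count /
                                   s$total_mirnas))
  expect_equal(s$multi_host_count, 3L)  # the planted dual-host miRNAs
  # whitelisting chromosomes restricts the summary consistently
  s1 <- summarize_catalog(ct, chrom_whitelist = "1")
  expect_equal(sum(s1$category_counts), s1$intragenic_count)
  expect_lte(s1$intragenic_count, s$intragenic_count)
})

test_that("percentages are truncated, not rounded, to one decimal", {
  # printed convention: 849/1600 = 53.0625% appears as 53.0%
  expect_equal(trunc_one_decimal(100 * 849 / 1600), 53.0)
  expect_equal(trunc_one_decimal(100 * 418 / 855), 48.8)
  expect_equal(trunc_one_decimal(100 * 210 / 499), 42.0)
  expect_equal(trunc_one_decimal(100 * 121 / 849), 14.2)
  expect_equal(trunc_one_decimal(53.09999), 53.0)
  expect_equal(trunc_one_decimal(53.1), 53.1)  # exact values unchanged
})

test_that("reflecting the genome preserves labels and categories", {
  set.seed(47)
  cfg <- generator_config(
    planted = c(intron = 10L, exon = 5L, five_utr = 4L, three_utr = 4L,
                mixed = 3L, cluster = 2L, dual_host = 2L,
                gene_body = 2L),
    decoys = c(antisense = 3L, intergenic = 3L, partial_overlap = 2L),
    background_genes = 2L, seed_variants = 0L)
  sp <- generate_species(cfg, seed = 47)
  ct <- build_catalog(sp$mirnas, sp$genes, species = "s")
  rg <- reflect_gene_set(sp$genes)
  rm_ <- reflect_mirna_set(sp$mirnas)
  ct_r <- build_catalog(rm_, rg, species = "s")
  key <- function(a) {
    o <- order(a$precursor_id, a$gene_id)
    paste(a$precursor_id[o], a$gene_id[o], a$location_label[o],
          a$category[o])
  }
  expect_identical(key(ct_r$assignments), key(ct$assignments))
  expect_identical(ct_r$antisense, ct$antisense)
  expect_identical(ct_r$partial, ct$partial)
})
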