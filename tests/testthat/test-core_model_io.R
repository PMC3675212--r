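test_that("miRBase-dialect reader agrees with a manual parse", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr17\tmb\tmiRNA_primary_transcript\t1200\t1290\t.\t-\t.\tID=MI0099;Name=hsa-mir-10a",
    "chr17\tmb\tmiRNA\t1255\t1276\t.\t-\t.\tID=MIMAT0099;Name=hsa-miR-10a-5p;Derives_from=MI0099"
  ), path)
  ms <- read_mirna_annotation(path)
  expect_equal(nrow(ms$mirnas), 1L)
  # hand-parsed expectations, chromosome harmonized from chr17 to 17
  expect_equal(ms$mirnas$precursor_id, "MI0099")
  expect_equal(ms$mirnas$name, "hsa-mir-10a")
  expect_equal(ms$mirnas$chrom, "17")
  expect_equal(ms$mirnas$start, 1200L)
  expect_equal(ms$mirnas$end, 1290L)
  expect_equal(ms$mirnas$strand, "-")
  expect_equal(ms$matures$mature_id, "MIMAT0099")
  expect_equal(ms$matures$derives_from, "MI0099")
  expect_equal(ms$matures$start, 1255L)
})

test_that("miRNA reader handles empty input, bad strand, and orphans", {
  empty <- withr::local_tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", empty)
  ms <- read_mirna_annotation(empty)
  expect_s3_class(ms, "mirna_set")
  expect_equal(nrow(ms$mirnas), 0L)

  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tmb\tmiRNA_primary_transcript\t100\t190\t.\t+\t.\tID=MI1;Name=syn-mir-1",
    "1\tmb\tmiRNA\t110\t131\t.\t-\t.\tID=MAT1;Name=syn-miR-1-5p;Derives_from=MI1"
  ), bad)
  expect_error(read_mirna_annotation(bad), "MAT1")

  orp <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "1\tmb\tmiRNA_primary_transcript\t100\t190\t.\t+\t.\tID=MI1;Name=syn-mir-1",
    "1\tmb\tmiRNA\t500\t521\t.\t+\t.\tID=MAT9;Name=syn-miR-9;Derives_from=MI_MISSING"
  ), orp)
  expect_warning(ms <- read_mirna_annotation(orp), "MAT9")
  expect_equal(nrow(ms$mirnas), 1L)
  expect_equal(nrow(ms$matures), 0L)
  expect_equal(attr(ms, "orphans"), "MAT9")
})

test_that("malformed annotation rows are reported with line numbers", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "1\tmb\tmiRNA\t100\t190\t.\t+\t."), bad)  # 8 columns
  expect_error(read_mirna_annotation(bad), "line 2")
})

test_that("gene reader derives introns as the inter-exon gaps", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    '1\tens\tgene\t100\t2000\t.\t+\t.\tgene_id "G1"; gene_name "FOO"; gene_biotype "protein_coding";',
    '1\tens\ttranscript\t100\t2000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tens\texon\t100\t300\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tens\texon\t500\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tens\texon\t1500\t2000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  ), path)
  gs <- read_gene_annotation(path, dialect = "gtf")
  tx <- get_transcript(gs, "T1")
  # gaps computed by hand: (301..499) and (901..1499)
  expect_equal(tx$introns$start, c(301L, 901L))
  expect_equal(tx$introns$end, c(499L, 1499L))
  expect_equal(nrow(tx$introns), nrow(tx$exons) - 1L)
  expect_equal(gs$genes$start, 100L)
  expect_equal(gs$genes$end, 2000L)
})

test_that("gene reader rejects broken transcript structure", {
  noex <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    '1\tens\tgene\t100\t2000\t.\t+\t.\tgene_id "G1"; gene_biotype "protein_coding";',
    '1\tens\ttranscript\t100\t2000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  ), noex)
  expect_error(read_gene_annotation(noex, dialect = "gtf"), "T1")

  ovl <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    '1\tens\tgene\t100\t2000\t.\t+\t.\tgene_id "G1"; gene_biotype "protein_coding";',
    '1\tens\ttranscript\t100\t2000\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tens\texon\t100\t600\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tens\texon\t500\t900\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  ), ovl)
  expect_error(read_gene_annotation(ovl, dialect = "gtf"),
               "overlapping exons.*T1")
})

test_that("unknown biotypes are mapped to other_ncRNA with a note", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    '1\tens\tgene\t100\t400\t.\t+\t.\tgene_id "G1"; gene_biotype "scaRNA";',
    '1\tens\ttranscript\t100\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    '1\tens\texon\t100\t400\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'
  ), path)
  expect_message(gs <- read_gene_annotation(path, dialect = "gtf"),
                 "scaRNA")
  expect_equal(gs$genes$biotype, "other_ncRNA")
})

test_that("GTF and GFF3 encodings of the same genes are equivalent", {
  set.seed(401)
  cfg <- generator_config(
    planted = c(intron = 20L, exon = 10L, five_utr = 8L, three_utr = 8L,
                mixed = 6L, cluster = 4L, dual_host = 2L, gene_body = 2L),
    decoys = c(antisense = 2L, intergenic = 2L, partial_overlap = 2L),
    background_genes = 5L, seed_variants = 0L)
  sp <- generate_species(cfg, seed = 401, outdir = withr::local_tempdir())
  gtf <- read_gene_annotation(sp$paths$gene_gtf, dialect = "gtf")
  expect_gte(nrow(gtf$genes), 50L)

  # re-encode the same models as Ensembl-style GFF3 and re-read
  gff <- withr::local_tempfile(fileext = ".gff3")
  lines <- "##gff-version 3"
  g <- gtf$genes
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, sprintf(
      "%s\tx\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s;Name=%s;biotype=%s",
      g$chrom[i], g$start[i], g$end[i], g$strand[i], g$gene_id[i],
      g$symbol[i], g$biotype[i]))
    txs <- gtf$transcripts[gtf$transcripts$gene_id == g$gene_id[i], ]
    for (t in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[t]
      lines <- c(lines, sprintf(
        "%s\tx\ttranscript\t%d\t%d\t.\t%s\t.\tID=transcript:%s;Parent=gene:%s",
        txs$chrom[t], txs$start[t], txs$end[t], txs$strand[t], tid,
        g$gene_id[i]))
      for (feat in list(c("exons", "exon"),
                        c("five_utr", "five_prime_UTR"),
                        c("three_utr", "three_prime_UTR"))) {
        df <- gtf[[feat[1L]]]
        df <- df[df$transcript_id == tid, , drop = FALSE]
        for (k in seq_len(nrow(df))) {
          lines <- c(lines, sprintf(
            "%s\tx\t%s\t%d\t%d\t.\t%s\t.\tParent=transcript:%s",
            df$chrom[k], feat[2L], df$start[k], df$end[k], df$strand[k],
            tid))
        }
      }
    }
  }
  writeLines(lines, gff)
  gff3 <- read_gene_annotation(gff, dialect = "gff3")
  expect_equal(gff3$genes, gtf$genes)
  ord <- function(df) {
    df <- df[order(df$transcript_id, df$start), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(ord(gff3$exons), ord(gtf$exons))
  expect_equal(ord(gff3$introns), ord(gtf$introns))
  expect_equal(ord(gff3$five_utr), ord(gtf$five_utr))
  expect_equal(ord(gff3$three_utr), ord(gtf$three_utr))

  # every parsed interval satisfies the interval invariants
  for (df in list(gff3$exons, gff3$introns, gff3$five_utr)) {
    expect_true(all(df$start >= 1L & df$start <= df$end))
    expect_true(all(df$strand %in% c("+", "-")))
    expect_true(all(nzchar(df$chrom)))
  }
})

test_that("variant, ortholog and override tables parse correctly", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t150\trs1\tA\tG\t.\t.\t.",
               "1\t275\t.\tCT\tC\t.\t.\t.",
               "2\t99\trs3\tG\tA,T\t.\t.\t."), vcf)
  v <- read_variant_table(vcf)
  expect_equal(nrow(v), 3L)
  expect_equal(v$pos, c(150L, 275L, 99L))
  expect_equal(v$chrom, c("1", "1", "2"))   # chr prefix harmonized
  expect_equal(v$variant_id[2L], "1:275:CT")
  expect_equal(v$alt_alleles[3L], "A,T")

  ort <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species_a\tgene_id_a\tspecies_b\tgene_id_b\tlink_type",
               "human\tENSG1\tmouse\tENSMUSG1\tone2one"), ort)
  om <- read_ortholog_table(ort)
  expect_equal(nrow(om$links), 1L)
  expect_true(orthology_linked(om, "mouse", "ENSMUSG1", "human", "ENSG1"))
  expect_false(orthology_linked(om, "human", "ENSG1", "human", "ENSG1"))

  conf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species_a\tgene_id_a\tspecies_b\tgene_id_b\tlink_type",
               "human\tENSG1\tmouse\tENSMUSG1\tone2one",
               "mouse\tENSMUSG1\thuman\tENSG1\tone2many"), conf)
  expect_error(read_ortholog_table(conf), "conflicting link_type")

  ov <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("canonical_stem\tmember_name",
               "mir-211\thsa-mir-211",
               "mir-211\tgga-mir-204-2"), ov)
  om2 <- read_override_table(ov)
  expect_equal(om2$overrides,
               list(`mir-211` = c("hsa-mir-211", "gga-mir-204-2")))

  ov_bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("canonical_stem\tmember_name", "mir-1\thsa-mir-1"), ov_bad)
  expect_error(read_override_table(ov_bad), "at least 2")
})

test_that("catalog write then read is the identity", {
  set.seed(77)
  inst <- random_instance(30L, 12L)
  ct <- build_catalog(inst$mirnas, inst$genes, species = "toy",
                      source = "unit")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(ct, path)
  ct2 <- read_catalog(path)
  expect_identical(ct2$species, ct$species)
  expect_identical(ct2$total_mirnas, ct$total_mirnas)
  expect_identical(ct2$antisense, ct$antisense)
  expect_identical(ct2$partial, ct$partial)
  expect_identical(ct2$assignments, ct$assignments)
  expect_identical(ct2$summary, ct$summary)
  # header is bit-exact
  header <- readLines(path)
  header <- header[!startsWith(header, "#")][1L]
  expect_identical(header, paste(CATALOG_COLUMNS, collapse = "\t"))
})
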