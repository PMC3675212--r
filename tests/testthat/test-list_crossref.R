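test_that("location labels parse under both canonical and printed grammar", {
  p1 <- parse_location_label("exon 7; intron 4, 5, 6")
  expect_equal(p1$kind, c("exon", rep("intron", 3L)))
  expect_equal(p1$ordinal, c(7L, 4L, 5L, 6L))
  # printed table style: comma-joined groups, UTR tokens inline
  p2 <- parse_location_label("intron 1, 5'-UTR")
  expect_equal(p2$kind, c("intron", "five_utr"))
  p3 <- parse_location_label("exon 2, 4, intron 2, 3")
  expect_equal(p3$kind, c("exon", "exon", "intron", "intron"))
  expect_equal(p3$ordinal, c(2L, 4L, 2L, 3L))
  expect_equal(nrow(parse_location_label("gene-body")), 0L)
  expect_equal(parse_location_label("3'-UTR")$kind, "three_utr")
  expect_error(parse_location_label("5, intron 1"), "unparseable")
  expect_error(parse_location_label("promoter 1"), "unparseable")
})

test_that("miRNA-mode cross-reference resolves names at several depths", {
  cfg <- generator_config(
    planted = c(intron = 8L, exon = 4L, five_utr = 2L, three_utr = 2L,
                mixed = 2L, cluster = 2L, dual_host = 0L,
                gene_body = 0L),
    decoys = c(antisense = 2L, intergenic = 2L, partial_overlap = 0L),
    background_genes = 2L, seed_variants = 0L)
  sp <- generate_species(cfg, seed = 301)
  ct <- build_catalog(sp$mirnas, sp$genes, species = "toy")
  present <- unique(ct$assignments$mirna_name)[1:2]
  rows <- cross_reference(c(present, "syn-mir-99999"), ct,
                          mode = "mirna")
  expect_equal(sum(rows$matched), 2L)
  expect_equal(sum(!rows$matched), 1L)
  expect_true(all(c(present, "syn-mir-99999") %in% rows$query))
  # a query without the species prefix still resolves
  stripped <- sub("^syn-", "", present[1L])
  r2 <- cross_reference(stripped, ct, mode = "mirna")
  expect_true(all(r2$matched))
})

test_that("host-gene mode reports every resident miRNA", {
  # machinery-gene pattern: DGCR8 hosts two miRNAs, DICER1 and SND1 one
  genes <- data.frame(
    gene_id = c("GD8", "GD1", "GS1"),
    symbol = c("DGCR8", "DICER1", "SND1"),
    biotype = "protein_coding", chrom = "1", strand = "+",
    stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = paste0(genes$gene_id, ".t"),
                            gene_id = genes$gene_id,
                            stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = transcripts$transcript_id,
                      chrom = "1", start = c(1000L, 20000L, 40000L),
                      end = c(9000L, 29000L, 49000L), strand = "+",
                      stringsAsFactors = FALSE)
  gs <- gene_set(genes, transcripts, exons)
  ms <- mirna_set(data.frame(
    precursor_id = c("MI1306", "MI3618", "MI3173", "MI593"),
    name = c("hsa-mir-1306", "hsa-mir-3618", "hsa-mir-3173",
             "hsa-mir-593"),
    chrom = "1", start = c(2000L, 5000L, 22000L, 42000L),
    end = c(2090L, 5090L, 22090L, 42090L), strand = "+",
    stringsAsFactors = FALSE))
  ct <- build_catalog(ms, gs, species = "human")
  rows <- cross_reference(c("DGCR8", "DICER1", "SND1"), ct,
                          mode = "host_gene")
  expect_equal(sum(rows$matched), 4L)
  expect_setequal(rows$mirna_name[rows$matched],
                  c("hsa-mir-1306", "hsa-mir-3618", "hsa-mir-3173",
                    "hsa-mir-593"))
  # unmatched symbols are flagged, not dropped
  r2 <- cross_reference(c("DGCR8", "NOPE"), ct, mode = "host_gene")
  expect_true(any(!r2$matched))
  expect_equal(r2$query[!r2$matched], "NOPE")
})

test_that("positional tallies evaluate the predicate disjunction", {
  rows <- data.frame(
    query = c("a", "b", "c", "c", "d"),
    location_label = c("intron 1", "exon 5", "intron 2", "5'-UTR",
                       "gene-body"),
    stringsAsFactors = FALSE)
  expect_equal(tally_positions(rows, "intron:1"), 1L)
  expect_equal(tally_positions(rows, "5utr|intron:1|exon:1"), 2L)
  # query c satisfies via its second row; counted once
  expect_equal(tally_positions(rows, "5utr|intron:2"), 1L)
  expect_equal(tally_positions(rows[0L, ], "intron:1"), 0L)
  expect_equal(tally_positions(rows, "intron"), 2L)  # any ordinal
  expect_error(
    tally_positions(data.frame(query = "x", location_label = "bogus 1"),
                    "intron:1"),
    "x")
})

test_that("adding a disjunct never decreases a tally", {
  set.seed(307)
  kinds <- c("intron", "exon", "five_utr", "three_utr")
  for (rep in 1:20) {
    n <- sample(5:15, 1L)
    rows <- data.frame(
      query = paste0("q", seq_len(n)),
      location_label = vapply(seq_len(n), function(i) {
        k <- sample(kinds, 1L)
        if (k %in% c("intron", "exon")) {
          paste(k, sample.int(5L, 1L))
        } else if (k == "five_utr") "5'-UTR" else "3'-UTR"
      }, ""),
      stringsAsFactors = FALSE)
    base <- sample(c("intron:1", "exon:2", "5utr"), 2L)
    t1 <- tally_positions(rows, paste(base, collapse = "|"))
    t2 <- tally_positions(rows, paste(c(base, "3utr"), collapse = "|"))
    expect_gte(t2, t1)
  }
})

test_that("the packaged reference tables have their documented shape", {
  t1 <- conserved_pair_table()
  expect_equal(nrow(t1), 27L)
  expect_true(all(c("human_mirna", "human_location", "human_host",
                    "mouse_mirna", "chicken_mirna") %in% names(t1)))
  t2 <- epigenetic_mirna_table()
  expect_equal(length(unique(t2$mirna[t2$section == "protein_coding"])),
               30L)
  expect_equal(length(unique(t2$mirna[t2$section == "ncRNA"])), 13L)
  # every fixture label parses under the label grammar
  for (lab in c(t1$human_location, t1$mouse_location,
                t1$chicken_location, t2$location)) {
    expect_silent(parse_location_label(lab))
  }
})
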