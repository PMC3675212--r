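# Deterministic synthetic annotation generator with a ground-truth
# manifest. Features are planted by construction (intervals chosen inside
# known introns/exons/UTRs), then re-verified per base before anything is
# returned or written, so manifest labels are ground truth rather than
# probabilistic.

#' Generator configuration
#'
#' Defaults describe a small but structurally complete genome: a few
#' linear chromosomes, hosts in every placement class, non-coding hosts,
#' clusters, dual-host miRNAs, and antisense / intergenic /
#' partial-overlap decoys, plus planted seed-region variants.
#'
#' @param chromosomes number of synthetic chromosomes.
#' @param planted named counts of planted intragenic miRNAs per placement
#'   class: \code{intron}, \code{exon}, \code{five_utr}, \code{three_utr},
#'   \code{mixed}, \code{cluster} (miRNAs living in multi-miRNA hosts),
#'   \code{dual_host} (miRNAs contained in two overlapping hosts),
#'   \code{gene_body}.
#' @param decoys named counts: \code{antisense}, \code{intergenic},
#'   \code{partial_overlap}.
#' @param biotype_mix host biotype proportions (must sum to 1) for
#'   classes that do not force a biotype (UTR hosts are always
#'   protein_coding).
#' @param background_genes miRNA-free genes added for realism.
#' @param seed_variants number of variants planted inside mature seed
#'   regions (plus an equal number of non-seed decoy variants).
#' @param intergenic_spacing range (bp) of gaps between neighbouring
#'   genes.
#' @param with_utrs set \code{FALSE} to generate UTR-less transcripts
#'   (then requesting \code{five_utr}/\code{three_utr} plants errors).
#' @param species species tag; \code{prefix} the miRNA name prefix.
#' @param conserved_triples,distractors,override_fraction,tier2_fraction
#'   trio mode: number of conserved cross-species miRNA/host groups,
#'   number of non-conserved distractors, and the fractions of conserved
#'   groups whose names only match via an explicit override or via
#'   tier-2 letter stripping.
#' @param seed default random seed (overridable in the generate calls).
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(
    chromosomes = 3L,
    planted = c(intron = 60L, exon = 30L, five_utr = 25L,
                three_utr = 25L, mixed = 20L, cluster = 20L,
                dual_host = 10L, gene_body = 10L),
    decoys = c(antisense = 40L, intergenic = 40L, partial_overlap = 20L),
    biotype_mix = c(protein_coding = 0.80, lincRNA = 0.12,
                    snoRNA = 0.05, other_ncRNA = 0.03),
    background_genes = 20L,
    seed_variants = 12L,
    intergenic_spacing = c(2000L, 8000L),
    with_utrs = TRUE,
    species = "synthA", prefix = "syn",
    conserved_triples = 27L, distractors = 40L,
    override_fraction = 0.15, tier2_fraction = 0.25,
    seed = 42L) {
  cfg <- list(chromosomes = as.integer(chromosomes),
              planted = planted, decoys = decoys,
              biotype_mix = biotype_mix,
              background_genes = as.integer(background_genes),
              seed_variants = as.integer(seed_variants),
              intergenic_spacing = as.integer(intergenic_spacing),
              with_utrs = isTRUE(with_utrs),
              species = species, prefix = prefix,
              conserved_triples = as.integer(conserved_triples),
              distractors = as.integer(distractors),
              override_fraction = override_fraction,
              tier2_fraction = tier2_fraction,
              seed = as.integer(seed))
  need <- c("intron", "exon", "five_utr", "three_utr", "mixed",
            "cluster", "dual_host", "gene_body")
  if (!all(need %in% names(cfg$planted))) {
    stop("planted must name counts for: ", paste(need, collapse = ", "))
  }
  if (any(cfg$planted < 0L) || any(cfg$decoys < 0L)) {
    stop("planted/decoy counts must be >= 0")
  }
  if (abs(sum(cfg$biotype_mix) - 1) > 1e-9) {
    stop("biotype_mix proportions must sum to 1")
  }
  if (!cfg$with_utrs &&
      (cfg$planted[["five_utr"]] > 0L || cfg$planted[["three_utr"]] > 0L)) {
    stop("UTR placement classes requested but with_utrs = FALSE")
  }
  structure(cfg, class = "generator_config")
}

# --- builder state ---------------------------------------------------------

# fast rbind for accumulated row-lists (each element: named list of equal
# length vectors); proto supplies column names and types for empty input
bind_rows_fast <- function(lst, proto) {
  if (!length(lst)) return(proto)
  cols <- lapply(names(proto), function(cn) {
    unlist(lapply(lst, `[[`, cn), use.names = FALSE)
  })
  names(cols) <- names(proto)
  as.data.frame(cols, stringsAsFactors = FALSE)
}

new_builder <- function(cfg) {
  b <- new.env(parent = emptyenv())
  b$cfg <- cfg
  b$cursor <- stats::setNames(rep(10000L, cfg$chromosomes),
                              as.character(seq_len(cfg$chromosomes)))
  b$genes <- list(); b$transcripts <- list(); b$exons <- list()
  b$utr5 <- list(); b$utr3 <- list()
  b$mirnas <- list(); b$matures <- list()
  b$manifest <- list()
  b$gene_n <- 0L; b$mir_n <- 0L
  b
}

pick_chrom <- function(b) {
  as.character(sample.int(b$cfg$chromosomes, 1L))
}

alloc <- function(b, chrom, width) {
  start <- b$cursor[[chrom]]
  gap <- sample(seq(b$cfg$intergenic_spacing[1L],
                    b$cfg$intergenic_spacing[2L]), 1L)
  b$cursor[[chrom]] <- start + width + gap
  start
}

pick_biotype <- function(b) {
  sample(names(b$cfg$biotype_mix), 1L, prob = b$cfg$biotype_mix)
}

# register a single-transcript gene with the given relative exon layout
# (matrix of start/end offsets from 0); returns absolute feature info
add_gene <- function(b, chrom, strand, biotype, exon_off,
                     utr5_off = NULL, utr3_off = NULL, start = NULL,
                     symbol = NULL, gene_id = NULL, extra_tx = list()) {
  b$gene_n <- b$gene_n + 1L
  if (is.null(gene_id)) {
    gene_id <- sprintf("%s_G%04d", toupper(b$cfg$species), b$gene_n)
  }
  if (is.null(symbol)) symbol <- sprintf("SYM%04d", b$gene_n)
  width <- max(c(exon_off[, 2L],
                 vapply(extra_tx, function(t) max(t[, 2L]), numeric(1L))))
  if (is.null(start)) start <- alloc(b, chrom, as.integer(width) + 1L)
  abs_iv <- function(off) {
    list(start = as.integer(start + off[, 1L]),
         end = as.integer(start + off[, 2L]))
  }
  b$genes[[length(b$genes) + 1L]] <- list(
    gene_id = gene_id, symbol = symbol, biotype = biotype, chrom = chrom,
    strand = strand)
  primary_exons <- NULL
  register_tx <- function(off, u5 = NULL, u3 = NULL) {
    tid <- sprintf("%s.t%d", gene_id, length(b$transcripts) + 1L)
    b$transcripts[[length(b$transcripts) + 1L]] <- list(
      transcript_id = tid, gene_id = gene_id)
    ex <- abs_iv(off)
    if (is.null(primary_exons)) primary_exons <<- ex
    n <- length(ex$start)
    b$exons[[length(b$exons) + 1L]] <- list(
      transcript_id = rep(tid, n), chrom = rep(chrom, n),
      start = ex$start, end = ex$end, strand = rep(strand, n))
    for (u in list(list(u5, "utr5"), list(u3, "utr3"))) {
      if (is.null(u[[1L]])) next
      uv <- abs_iv(u[[1L]])
      nu <- length(uv$start)
      b[[u[[2L]]]][[length(b[[u[[2L]]]]) + 1L]] <- list(
        transcript_id = rep(tid, nu), chrom = rep(chrom, nu),
        start = uv$start, end = uv$end, strand = rep(strand, nu))
    }
    tid
  }
  tid <- register_tx(exon_off, utr5_off, utr3_off)
  extra_ids <- vapply(extra_tx, register_tx, "")
  o <- order(primary_exons$start)
  ex <- data.frame(start = primary_exons$start[o],
                   end = primary_exons$end[o])
  introns <- if (nrow(ex) > 1L) {
    data.frame(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
  } else data.frame(start = integer(), end = integer())
  list(gene_id = gene_id, transcript_id = tid, extra_ids = extra_ids,
       start = as.integer(start), chrom = chrom, strand = strand,
       exons = ex, introns = introns)
}

# relative exon layout: n exons with given length ranges
random_exon_layout <- function(n_exons, exon_len = c(150L, 400L),
                               intron_len = c(300L, 1500L)) {
  el <- sample(seq(exon_len[1L], exon_len[2L]), n_exons, replace = TRUE)
  il <- if (n_exons > 1L) {
    sample(seq(intron_len[1L], intron_len[2L]), n_exons - 1L,
           replace = TRUE)
  } else integer()
  s <- integer(n_exons); e <- integer(n_exons)
  pos <- 0L
  for (i in seq_len(n_exons)) {
    s[i] <- pos; e[i] <- pos + el[i] - 1L
    pos <- e[i] + 1L + if (i < n_exons) il[i] else 0L
  }
  cbind(start = s, end = e)
}

add_mirna <- function(b, chrom, start, end, strand, name = NULL,
                      with_matures = TRUE) {
  b$mir_n <- b$mir_n + 1L
  pid <- sprintf("%s_MI%04d", toupper(b$cfg$species), b$mir_n)
  if (is.null(name)) {
    name <- sprintf("%s-mir-%d", b$cfg$prefix, 1000L + b$mir_n)
  }
  b$mirnas[[length(b$mirnas) + 1L]] <- list(
    precursor_id = pid, name = name, chrom = chrom,
    start = as.integer(start), end = as.integer(end), strand = strand)
  if (with_matures) {
    # one mature at each arm of the hairpin
    b$matures[[length(b$matures) + 1L]] <- list(
      mature_id = paste0(pid, "_5p"), name = paste0(name, "-5p"),
      chrom = chrom,
      start = as.integer(if (strand == "+") start + 8L else end - 29L),
      end = as.integer(if (strand == "+") start + 29L else end - 8L),
      strand = strand, derives_from = pid)
    b$matures[[length(b$matures) + 1L]] <- list(
      mature_id = paste0(pid, "_3p"), name = paste0(name, "-3p"),
      chrom = chrom,
      start = as.integer(if (strand == "+") end - 29L else start + 8L),
      end = as.integer(if (strand == "+") end - 8L else start + 29L),
      strand = strand, derives_from = pid)
  }
  pid
}

note_truth <- function(b, pid, class, host = NA_character_,
                       label = NA_character_, category = NA_character_,
                       cluster_id = NA_character_,
                       conservation_group = NA_character_,
                       requires_override = FALSE) {
  last <- b$mirnas[[length(b$mirnas)]]
  nm <- if (identical(last$precursor_id, pid)) last$name else NA_character_
  b$manifest[[length(b$manifest) + 1L]] <- list(
    precursor_id = pid, name = nm, class = class, host_gene_id = host,
    expected_label = label, expected_category = category,
    cluster_id = cluster_id, conservation_group = conservation_group,
    requires_override = requires_override)
}

# transcription-direction ordinal of the j-th genomic intron/exon
tx_ordinal <- function(j, n, strand) if (strand == "+") j else n - j + 1L

mirna_len <- function() sample(70:110, 1L)

# --- per-class planting ----------------------------------------------------

plant_intron_class <- function(b, class = "intron", name = NULL,
                               conservation_group = NA_character_,
                               requires_override = FALSE,
                               biotype = NULL) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(3:6, 1L)
  g <- add_gene(b, chrom, strand, biotype %||% pick_biotype(b),
                random_exon_layout(n_ex))
  j <- sample.int(nrow(g$introns), 1L)
  iv <- place_inside(g$introns$start[j], g$introns$end[j])
  pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand, name = name)
  k <- tx_ordinal(j, nrow(g$introns), strand)
  note_truth(b, pid, class, g$gene_id, paste("intron", k), "intron",
             conservation_group = conservation_group,
             requires_override = requires_override)
  invisible(pid)
}

plant_exon_class <- function(b) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(3:5, 1L)
  lay <- random_exon_layout(n_ex, exon_len = c(250L, 450L))
  g <- add_gene(b, chrom, strand, pick_biotype(b), lay)
  j <- sample(2:(n_ex - 1L), 1L)  # middle exon, clear of any UTR
  iv <- place_inside(g$exons$start[j], g$exons$end[j],
                     len = sample(70:90, 1L))
  pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand)
  k <- tx_ordinal(j, n_ex, strand)
  note_truth(b, pid, "exon", g$gene_id, paste("exon", k), "exon")
  invisible(pid)
}

plant_utr_class <- function(b, which = c("five_utr", "three_utr")) {
  which <- match.arg(which)
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  n_ex <- sample(2:4, 1L)
  lay <- random_exon_layout(n_ex, exon_len = c(350L, 500L))
  # the UTR sits at the transcription 5' or 3' terminal exon
  terminal_first <- (which == "five_utr") == (strand == "+")
  term <- if (terminal_first) 1L else n_ex
  ex_s <- lay[term, 1L]; ex_e <- lay[term, 2L]
  utr <- if (terminal_first) {
    cbind(start = ex_s, end = ex_s + 240L)
  } else {
    cbind(start = ex_e - 240L, end = ex_e)
  }
  g <- add_gene(b, chrom, strand, "protein_coding", lay,
                utr5_off = if (which == "five_utr") utr,
                utr3_off = if (which == "three_utr") utr)
  iv <- place_inside(g$start + utr[1L, 1L], g$start + utr[1L, 2L],
                     len = sample(70:90, 1L))
  pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand)
  label <- if (which == "five_utr") "5'-UTR" else "3'-UTR"
  note_truth(b, pid, which, g$gene_id, label, which)
  invisible(pid)
}

plant_mixed_class <- function(b) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  # T1: two exons around an intron; T2: one exon covering everything
  lay1 <- cbind(start = c(0L, 1100L), end = c(299L, 1399L))
  lay2 <- cbind(start = 0L, end = 1399L)
  g <- add_gene(b, chrom, strand, pick_biotype(b), lay1,
                extra_tx = list(lay2))
  iv <- place_inside(g$start + 300L, g$start + 1099L)
  pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand)
  # T1 has a single intron, T2 a single exon, on either strand
  note_truth(b, pid, "mixed", g$gene_id, "exon 1; intron 1", "mixed")
  invisible(pid)
}

plant_cluster_class <- function(b, n_members) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  n_ex <- n_members + 2L
  lay <- random_exon_layout(n_ex, intron_len = c(600L, 1200L))
  g <- add_gene(b, chrom, strand, pick_biotype(b), lay)
  js <- sample.int(nrow(g$introns), n_members)
  cl_id <- paste0("cluster:", g$gene_id)
  for (j in js) {
    iv <- place_inside(g$introns$start[j], g$introns$end[j])
    pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand)
    k <- tx_ordinal(j, nrow(g$introns), strand)
    note_truth(b, pid, "cluster", g$gene_id, paste("intron", k),
               "intron", cluster_id = cl_id)
  }
  invisible(cl_id)
}

plant_dual_host_class <- function(b) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  # outer gene with one long intron; inner single-exon gene inside it
  lay_out <- cbind(start = c(0L, 3000L), end = c(499L, 3499L))
  g1 <- add_gene(b, chrom, strand, "protein_coding", lay_out)
  lay_in <- cbind(start = 0L, end = 1200L)
  g2 <- add_gene(b, chrom, strand, pick_biotype(b), lay_in,
                 start = g1$start + 1000L)
  iv <- place_inside(g1$start + 1400L, g1$start + 1900L)
  pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand)
  note_truth(b, pid, "dual_host", g1$gene_id, "intron 1", "intron")
  note_truth(b, pid, "dual_host", g2$gene_id, "exon 1", "exon")
  invisible(pid)
}

plant_gene_body_class <- function(b) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  # two transcripts with disjoint spans leave an uncovered middle
  lay1 <- cbind(start = c(0L, 500L), end = c(299L, 899L))
  lay2 <- cbind(start = c(2200L, 2900L), end = c(2599L, 3199L))
  g <- add_gene(b, chrom, strand, pick_biotype(b), lay1,
                extra_tx = list(lay2))
  iv <- place_inside(g$start + 1100L, g$start + 1900L)
  pid <- add_mirna(b, chrom, iv[1L], iv[2L], strand)
  note_truth(b, pid, "gene_body", g$gene_id, "gene-body", "gene_body")
  invisible(pid)
}

plant_antisense_decoy <- function(b) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  g <- add_gene(b, chrom, strand, pick_biotype(b),
                random_exon_layout(3L))
  iv <- place_inside(g$introns$start[1L], g$introns$end[1L])
  pid <- add_mirna(b, chrom, iv[1L], iv[2L],
                   if (strand == "+") "-" else "+")
  note_truth(b, pid, "decoy_antisense")
  invisible(pid)
}

plant_partial_decoy <- function(b) {
  chrom <- pick_chrom(b)
  strand <- sample(c("+", "-"), 1L)
  g <- add_gene(b, chrom, strand, pick_biotype(b),
                random_exon_layout(2L))
  len <- mirna_len()
  start <- g$start - sample(20:40, 1L)  # straddles the gene 5' boundary
  pid <- add_mirna(b, chrom, start, start + len - 1L, strand)
  note_truth(b, pid, "decoy_partial")
  invisible(pid)
}

place_inside <- function(lo, hi, len = NULL, margin = 5L) {
  if (is.null(len)) len <- mirna_len()
  lo <- lo + margin; hi <- hi - margin
  if (hi - lo + 1L < len) stop("feature too small to host a miRNA")
  s <- lo + sample.int(hi - lo + 2L - len, 1L) - 1L
  c(s, s + len - 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_builder_gene_frame <- function() {
  data.frame(gene_id = character(), symbol = character(),
             biotype = character(), chrom = character(),
             strand = character(), stringsAsFactors = FALSE)
}

empty_manifest_frame <- function() {
  data.frame(precursor_id = character(), name = character(),
             class = character(), host_gene_id = character(),
             expected_label = character(), expected_category = character(),
             cluster_id = character(), conservation_group = character(),
             requires_override = logical(), stringsAsFactors = FALSE)
}

# --- top-level generators --------------------------------------------------

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate one synthetic species
#'
#' Emits a miRNA annotation, gene models, variants and the truth manifest
#' for one species under the given configuration. Identical
#' (config, seed) pairs produce byte-identical files. Every planted
#' record is re-verified with an internal per-base labeller before the
#' function returns; a mismatch aborts (and nothing is written).
#'
#' @param config a \code{\link{generator_config}}.
#' @param seed integer seed (defaults to \code{config$seed}).
#' @param outdir optional directory; when given, writes
#'   \code{<species>.mirna.gff3}, \code{<species>.genes.gtf},
#'   \code{<species>.variants.vcf} and \code{<species>.manifest.tsv}.
#' @return list with \code{mirnas} (\code{\link{mirna_set}}),
#'   \code{genes} (\code{\link{gene_set}}), \code{variants} (data.frame),
#'   \code{manifest} (data.frame; one row per intended (miRNA, host),
#'   decoys with \code{host_gene_id} NA), \code{variant_truth}, and
#'   \code{paths} when \code{outdir} was given.
#' @export
generate_species <- function(config = generator_config(),
                             seed = config$seed, outdir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  res <- with_seed(seed, build_species(config))
  if (!is.null(outdir)) {
    res$paths <- write_species_bundle(res, config$species, outdir)
  }
  res
}

build_species <- function(cfg) {
  b <- new_builder(cfg)
  p <- cfg$planted
  for (i in seq_len(p[["intron"]])) plant_intron_class(b)
  for (i in seq_len(p[["exon"]])) plant_exon_class(b)
  for (i in seq_len(p[["five_utr"]])) plant_utr_class(b, "five_utr")
  for (i in seq_len(p[["three_utr"]])) plant_utr_class(b, "three_utr")
  for (i in seq_len(p[["mixed"]])) plant_mixed_class(b)
  left <- p[["cluster"]]
  if (left == 1L) stop("cluster count must be 0 or >= 2")
  while (left > 0L) {
    n <- min(left, sample(2:3, 1L))
    if (left - n == 1L) n <- if (n == 2L) 3L else 2L  # never strand one
    plant_cluster_class(b, n)
    left <- left - n
  }
  for (i in seq_len(p[["dual_host"]])) plant_dual_host_class(b)
  for (i in seq_len(p[["gene_body"]])) plant_gene_body_class(b)
  for (i in seq_len(cfg$decoys[["antisense"]])) plant_antisense_decoy(b)
  for (i in seq_len(cfg$decoys[["partial_overlap"]])) {
    plant_partial_decoy(b)
  }
  for (i in seq_len(cfg$background_genes)) {
    add_gene(b, pick_chrom(b), sample(c("+", "-"), 1L), pick_biotype(b),
             random_exon_layout(sample(2:5, 1L)))
  }
  # intergenic decoys beyond every gene on their chromosome
  for (i in seq_len(cfg$decoys[["intergenic"]])) {
    chrom <- pick_chrom(b)
    len <- mirna_len()
    start <- b$cursor[[chrom]] + 5000L
    b$cursor[[chrom]] <- start + len + 1000L
    pid <- add_mirna(b, chrom, start, start + len - 1L,
                     sample(c("+", "-"), 1L))
    note_truth(b, pid, "decoy_intergenic")
  }

  genes <- gene_set(
    bind_rows_fast(b$genes, empty_builder_gene_frame()),
    bind_rows_fast(b$transcripts,
                   data.frame(transcript_id = character(),
                              gene_id = character(),
                              stringsAsFactors = FALSE)),
    bind_rows_fast(b$exons, empty_feature_frame()),
    bind_rows_fast(b$utr5, empty_feature_frame()),
    bind_rows_fast(b$utr3, empty_feature_frame()))
  mirnas <- mirna_set(bind_rows_fast(b$mirnas, empty_mirna_frame()),
                      bind_rows_fast(b$matures, empty_mature_frame()))
  manifest <- bind_rows_fast(b$manifest, empty_manifest_frame())

  variants <- plant_variants(cfg, mirnas, manifest)
  verify_manifest(mirnas, genes, manifest)
  list(mirnas = mirnas, genes = genes, variants = variants$table,
       variant_truth = variants$truth, manifest = manifest,
       species = cfg$species)
}

# plant seed variants in intragenic matures, plus non-seed decoy variants
plant_variants <- function(cfg, mirnas, manifest) {
  empty <- data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref_allele = character(),
                      alt_alleles = character(), stringsAsFactors = FALSE)
  truth <- data.frame(variant_id = character(), mature_id = character(),
                      precursor_id = character(), offset = integer(),
                      in_seed = logical(), stringsAsFactors = FALSE)
  n <- cfg$seed_variants
  if (n == 0L) return(list(table = empty, truth = truth))
  intra <- unique(manifest$precursor_id[!is.na(manifest$host_gene_id)])
  mat <- mirnas$matures
  mat <- mat[mat$derives_from %in% intra, , drop = FALSE]
  mat <- mat[!duplicated(mat$derives_from), , drop = FALSE]  # one arm each
  if (nrow(mat) < n) stop("not enough intragenic matures for seed plants")
  pick <- mat[sort(sample.int(nrow(mat), n)), , drop = FALSE]
  sd <- seed_definition(2L, 8L)
  rows <- list(); trows <- list()
  for (i in seq_len(n)) {
    m <- pick[i, ]
    iv <- project_seed(m, sd)
    off <- sample.int(sd$last - sd$first + 1L, 1L)
    pos <- if (m$strand == "+") iv$start + off - 1L else iv$end - off + 1L
    rows[[i]] <- data.frame(variant_id = sprintf("simvar%04d", i),
                            chrom = m$chrom, pos = as.integer(pos),
                            ref_allele = "A", alt_alleles = "G",
                            stringsAsFactors = FALSE)
    trows[[i]] <- data.frame(variant_id = sprintf("simvar%04d", i),
                             mature_id = m$mature_id,
                             precursor_id = m$derives_from,
                             offset = as.integer(off), in_seed = TRUE,
                             stringsAsFactors = FALSE)
  }
  # decoy variants just outside the seed (position seed.last + 3)
  for (i in seq_len(n)) {
    m <- pick[i, ]
    pos <- if (m$strand == "+") m$start + sd$last + 2L
           else m$end - sd$last - 2L
    rows[[n + i]] <- data.frame(variant_id = sprintf("simdec%04d", i),
                                chrom = m$chrom, pos = as.integer(pos),
                                ref_allele = "C", alt_alleles = "T",
                                stringsAsFactors = FALSE)
    trows[[n + i]] <- data.frame(variant_id = sprintf("simdec%04d", i),
                                 mature_id = m$mature_id,
                                 precursor_id = m$derives_from,
                                 offset = NA_integer_, in_seed = FALSE,
                                 stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$chrom, tab$pos, tab$variant_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, truth = do.call(rbind, trows))
}

# --- per-base self-verification -------------------------------------------

# independent per-base placement of an interval within one transcript
perbase_placement <- function(interval, tx) {
  if (interval$chrom != tx$chrom || interval$strand != tx$strand) {
    return(NULL)
  }
  pos <- seq(interval$start, interval$end)
  if (any(pos < tx$start | pos > tx$end)) return(NULL)
  in_range <- function(df) {
    if (!nrow(df)) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(df$start <= p & p <= df$end), logical(1L))
  }
  if (all(in_range(tx$five_utr))) return(list(kind = "five_utr",
                                              ordinal = NA_integer_))
  if (all(in_range(tx$three_utr))) return(list(kind = "three_utr",
                                               ordinal = NA_integer_))
  which_feat <- function(df) {
    vapply(pos, function(p) {
      w <- which(df$start <= p & p <= df$end)
      if (length(w)) w else 0L
    }, integer(1L))
  }
  wi <- which_feat(tx$introns)
  if (all(wi > 0L) && length(unique(wi)) == 1L) {
    return(list(kind = "intron",
                ordinal = tx_ordinal(wi[1L], nrow(tx$introns),
                                     tx$strand)))
  }
  we <- which_feat(tx$exons)
  if (all(we > 0L) && length(unique(we)) == 1L) {
    return(list(kind = "exon",
                ordinal = tx_ordinal(we[1L], nrow(tx$exons), tx$strand)))
  }
  list(kind = "junction", ordinal = NA_integer_)
}

verify_manifest <- function(mirnas, genes, manifest) {
  planted <- manifest[!is.na(manifest$host_gene_id), , drop = FALSE]
  for (i in seq_len(nrow(planted))) {
    row <- planted[i, ]
    mi <- mirnas$mirnas[mirnas$mirnas$precursor_id == row$precursor_id, ]
    tids <- genes$transcripts$transcript_id[
      genes$transcripts$gene_id == row$host_gene_id]
    pls <- list()
    for (tid in tids) {
      p <- perbase_placement(mi, get_transcript(genes, tid))
      if (!is.null(p)) pls[[length(pls) + 1L]] <- p
    }
    agg <- aggregate_assignment(pls)
    if (agg$location_label != row$expected_label ||
        agg$category != row$expected_category) {
      stop("generator self-check failed for ", row$precursor_id, " in ",
           row$host_gene_id, ": built '", agg$location_label,
           "' but intended '", row$expected_label, "'")
    }
  }
  invisible(TRUE)
}

# --- trio generation -------------------------------------------------------

#' Generate a three-species bundle with planted conserved co-location
#'
#' Builds three synthetic species whose intragenic miRNA complements
#' share \code{conserved_triples} planted (miRNA stem, orthologous host)
#' groups; group names match across species at tier 1, at tier 2
#' (letter-variant names), or only through the emitted orthologue
#' override table, in the configured proportions. Distractors share
#' stems without orthologous hosts, or orthologous hosts without
#' matching stems, and must not be recovered.
#'
#' @param config a \code{\link{generator_config}}; the trio-relevant
#'   fields are \code{conserved_triples}, \code{distractors},
#'   \code{override_fraction} and \code{tier2_fraction}.
#' @param seed integer seed.
#' @param outdir optional output directory (per-species bundles plus
#'   \code{orthologs.tsv}, \code{overrides.tsv},
#'   \code{trio.manifest.tsv}).
#' @return list with \code{species} (named list of per-species bundles
#'   as from \code{\link{generate_species}}), \code{orthology} (an
#'   \code{\link{orthology_map}} including the overrides),
#'   \code{orthology_no_overrides}, \code{override_table} (data.frame),
#'   and \code{manifest}.
#' @export
generate_trio <- function(config = generator_config(),
                          seed = config$seed, outdir = NULL) {
  stopifnot(inherits(config, "generator_config"))
  res <- with_seed(seed, build_trio(config))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    for (sp in names(res$species)) {
      paths[[sp]] <- write_species_bundle(res$species[[sp]], sp, outdir)
    }
    ortho_path <- file.path(outdir, "orthologs.tsv")
    utils::write.table(res$orthology$links, ortho_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ov_path <- file.path(outdir, "overrides.tsv")
    utils::write.table(res$override_table, ov_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    man_path <- file.path(outdir, "trio.manifest.tsv")
    utils::write.table(res$manifest, man_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    res$paths <- c(paths, orthologs = ortho_path, overrides = ov_path,
                   manifest = man_path)
  }
  res
}

build_trio <- function(cfg) {
  species <- c("human", "mouse", "chicken")
  prefixes <- c(human = "hsa", mouse = "mmu", chicken = "gga")
  P <- cfg$conserved_triples
  Q <- cfg$distractors
  n_ov <- round(P * cfg$override_fraction)
  n_t2 <- round(P * cfg$tier2_fraction)
  tiers <- rep("1", P)
  if (P > 0L) {
    tiers[seq_len(min(n_ov, P))] <- "override"
    if (n_ov < P) {
      tiers[seq(n_ov + 1L, min(n_ov + n_t2, P))] <- "2"
    }
    tiers <- sample(tiers)
  }

  builders <- lapply(species, function(sp) {
    sub <- cfg
    sub$species <- paste0("trio_", sp)
    sub$prefix <- prefixes[[sp]]
    new_builder(sub)
  })
  names(builders) <- species

  links <- list(); overrides <- list(); man_extra <- list()
  conserved_hosts <- list()
  for (g in seq_len(P)) {
    fam <- 100L + g
    names_by_sp <- switch(
      tiers[g],
      "1" = stats::setNames(sprintf("%s-mir-%d", prefixes, fam), species),
      "2" = c(human = sprintf("hsa-mir-%da-1", fam),
              mouse = sprintf("mmu-mir-%d-1", fam),
              chicken = sprintf("gga-mir-%d", fam)),
      "override" = c(human = sprintf("hsa-mir-%d", fam),
                     mouse = sprintf("mmu-mir-%d", fam + 2000L),
                     chicken = sprintf("gga-mir-%d", fam + 2000L)))
    if (tiers[g] == "override") {
      overrides[[length(overrides) + 1L]] <- data.frame(
        canonical_stem = sprintf("grp-mir-%d", fam),
        member_name = unname(names_by_sp), stringsAsFactors = FALSE)
    }
    host_ids <- character(3L); names(host_ids) <- species
    for (sp in species) {
      bsp <- builders[[sp]]
      pid <- plant_intron_class(
        bsp, class = "conserved", name = names_by_sp[[sp]],
        conservation_group = sprintf("grp%03d", g),
        requires_override = tiers[g] == "override",
        biotype = "protein_coding")
      last <- bsp$manifest[[length(bsp$manifest)]]
      host_ids[[sp]] <- last$host_gene_id
    }
    conserved_hosts[[g]] <- host_ids
    for (i in 1:2) for (j in seq(i + 1L, 3L)) {
      links[[length(links) + 1L]] <- data.frame(
        species_a = species[i], gene_id_a = host_ids[[i]],
        species_b = species[j], gene_id_b = host_ids[[j]],
        link_type = "one2one", stringsAsFactors = FALSE)
    }
  }

  # distractors: half share a stem without orthologous hosts, half have
  # orthologous hosts with unrelated stems
  q_stem <- ceiling(Q / 2L); q_ortho <- Q - q_stem
  for (q in seq_len(q_stem)) {
    fam <- 500L + q
    for (sp in c("human", "mouse")) {
      plant_intron_class(builders[[sp]], class = "distractor_stem",
                         name = sprintf("%s-mir-%d", prefixes[[sp]], fam))
    }
  }
  for (q in seq_len(q_ortho)) {
    fam_h <- 700L + q; fam_m <- 800L + q
    pid_h <- plant_intron_class(builders[["human"]],
                                class = "distractor_ortho",
                                name = sprintf("hsa-mir-%d", fam_h))
    host_h <- builders[["human"]]$manifest[[
      length(builders[["human"]]$manifest)]]$host_gene_id
    pid_m <- plant_intron_class(builders[["mouse"]],
                                class = "distractor_ortho",
                                name = sprintf("mmu-mir-%d", fam_m))
    host_m <- builders[["mouse"]]$manifest[[
      length(builders[["mouse"]]$manifest)]]$host_gene_id
    links[[length(links) + 1L]] <- data.frame(
      species_a = "human", gene_id_a = host_h, species_b = "mouse",
      gene_id_b = host_m, link_type = "one2one", stringsAsFactors = FALSE)
  }
  # a few intergenic decoys per species
  for (sp in species) {
    bsp <- builders[[sp]]
    for (i in 1:3) {
      chrom <- pick_chrom(bsp)
      len <- mirna_len()
      start <- bsp$cursor[[chrom]] + 5000L
      bsp$cursor[[chrom]] <- start + len + 1000L
      pid <- add_mirna(bsp, chrom, start, start + len - 1L,
                       sample(c("+", "-"), 1L))
      note_truth(bsp, pid, "decoy_intergenic")
    }
  }

  bundles <- lapply(species, function(sp) finalize_builder(builders[[sp]]))
  names(bundles) <- species
  override_table <- do.call(rbind, c(overrides, list(data.frame(
    canonical_stem = character(), member_name = character(),
    stringsAsFactors = FALSE))))
  link_df <- do.call(rbind, links)
  ov_list <- if (nrow(override_table)) {
    split(override_table$member_name, override_table$canonical_stem)
  } else list()
  manifest <- do.call(rbind, lapply(species, function(sp) {
    m <- bundles[[sp]]$manifest
    if (nrow(m)) cbind(species = sp, m, stringsAsFactors = FALSE) else NULL
  }))
  rownames(manifest) <- NULL
  list(species = bundles,
       orthology = orthology_map(link_df, overrides = ov_list),
       orthology_no_overrides = orthology_map(link_df),
       override_table = override_table, manifest = manifest)
}

finalize_builder <- function(b) {
  genes <- gene_set(
    bind_rows_fast(b$genes, empty_builder_gene_frame()),
    bind_rows_fast(b$transcripts,
                   data.frame(transcript_id = character(),
                              gene_id = character(),
                              stringsAsFactors = FALSE)),
    bind_rows_fast(b$exons, empty_feature_frame()),
    bind_rows_fast(b$utr5, empty_feature_frame()),
    bind_rows_fast(b$utr3, empty_feature_frame()))
  mirnas <- mirna_set(bind_rows_fast(b$mirnas, empty_mirna_frame()),
                      bind_rows_fast(b$matures, empty_mature_frame()))
  manifest <- bind_rows_fast(b$manifest, empty_manifest_frame())
  verify_manifest(mirnas, genes, manifest)
  list(mirnas = mirnas, genes = genes, manifest = manifest,
       variants = NULL, species = b$cfg$species)
}

# --- writers ---------------------------------------------------------------

write_lines_bytes <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

write_mirna_gff3 <- function(mirnas, path) {
  m <- mirnas$mirnas; mt <- mirnas$matures
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(m))) {
    lines <- c(lines, sprintf(
      "%s\tmirhost_sim\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
      m$chrom[i], m$start[i], m$end[i], m$strand[i], m$precursor_id[i],
      m$name[i]))
    sub <- mt[mt$derives_from == m$precursor_id[i], , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      lines <- c(lines, sprintf(
        "%s\tmirhost_sim\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;Derives_from=%s",
        sub$chrom[k], sub$start[k], sub$end[k], sub$strand[k],
        sub$mature_id[k], sub$name[k], sub$derives_from[k]))
    }
  }
  write_lines_bytes(lines, path)
}

write_gene_gtf <- function(genes, path) {
  g <- genes$genes
  lines <- character()
  fmt <- function(chrom, type, s, e, strand, attrs) {
    sprintf("%s\tmirhost_sim\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, type, s,
            e, strand, attrs)
  }
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    gattr <- sprintf(
      'gene_id "%s"; gene_name "%s"; gene_biotype "%s";', gid,
      g$symbol[i], g$biotype[i])
    lines <- c(lines, fmt(g$chrom[i], "gene", g$start[i], g$end[i],
                          g$strand[i], gattr))
    txs <- genes$transcripts[genes$transcripts$gene_id == gid, ,
                             drop = FALSE]
    for (t in seq_len(nrow(txs))) {
      tid <- txs$transcript_id[t]
      tattr <- sprintf(
        'gene_id "%s"; transcript_id "%s"; gene_name "%s"; gene_biotype "%s";',
        gid, tid, g$symbol[i], g$biotype[i])
      lines <- c(lines, fmt(txs$chrom[t], "transcript", txs$start[t],
                            txs$end[t], txs$strand[t], tattr))
      for (feat in list(c("exon", "exons"), c("five_prime_utr", "five_utr"),
                        c("three_prime_utr", "three_utr"))) {
        df <- genes[[feat[2L]]]
        df <- df[df$transcript_id == tid, , drop = FALSE]
        df <- df[order(df$start), , drop = FALSE]
        for (k in seq_len(nrow(df))) {
          lines <- c(lines, fmt(df$chrom[k], feat[1L], df$start[k],
                                df$end[k], df$strand[k], tattr))
        }
      }
    }
  }
  write_lines_bytes(lines, path)
}

write_vcf <- function(variants, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=mirhost_sim",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (!is.null(variants) && nrow(variants)) {
    sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", variants$chrom, variants$pos,
            variants$variant_id, variants$ref_allele,
            variants$alt_alleles)
  } else character()
  write_lines_bytes(c(header, body), path)
}

write_species_bundle <- function(bundle, tag, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    mirna_gff3 = file.path(outdir, paste0(tag, ".mirna.gff3")),
    gene_gtf = file.path(outdir, paste0(tag, ".genes.gtf")),
    manifest = file.path(outdir, paste0(tag, ".manifest.tsv")))
  write_mirna_gff3(bundle$mirnas, paths$mirna_gff3)
  write_gene_gtf(bundle$genes, paths$gene_gtf)
  man <- bundle$manifest
  man_lines <- c(paste(names(man), collapse = "\t"),
                 if (nrow(man)) apply(man, 1L, function(r) {
                   r[is.na(r)] <- "."
                   paste(r, collapse = "\t")
                 }) else character())
  write_lines_bytes(man_lines, paths$manifest)
  if (!is.null(bundle$variants)) {
    paths$vcf <- file.path(outdir, paste0(tag, ".variants.vcf"))
    write_vcf(bundle$variants, paths$vcf)
  }
  paths
}
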