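#' Read a variant table (VCF)
#'
#' Sites-only VCF is sufficient: only CHROM/POS/ID/REF/ALT are used.
#' Positions are 1-based as in the file; chromosome names are harmonized.
#' Records with a missing ID (\code{.}) get a synthetic
#' \code{chrom:pos:ref} identifier.
#'
#' @param path path to a VCF file (plain text or gzipped).
#' @param aliases optional chromosome alias table.
#' @return data.frame with columns \code{variant_id}, \code{chrom},
#'   \code{pos}, \code{ref_allele}, \code{alt_alleles} (comma-separated).
#' @export
read_variant_table <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- suppressMessages(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(data.frame(variant_id = character(), chrom = character(),
                      pos = integer(), ref_allele = character(),
                      alt_alleles = character(), stringsAsFactors = FALSE))
  }
  if (any(is.na(fix$REF) | !nzchar(fix$REF))) {
    stop("VCF record with empty REF allele")
  }
  id <- fix$ID
  miss <- is.na(id) | id == "."
  id[miss] <- paste(fix$CHROM[miss], fix$POS[miss], fix$REF[miss],
                    sep = ":")
  out <- data.frame(variant_id = id,
                    chrom = harmonize_chrom(fix$CHROM, aliases),
                    pos = as.integer(fix$POS), ref_allele = fix$REF,
                    alt_alleles = ifelse(is.na(fix$ALT), "", fix$ALT),
                    stringsAsFactors = FALSE)
  if (any(out$pos < 1L)) stop("VCF record with position < 1")
  out
}

#' Read a gene-orthology table
#'
#' Tab-separated with header
#' \code{species_a gene_id_a species_b gene_id_b link_type}; links are
#' unordered cross-species pairs tagged \code{one2one}, \code{one2many} or
#' \code{many2many}. The same unordered pair listed twice with conflicting
#' link types is an error.
#'
#' @param path path to the table.
#' @return object of class \code{orthology_map}: a list with element
#'   \code{links} (canonicalized data.frame) and \code{overrides} (empty;
#'   see \code{\link{read_override_table}}).
#' @export
read_ortholog_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species_a", "gene_id_a", "species_b", "gene_id_b", "link_type")
  if (!all(need %in% names(df))) {
    stop("ortholog table must have columns: ", paste(need, collapse = " "))
  }
  orthology_map(df)
}

#' Construct an orthology map
#'
#' @param links data.frame of cross-species gene links (see
#'   \code{\link{read_ortholog_table}}).
#' @param overrides named list of character vectors: canonical miRNA stem
#'   -> member names it unifies across species.
#' @return object of class \code{orthology_map}.
#' @export
orthology_map <- function(links = NULL, overrides = list()) {
  if (is.null(links) || nrow(links) == 0L) {
    links <- data.frame(species_a = character(), gene_id_a = character(),
                        species_b = character(), gene_id_b = character(),
                        link_type = character(), stringsAsFactors = FALSE)
  }
  if (nrow(links)) {
    if (any(links$species_a == links$species_b)) {
      stop("ortholog link within a single species")
    }
    if (!all(links$link_type %in% c("one2one", "one2many", "many2many"))) {
      stop("unknown link_type in ortholog table")
    }
    # canonical order within each unordered pair
    flip <- paste(links$species_a, links$gene_id_a) >
      paste(links$species_b, links$gene_id_b)
    tmp_s <- links$species_a[flip]; tmp_g <- links$gene_id_a[flip]
    links$species_a[flip] <- links$species_b[flip]
    links$gene_id_a[flip] <- links$gene_id_b[flip]
    links$species_b[flip] <- tmp_s; links$gene_id_b[flip] <- tmp_g
    key <- paste(links$species_a, links$gene_id_a, links$species_b,
                 links$gene_id_b, sep = "\r")
    conflict <- tapply(links$link_type, key,
                       function(x) length(unique(x)) > 1L)
    if (any(conflict)) {
      stop("conflicting link_type for ortholog pair(s): ",
           paste(gsub("\r", "/", names(conflict)[conflict]), collapse = "; "))
    }
    links <- links[!duplicated(key), , drop = FALSE]
    links <- links[order(links$species_a, links$gene_id_a, links$species_b,
                         links$gene_id_b), , drop = FALSE]
    rownames(links) <- NULL
  }
  for (nm in names(overrides)) {
    if (length(overrides[[nm]]) < 2L) {
      stop("override set '", nm, "' must unify at least 2 names")
    }
  }
  structure(list(links = links, overrides = overrides),
            class = "orthology_map")
}

#' Read a miRNA orthologue-override table
#'
#' Tab-separated rows \code{canonical_stem member_name}; each canonical
#' stem must unify at least two member names. Explicit overrides unify
#' cross-species miRNA names that no amount of name normalization can
#' match (e.g. chicken mir-204-2 standing in for mammalian mir-211).
#'
#' @param path path to the table.
#' @param map optional existing \code{orthology_map} to attach the
#'   overrides to.
#' @return an \code{orthology_map} carrying the overrides.
#' @export
read_override_table <- function(path, map = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("canonical_stem", "member_name") %in% names(df))) {
    stop("override table must have columns canonical_stem, member_name")
  }
  ov <- split(df$member_name, df$canonical_stem)
  if (is.null(map)) map <- orthology_map()
  orthology_map(map$links, overrides = ov)
}

# TRUE iff (sp_a, gene_a) and (sp_b, gene_b) are linked in the map
orthology_linked <- function(map, sp_a, gene_a, sp_b, gene_b) {
  if (sp_a == sp_b) return(FALSE)
  if (paste(sp_a, gene_a) > paste(sp_b, gene_b)) {
    tmp <- sp_a; sp_a <- sp_b; sp_b <- tmp
    tmp <- gene_a; gene_a <- gene_b; gene_b <- tmp
  }
  l <- map$links
  any(l$species_a == sp_a & l$gene_id_a == gene_a &
      l$species_b == sp_b & l$gene_id_b == gene_b)
}

CATALOG_COLUMNS <- c("species", "precursor_id", "mirna_name", "chrom",
                     "start", "end", "strand", "gene_id", "gene_symbol",
                     "gene_biotype", "containment", "location_label",
                     "category", "cluster_id")

#' Write / read an intragenic miRNA catalog
#'
#' The catalog is serialized as a UTF-8, Unix-newline, tab-separated file
#' with metadata lines (\code{# key=value}: species, source, total
#' miRNAs, antisense and partial-overlap tallies) followed by a fixed
#' 14-column header. \code{read_catalog(write_catalog(x))} is the
#' identity.
#'
#' @param catalog a \code{catalog} object (see \code{\link{build_catalog}}).
#' @param path output / input path.
#' @return \code{write_catalog} returns \code{path} invisibly;
#'   \code{read_catalog} returns the \code{catalog}.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "catalog"))
  a <- catalog$assignments
  meta <- c(sprintf("# species=%s", catalog$species),
            sprintf("# source=%s", catalog$source),
            sprintf("# total_mirnas=%d", catalog$total_mirnas),
            sprintf("# antisense=%d", catalog$antisense),
            sprintf("# partial=%d", catalog$partial))
  body <- apply(a[, CATALOG_COLUMNS, drop = FALSE], 1L, function(r) {
    r[is.na(r)] <- "."
    paste(r, collapse = "\t")
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, paste(CATALOG_COLUMNS, collapse = "\t"), body),
             con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^# ", lines, value = TRUE)
  kv <- sub("^# ", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  meta <- stats::setNames(vals, keys)
  body <- lines[!startsWith(lines, "#")]
  header <- strsplit(body[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, CATALOG_COLUMNS)) {
    stop("catalog header does not match the expected 14 columns")
  }
  rows <- body[-1L]
  if (length(rows)) {
    m <- do.call(rbind, strsplit(rows, "\t", fixed = TRUE))
    a <- as.data.frame(m, stringsAsFactors = FALSE)
    names(a) <- CATALOG_COLUMNS
    a$start <- as.integer(a$start)
    a$end <- as.integer(a$end)
    a$cluster_id[a$cluster_id == "."] <- NA_character_
  } else {
    a <- empty_assignment_frame()
    a$species <- character()
  }
  new_catalog(species = unname(meta[["species"]]),
              source = unname(meta[["source"]]),
              total_mirnas = as.integer(meta[["total_mirnas"]]),
              assignments = a,
              antisense = as.integer(meta[["antisense"]]),
              partial = as.integer(meta[["partial"]]))
}
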