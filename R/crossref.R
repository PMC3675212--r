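# Cross-referencing external miRNA / host-gene lists against a catalog
# and tallying positional predicates over location labels.

#' Parse a location label into placements
#'
#' Understands both the catalog's canonical grammar
#' (\code{"exon 7; intron 4, 5, 6"}) and the comma-separated style common
#' in printed tables (\code{"intron 1, 5'-UTR"}, \code{"exon 3, intron
#' 3"}): tokens are split on commas/semicolons, a token starting with a
#' kind word opens an ordinal group, bare numbers extend the current
#' group, and UTR/junction/gene-body tokens stand alone.
#'
#' @param label location label string.
#' @return data.frame with columns \code{kind}, \code{ordinal} (NA for
#'   ordinal-free kinds); zero rows for \code{"gene-body"}.
#' @export
parse_location_label <- function(label) {
  out <- data.frame(kind = character(), ordinal = integer(),
                    stringsAsFactors = FALSE)
  lab <- trimws(label)
  if (!nzchar(lab)) stop("unparseable location label: empty")
  if (tolower(lab) %in% c("gene-body", "gene_body")) return(out)
  tokens <- trimws(strsplit(lab, "[;,]")[[1L]])
  tokens <- tokens[nzchar(tokens)]
  current <- NA_character_
  for (tok in tokens) {
    low <- tolower(tok)
    low <- gsub("\u2032", "'", low)  # typographic prime -> apostrophe
    if (grepl("^5'?-?utr$", low)) {
      out <- rbind(out, data.frame(kind = "five_utr",
                                   ordinal = NA_integer_))
      current <- NA_character_
    } else if (grepl("^3'?-?utr$", low)) {
      out <- rbind(out, data.frame(kind = "three_utr",
                                   ordinal = NA_integer_))
      current <- NA_character_
    } else if (low == "junction") {
      out <- rbind(out, data.frame(kind = "junction",
                                   ordinal = NA_integer_))
      current <- NA_character_
    } else if (grepl("^(intron|exon)\\s+[0-9]+(\\s*[-\u2013]\\s*[0-9]+)?$",
                     low)) {
      current <- sub("\\s.*$", "", low)
      rng <- range_to_ordinals(sub("^(intron|exon)\\s+", "", low))
      out <- rbind(out, data.frame(kind = current, ordinal = rng))
    } else if (grepl("^[0-9]+(\\s*[-\u2013]\\s*[0-9]+)?$", low)) {
      if (is.na(current)) {
        stop("unparseable location label: ", label)
      }
      out <- rbind(out, data.frame(kind = current,
                                   ordinal = range_to_ordinals(low)))
    } else {
      stop("unparseable location label: ", label)
    }
  }
  rownames(out) <- NULL
  out
}

range_to_ordinals <- function(x) {
  parts <- as.integer(strsplit(x, "\\s*[-\u2013]\\s*")[[1L]])
  if (length(parts) == 2L) seq(parts[1L], parts[2L]) else parts[1L]
}

#' Cross-reference a name list against a catalog
#'
#' In \code{mirna} mode each query is resolved against catalog miRNA
#' names: exact (case-insensitive) name, then name with species prefix
#' removed, then tier-1 stem match (see
#' \code{\link{normalize_mirna_name}}). In \code{host_gene} mode queries
#' match host gene symbols or ids case-insensitively and the row reports
#' the resident miRNAs. A query matching several catalog records yields
#' one row per record; an unmatched query yields a single row flagged
#' \code{matched = FALSE} and is never dropped.
#'
#' @param names character vector of query names (non-empty).
#' @param catalog a \code{catalog}.
#' @param mode \code{"mirna"} or \code{"host_gene"}.
#' @return data.frame with columns \code{query}, \code{matched},
#'   \code{precursor_id}, \code{mirna_name}, \code{gene_id},
#'   \code{gene_symbol}, \code{gene_biotype}, \code{location_label},
#'   \code{category}.
#' @export
cross_reference <- function(names, catalog, mode = c("mirna",
                                                     "host_gene")) {
  mode <- match.arg(mode)
  if (!length(names)) stop("query name list must be non-empty")
  a <- catalog$assignments
  st <- if (nrow(a)) stem_frame(a$mirna_name) else NULL
  rows <- list()
  for (q in names) {
    hit <- if (nrow(a) == 0L) {
      logical(0L)
    } else if (mode == "mirna") {
      ql <- tolower(q)
      h <- tolower(a$mirna_name) == ql
      if (!any(h)) {
        qn <- normalize_mirna_name(q)
        stripped <- sub("^[a-z0-9]{2,4}-(?=(mir|let)-)", "",
                        tolower(a$mirna_name), perl = TRUE)
        h <- stripped == ql
        if (!any(h)) h <- st$tier1 == qn$tier1_stem
      }
      h
    } else {
      tolower(a$gene_symbol) == tolower(q) |
        tolower(a$gene_id) == tolower(q)
    }
    if (any(hit)) {
      sel <- a[hit, , drop = FALSE]
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, matched = TRUE, precursor_id = sel$precursor_id,
        mirna_name = sel$mirna_name, gene_id = sel$gene_id,
        gene_symbol = sel$gene_symbol, gene_biotype = sel$gene_biotype,
        location_label = sel$location_label, category = sel$category,
        stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        query = q, matched = FALSE, precursor_id = NA_character_,
        mirna_name = NA_character_, gene_id = NA_character_,
        gene_symbol = NA_character_, gene_biotype = NA_character_,
        location_label = NA_character_, category = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Parse a positional predicate specification
#'
#' Syntax: terms joined by \code{|}; a term is \code{5utr}, \code{3utr},
#' \code{junction}, \code{intron}, \code{exon} (any ordinal) or
#' \code{intron:k} / \code{exon:k} (that ordinal only). Example:
#' \code{"5utr|intron:1|exon:1"}.
#'
#' @param spec predicate string.
#' @return data.frame with columns \code{kind}, \code{ordinal}.
#' @export
parse_predicate <- function(spec) {
  terms <- trimws(strsplit(spec, "|", fixed = TRUE)[[1L]])
  rows <- lapply(terms, function(t) {
    low <- tolower(t)
    if (low %in% c("5utr", "5'-utr", "five_utr")) {
      data.frame(kind = "five_utr", ordinal = NA_integer_)
    } else if (low %in% c("3utr", "3'-utr", "three_utr")) {
      data.frame(kind = "three_utr", ordinal = NA_integer_)
    } else if (low == "junction") {
      data.frame(kind = "junction", ordinal = NA_integer_)
    } else if (grepl("^(intron|exon)(:[0-9]+)?$", low)) {
      parts <- strsplit(low, ":", fixed = TRUE)[[1L]]
      data.frame(kind = parts[1L],
                 ordinal = if (length(parts) == 2L)
                   as.integer(parts[2L]) else NA_integer_)
    } else {
      stop("unparseable predicate term: ", t)
    }
  })
  do.call(rbind, rows)
}

#' Tally queries satisfying a positional predicate
#'
#' Counts distinct query names among the matched rows whose parsed
#' location label satisfies at least one predicate term (a disjunction
#' over (kind, ordinal) terms). Counting distinct queries, not rows,
#' means a miRNA listed with two host genes is tallied once. Adding a
#' disjunct can never decrease the count.
#'
#' @param rows data.frame with columns \code{query},
#'   \code{location_label} and optionally \code{matched} (e.g. from
#'   \code{\link{cross_reference}}).
#' @param predicate a predicate data.frame from
#'   \code{\link{parse_predicate}} or its string form.
#' @return integer count of distinct satisfying queries.
#' @export
tally_positions <- function(rows, predicate) {
  if (is.character(predicate)) predicate <- parse_predicate(predicate)
  if ("matched" %in% names(rows)) {
    rows <- rows[rows$matched %in% TRUE, , drop = FALSE]
  }
  if (nrow(rows) == 0L) return(0L)
  sat <- logical(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    pl <- tryCatch(parse_location_label(rows$location_label[i]),
                   error = function(e) {
                     stop("row ", i, " (", rows$query[i], "): ",
                          conditionMessage(e))
                   })
    if (nrow(pl) == 0L) next
    for (k in seq_len(nrow(predicate))) {
      m <- pl$kind == predicate$kind[k] &
        (is.na(predicate$ordinal[k]) |
           (!is.na(pl$ordinal) & pl$ordinal == predicate$ordinal[k]))
      if (any(m)) { sat[i] <- TRUE; break }
    }
  }
  length(unique(rows$query[sat]))
}

#' Packaged reference tables
#'
#' Two curated plain-text tables ship with the package:
#' \code{conserved_pair_table()} -- 27 miRNA/host gene pairs with
#' co-location conserved across human, mouse and chicken (per-species
#' miRNA name, location annotation and host symbol; ordinal ranges
#' expanded to explicit lists); \code{epigenetic_mirna_table()} -- host
#' genes of epigenetically silenced miRNA genes in cancer, split into a
#' protein-coding and a non-coding host section, with one row per
#' (miRNA, host) including secondary hosts.
#'
#' @return data.frame of the table as shipped.
#' @export
conserved_pair_table <- function() {
  utils::read.delim(system.file("extdata", "table1_conserved_pairs.tsv",
                                package = "mirhost"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname conserved_pair_table
#' @export
epigenetic_mirna_table <- function() {
  utils::read.delim(system.file("extdata", "table2_epigenetic.tsv",
                                package = "mirhost"),
                    stringsAsFactors = FALSE, check.names = FALSE)
}
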