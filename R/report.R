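# Human- and machine-readable reports over summary statistics and
# conserved-pair subset counts.

#' Render summary statistics
#'
#' \code{text} prints the category and biotype breakdown with the
#' intragenic fraction to one decimal; \code{tsv} emits flat key/value
#' rows; \code{json} a flat object (via jsonlite). All three are
#' deterministic serializations of the same numbers.
#'
#' @param summary a \code{summary_stats} object from
#'   \code{\link{summarize_catalog}}.
#' @param format \code{"text"}, \code{"tsv"} or \code{"json"}.
#' @return character vector of lines (\code{text}/\code{tsv}) or a JSON
#'   string.
#' @export
render_summary <- function(summary, format = c("text", "tsv", "json")) {
  format <- match.arg(format)
  flat <- c(list(total_mirnas = summary$total_mirnas,
                 intragenic_count = summary$intragenic_count,
                 intragenic_fraction = summary$intragenic_fraction),
            as.list(stats::setNames(
              as.integer(summary$category_counts),
              paste0("category.", names(summary$category_counts)))),
            as.list(stats::setNames(
              as.integer(summary$biotype_classes),
              paste0("biotype.", names(summary$biotype_classes)))),
            list(host_gene_count = summary$host_gene_count,
                 cluster_count = summary$cluster_count,
                 multi_host_count = summary$multi_host_count),
            if (length(summary$per_chromosome)) {
              as.list(stats::setNames(
                as.integer(summary$per_chromosome),
                paste0("chrom.", names(summary$per_chromosome))))
            } else list())
  if (format == "json") {
    return(jsonlite::toJSON(flat, auto_unbox = TRUE, digits = NA,
                            na = "null"))
  }
  if (format == "tsv") {
    return(vapply(names(flat), function(k) {
      paste(k, format(flat[[k]], nsmall = 0L, trim = TRUE), sep = "\t")
    }, ""))
  }
  frac <- if (is.na(summary$intragenic_fraction)) "NA" else {
    paste0(formatC(summary$intragenic_fraction, format = "f",
                   digits = 1L), "%")
  }
  c(sprintf("intragenic miRNAs: %d / %d (%s)", summary$intragenic_count,
            summary$total_mirnas, frac),
    "by category:",
    sprintf("  %-10s %d", names(summary$category_counts),
            summary$category_counts),
    "by host biotype class:",
    sprintf("  %-20s %d", names(summary$biotype_classes),
            summary$biotype_classes),
    sprintf("host genes: %d; clusters: %d; multi-host miRNAs: %d",
            summary$host_gene_count, summary$cluster_count,
            summary$multi_host_count))
}

#' Render species-subset (Venn) counts
#'
#' One row per subset in fixed order: singletons, then pairs, then
#' larger subsets, each as \code{"<subset>\t<count>"}. All-zero cells
#' are still printed.
#'
#' @param cells named counts from \code{\link{subset_counts}}.
#' @param format \code{"text"}, \code{"tsv"} or \code{"json"}.
#' @return character vector of rows, or a JSON string.
#' @export
render_venn <- function(cells, format = c("text", "tsv", "json")) {
  format <- match.arg(format)
  # order by subset size, then name (subset_counts already emits this
  # order, but do not rely on it)
  size <- vapply(strsplit(names(cells), "&", fixed = TRUE), length, 1L)
  ord <- order(size, names(cells))
  cells <- cells[ord]
  if (format == "json") {
    return(jsonlite::toJSON(as.list(cells), auto_unbox = TRUE,
                            digits = NA))
  }
  paste(names(cells), cells, sep = "\t")
}
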