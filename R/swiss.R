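# Species-wide screen: tiered miRNA name matching + host-gene orthology.

#' Normalize a miRNA name into matching stems
#'
#' Tier-1 stem: lowercase, species prefix (e.g. \code{hsa-}, \code{mmu-},
#' \code{gga-}) removed, trailing \code{-<integer>} paralog counter
#' removed (\code{hsa-mir-103a-1} -> \code{mir-103a}). Tier-2 stem:
#' tier 1 with a single trailing letter variant removed when the stem
#' ends in one letter preceded by a digit (\code{mir-103a} ->
#' \code{mir-103}); the \code{let-7} family is exempt from letter
#' stripping because its letters name distinct family members, so there
#' tier 2 equals tier 1.
#'
#' @param name miRNA name (precursor naming, e.g. \code{hsa-mir-101-2}).
#' @return list with \code{raw_name}, \code{tier1_stem}, \code{tier2_stem}
#'   (\code{NA} when undefined).
#' @export
#' @examples
#' normalize_mirna_name("hsa-mir-103a-1")
#' normalize_mirna_name("gga-let-7g")
normalize_mirna_name <- function(name) {
  if (!nzchar(name)) stop("miRNA name must be non-empty")
  x <- tolower(name)
  # strip a species prefix only when followed by a family token
  x <- sub("^[a-z0-9]{2,4}-(?=(mir|let)-)", "", x, perl = TRUE)
  # family structure: (mir|let)-<number><letters?>(-<counter>)?
  m <- regmatches(x, regexec("^(mir|let)-([0-9]+[a-z]*)(-([0-9]+))?$", x))[[1L]]
  tier1 <- if (length(m)) paste0(m[2L], "-", m[3L]) else x
  tier2 <- NA_character_
  if (startsWith(tier1, "let-7")) {
    tier2 <- tier1
  } else if (grepl("[0-9][a-z]$", tier1)) {
    tier2 <- sub("[a-z]$", "", tier1)
  }
  list(raw_name = name, tier1_stem = tier1, tier2_stem = tier2)
}

# vectorized stems for a character vector of names
stem_frame <- function(names) {
  st <- lapply(names, normalize_mirna_name)
  data.frame(raw_name = names,
             tier1 = vapply(st, `[[`, "", "tier1_stem"),
             tier2 = vapply(st, `[[`, "", "tier2_stem"),
             stringsAsFactors = FALSE)
}

#' Find cross-species conserved miRNA/host gene pairs
#'
#' Matches intragenic miRNAs across species catalogs by name (explicit
#' orthologue overrides first, then tier-1 stem equality, then tier-2)
#' and requires the host genes to be pairwise linked in the orthology
#' map. One conserved pair is keyed by (stem, orthologous host group):
#' two members of a cluster in the same host are two pairs. The reported
#' \code{match_tier} is the lowest tier sufficient to unify all member
#' names (\code{1}, \code{2} or \code{"override"}).
#'
#' @param catalogs list of \code{catalog} objects with distinct species
#'   tags (at least two).
#' @param orthology an \code{\link{orthology_map}}; its \code{overrides}
#'   unify miRNA names that normalization cannot match.
#' @return data.frame with one row per (pair, species entry): columns
#'   \code{pair_id}, \code{stem}, \code{match_tier}, \code{n_species},
#'   \code{species}, \code{precursor_id}, \code{mirna_name},
#'   \code{gene_id}, \code{gene_symbol}, \code{location_label}; sorted by
#'   stem then species.
#' @export
find_conserved_pairs <- function(catalogs, orthology) {
  tags <- vapply(catalogs, `[[`, "", "species")
  if (length(tags) < 2L) stop("need at least 2 catalogs")
  if (anyDuplicated(tags)) stop("species tag collision: ",
                                paste(tags[duplicated(tags)], collapse = ", "))
  entries <- do.call(rbind, lapply(catalogs, function(ct) {
    a <- ct$assignments
    if (nrow(a) == 0L) return(NULL)
    data.frame(species = ct$species, precursor_id = a$precursor_id,
               mirna_name = a$mirna_name, gene_id = a$gene_id,
               gene_symbol = a$gene_symbol,
               location_label = a$location_label, stringsAsFactors = FALSE)
  }))
  empty <- data.frame(pair_id = character(), stem = character(),
                      match_tier = character(), n_species = integer(),
                      species = character(), precursor_id = character(),
                      mirna_name = character(), gene_id = character(),
                      gene_symbol = character(),
                      location_label = character(), stringsAsFactors = FALSE)
  if (is.null(entries) || nrow(entries) == 0L) return(empty)

  st <- stem_frame(entries$mirna_name)
  entries$tier1 <- st$tier1
  entries$tier2 <- st$tier2
  # override lookup: member name (lowercased) or tier1 stem -> canonical
  ov <- orthology$overrides
  ov_canon <- rep(NA_character_, nrow(entries))
  for (canon in names(ov)) {
    members <- tolower(ov[[canon]])
    hit <- tolower(entries$mirna_name) %in% members |
      entries$tier1 %in% members
    ov_canon[hit] <- canon
  }
  entries$match_key <- ifelse(!is.na(ov_canon), paste0("ov:", ov_canon),
                       ifelse(!is.na(entries$tier2), entries$tier2,
                              entries$tier1))
  entries$ov_canon <- ov_canon

  pairs <- list()
  for (key in sort(unique(entries$match_key))) {
    grp <- entries[entries$match_key == key, , drop = FALSE]
    n <- nrow(grp)
    # connected components over host-orthology edges between species
    comp <- seq_len(n)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        if (grp$species[i] != grp$species[j] &&
            orthology_linked(orthology, grp$species[i], grp$gene_id[i],
                             grp$species[j], grp$gene_id[j])) {
          comp[comp == comp[j]] <- comp[i]
        }
      }
    }
    for (cid in unique(comp)) {
      sel <- grp[comp == cid, , drop = FALSE]
      spp <- unique(sel$species)
      if (length(spp) < 2L) next
      # require full pairwise orthology across species entries
      ok <- TRUE
      for (i in seq_len(nrow(sel) - 1L)) for (j in seq(i + 1L, nrow(sel))) {
        if (sel$species[i] != sel$species[j] &&
            !orthology_linked(orthology, sel$species[i], sel$gene_id[i],
                              sel$species[j], sel$gene_id[j])) ok <- FALSE
      }
      if (!ok) next
      # effective tier-2 stem: tier 1 when no letter variant to strip
      eff2 <- ifelse(is.na(sel$tier2), sel$tier1, sel$tier2)
      tier <- if (length(unique(sel$tier1)) == 1L) {
        "1"
      } else if (length(unique(eff2)) == 1L) {
        "2"
      } else {
        "override"
      }
      stem <- if (tier == "1") sel$tier1[1L]
              else if (tier == "2") eff2[1L]
              else if (!is.na(sel$ov_canon[1L])) sel$ov_canon[1L]
              else sub("^ov:", "", key)
      sel <- sel[order(sel$species, sel$precursor_id), , drop = FALSE]
      pairs[[length(pairs) + 1L]] <- data.frame(
        pair_id = paste0(stem, "@", paste(sort(unique(sel$gene_id)),
                                          collapse = "|")),
        stem = stem, match_tier = tier, n_species = length(spp),
        sel[, c("species", "precursor_id", "mirna_name", "gene_id",
                "gene_symbol", "location_label")],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) return(empty)
  out <- do.call(rbind, pairs)
  out <- out[order(out$stem, out$pair_id, out$species, out$precursor_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count conserved pairs per species subset (Venn cells)
#'
#' Each conserved pair falls in exactly one cell: the subset of species
#' it spans. Cells are reported for every non-empty subset of the species
#' seen, singletons first, then pairs, then larger subsets; singleton
#' cells are always zero because a conserved pair spans at least two
#' species.
#'
#' @param pairs output of \code{\link{find_conserved_pairs}}.
#' @param species optional character vector fixing the species universe
#'   (defaults to the species occurring in \code{pairs}).
#' @return named integer vector; names are subsets like
#'   \code{"human&mouse"}.
#' @export
subset_counts <- function(pairs, species = NULL) {
  if (is.null(species)) species <- sort(unique(pairs$species))
  if (!length(species)) return(stats::setNames(integer(), character()))
  subsets <- list()
  for (k in seq_along(species)) {
    cmb <- utils::combn(species, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = "&"), "")
  counts <- stats::setNames(integer(length(keys)), keys)
  if (nrow(pairs)) {
    per_pair <- tapply(pairs$species, pairs$pair_id,
                       function(x) paste(sort(unique(x)), collapse = "&"))
    tab <- table(per_pair)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}
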