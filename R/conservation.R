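# Cross-species phosphosite conservation: pairwise alignment, site
# mapping through alignment columns, aggregate overlap, and category
# enrichment of the conserved fraction.

#' Global pairwise protein alignment
#'
#' Aligns two protein sequences globally (Needleman-Wunsch as provided
#' by Biostrings) with the BLOSUM62 substitution matrix and affine gap
#' penalties (open 10, extend 1). Intended for small inputs and
#' self-contained tests; externally produced alignments (e.g. Muscle)
#' can be supplied to the mapping functions instead and take precedence.
#'
#' @param query_seq,target_seq Protein sequences (20 standard letters).
#' @param query_id,target_id Identifiers stored in the result.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @return An [aligned_pair()] with an extra `score` element.
#' @export
align_pair <- function(query_seq, target_seq, query_id = "query",
                       target_id = "target", gap_opening = 10,
                       gap_extension = 1) {
  if (nchar(query_seq) == 0 || nchar(target_seq) == 0) {
    stop_data("cannot align empty sequences")
  }
  ok <- paste0("^[", paste(AA20, collapse = ""), "]+$")
  if (!grepl(ok, query_seq) || !grepl(ok, target_seq)) {
    stop_data("sequences contain non-amino-acid characters")
  }
  aln <- Biostrings::pairwiseAlignment(
    query_seq, target_seq, type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = gap_opening, gapExtension = gap_extension)
  pair <- aligned_pair(query_id, target_id,
                       as.character(Biostrings::alignedPattern(aln)),
                       as.character(Biostrings::alignedSubject(aln)))
  pair$score <- Biostrings::score(aln)
  pair
}

#' Map a phosphosite through a pairwise alignment
#'
#' Locates the alignment column holding the query site's (ungapped,
#' 1-based) position and reads off the target coordinate. The site is
#' *conserved* when the aligned target position carries a phosphosite in
#' the target dataset; by default any phosphorylated residue at that
#' position counts, with `strict_residue = TRUE` requiring the same
#' S/T/Y letter as the query site.
#'
#' @param site A one-row data frame (or list) with `protein_id`,
#'   `position`, `residue`.
#' @param pair An [aligned_pair()] whose query row carries the site.
#' @param target_sites Site set of the target species.
#' @param strict_residue Require the target phosphosite to have the same
#'   residue letter.
#' @return A list of class `site_mapping`: `protein_id`, `position`,
#'   `residue`, `target_protein`, `target_position` (NA when unmapped),
#'   `status` (one of `gap_in_target`, `aligned_not_phosphorylated`,
#'   `conserved`).
#' @export
map_site <- function(site, pair, target_sites, strict_residue = FALSE) {
  stopifnot(inherits(pair, "aligned_pair"))
  pos <- as.integer(site$position)
  q <- strsplit(pair$query_row, "", fixed = TRUE)[[1]]
  t <- strsplit(pair$target_row, "", fixed = TRUE)[[1]]
  nongap_q <- which(q != "-")
  if (pos < 1 || pos > length(nongap_q)) {
    stop_data("site position ", pos, " exceeds the ungapped query row length (",
              length(nongap_q), ")")
  }
  col <- nongap_q[pos]
  result <- list(protein_id = as.character(site$protein_id),
                 position = pos,
                 residue = as.character(site$residue),
                 target_protein = pair$target_id,
                 target_position = NA_integer_,
                 status = NA_character_)
  if (t[col] == "-") {
    result$status <- "gap_in_target"
  } else {
    tpos <- sum(t[seq_len(col)] != "-")
    result$target_position <- tpos
    ts <- as_sites(target_sites)
    hit <- ts$protein_id == pair$target_id & ts$position == tpos
    if (strict_residue) hit <- hit & ts$residue == result$residue
    result$status <- if (any(hit)) "conserved" else "aligned_not_phosphorylated"
  }
  class(result) <- "site_mapping"
  result
}

#' @export
print.site_mapping <- function(x, ...) {
  cat(sprintf("%s %s%d -> %s %s [%s]\n", x$protein_id, x$residue, x$position,
              x$target_protein,
              ifelse(is.na(x$target_position), "-", x$target_position),
              x$status))
  invisible(x)
}

#' Cross-species phosphosite overlap
#'
#' Maps every unique phosphosite of a query dataset onto a target
#' species through ortholog pairs and pairwise alignments, and reports
#' which sites are conserved (aligned exactly with a phosphosite of the
#' target dataset). The conservation fraction uses *all* query sites in
#' the denominator, including those without an ortholog or alignment.
#' When a query protein has several orthologs, the site is mapped
#' through each and called conserved if any mapping succeeds.
#'
#' @param query_dataset,target_dataset Site sets (`site_dataset` or data
#'   frame).
#' @param orthologs Data frame with columns `query_id`, `target_id` (see
#'   [read_ortholog_table()]).
#' @param alignments List of [aligned_pair()] objects covering the
#'   ortholog pairs; pairs without an alignment yield status
#'   `no_alignment`.
#' @param strict_residue Passed to [map_site()].
#' @return An object of class `conservation_result`: list with
#'   `mappings` (data frame: site columns plus `target_protein`,
#'   `target_position`, `status`), `n_query_sites`, `n_conserved`,
#'   `fraction_conserved`.
#' @export
cross_species_overlap <- function(query_dataset, target_dataset, orthologs,
                                  alignments, strict_residue = FALSE) {
  qs <- as_sites(query_dataset)
  ts <- as_sites(target_dataset)
  if (nrow(qs) == 0) stop_data("query dataset has no sites")
  orth <- split(as.character(orthologs$target_id),
                as.character(orthologs$query_id))
  # Pre-digest alignments: column arithmetic is shared across all sites
  # of a protein pair.
  aln_index <- new.env(parent = emptyenv())
  for (p in alignments) {
    stopifnot(inherits(p, "aligned_pair"))
    q <- strsplit(p$query_row, "", fixed = TRUE)[[1]]
    t <- strsplit(p$target_row, "", fixed = TRUE)[[1]]
    assign(paste(p$query_id, p$target_id, sep = "\t"),
           list(nongap_q = which(q != "-"), t = t,
                tpos = cumsum(t != "-")),
           envir = aln_index)
  }
  ts_keys <- if (strict_residue) {
    site_key(ts$protein_id, ts$position, ts$residue)
  } else {
    paste(ts$protein_id, ts$position, sep = "\t")
  }
  status_rank <- c(no_ortholog = 1, no_alignment = 2, gap_in_target = 3,
                   aligned_not_phosphorylated = 4, conserved = 5)
  n <- nrow(qs)
  status <- character(n)
  tgt_prot <- rep(NA_character_, n)
  tgt_pos <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    targets <- orth[[qs$protein_id[i]]]
    if (is.null(targets)) {
      status[i] <- "no_ortholog"
      next
    }
    best <- "no_alignment"
    pos <- qs$position[i]
    for (tid in targets) {
      aln <- get0(paste(qs$protein_id[i], tid, sep = "\t"),
                  envir = aln_index)
      if (is.null(aln)) next
      if (pos < 1 || pos > length(aln$nongap_q)) {
        stop_data("site position ", pos,
                  " exceeds the ungapped query row length for ",
                  qs$protein_id[i])
      }
      col <- aln$nongap_q[pos]
      if (aln$t[col] == "-") {
        st <- "gap_in_target"
        tp <- NA_integer_
      } else {
        tp <- aln$tpos[col]
        key <- if (strict_residue) {
          site_key(tid, tp, qs$residue[i])
        } else {
          paste(tid, tp, sep = "\t")
        }
        st <- if (key %in% ts_keys) "conserved" else
          "aligned_not_phosphorylated"
      }
      if (status_rank[st] > status_rank[best]) {
        best <- st
        tgt_prot[i] <- tid
        tgt_pos[i] <- tp
      }
      if (best == "conserved") break
    }
    status[i] <- best
  }
  mappings <- cbind(qs, data.frame(target_protein = tgt_prot,
                                   target_position = tgt_pos,
                                   status = status,
                                   stringsAsFactors = FALSE))
  n_cons <- sum(status == "conserved")
  structure(list(mappings = mappings,
                 n_query_sites = n,
                 n_conserved = n_cons,
                 fraction_conserved = n_cons / n),
            class = "conservation_result")
}

#' @export
print.conservation_result <- function(x, ...) {
  cat(sprintf("Cross-species overlap: %d of %d query sites conserved (%.1f%%)\n",
              x$n_conserved, x$n_query_sites, 100 * x$fraction_conserved))
  print(table(x$mappings$status))
  invisible(x)
}

#' Category enrichment in the conserved phosphosite fraction
#'
#' Tests whether sites on proteins of a category (e.g. kinases) are
#' overrepresented among conserved phosphosites, with a one-sided
#' Fisher exact test on the site-level 2x2 table (conserved vs not,
#' in-category vs not).
#'
#' `category_enrichment()` derives the counts from a
#' [cross_species_overlap()] result; `category_enrichment_counts()`
#' accepts the four counts directly (useful when only published totals
#' are available).
#'
#' @param result A `conservation_result`.
#' @param category_proteins Character vector of category protein ids.
#' @return An object of class `category_enrichment`: list with the 2x2
#'   `table`, the input counts, `odds_ratio` and one-sided `p_value`.
#' @export
category_enrichment <- function(result, category_proteins) {
  stopifnot(inherits(result, "conservation_result"))
  m <- result$mappings
  in_cat <- m$protein_id %in% as.character(category_proteins)
  conserved <- m$status == "conserved"
  category_enrichment_counts(n_sites = nrow(m),
                             n_category = sum(in_cat),
                             n_conserved = sum(conserved),
                             n_conserved_category = sum(in_cat & conserved))
}

#' @rdname category_enrichment
#' @param n_sites Total number of sites.
#' @param n_category Sites on category proteins (out of `n_sites`).
#' @param n_conserved Conserved sites.
#' @param n_conserved_category Conserved sites on category proteins.
#' @export
category_enrichment_counts <- function(n_sites, n_category, n_conserved,
                                       n_conserved_category) {
  if (n_conserved > n_sites || n_category > n_sites ||
      n_conserved_category > min(n_conserved, n_category)) {
    stop_data("inconsistent counts for the 2x2 table")
  }
  a <- n_conserved_category
  b <- n_conserved - a
  c <- n_category - a
  d <- n_sites - n_conserved - c
  tab <- matrix(c(a, b, c, d), nrow = 2,
                dimnames = list(category = c("yes", "no"),
                                conserved = c("yes", "no")))
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    warning("degenerate 2x2 margins; p set to 1")
    p <- 1
    or <- NA_real_
  } else {
    ft <- fisher.test(tab, alternative = "greater")
    p <- ft$p.value
    or <- unname(ft$estimate)
  }
  structure(list(table = tab, n_sites = n_sites, n_category = n_category,
                 n_conserved = n_conserved,
                 n_conserved_category = n_conserved_category,
                 odds_ratio = or, p_value = p),
            class = "category_enrichment")
}

#' @export
print.category_enrichment <- function(x, ...) {
  cat(sprintf(
    "Category enrichment: %d/%d conserved vs %d/%d overall in category (one-sided Fisher p = %.3g)\n",
    x$n_conserved_category, x$n_conserved, x$n_category, x$n_sites,
    x$p_value))
  invisible(x)
}
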