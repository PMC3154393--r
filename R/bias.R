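# Enrichment-bias analysis: flank composition, randomization testing,
# common-reference correction, and category term enrichment.

# Per-site flank counts over the 20 standard amino acids: offsets
# -window..-1 and +1..+window around each site, truncated at the protein
# termini; the central phosphorylated residue is excluded. Returns an
# n_sites x 20 integer matrix. Non-standard letters in the flanks are
# not counted.
flank_counts_matrix <- function(sites, proteome, window = 5,
                                lenient = FALSE) {
  sites <- as_sites(sites)
  seqs <- unclass(proteome)
  known <- sites$protein_id %in% names(seqs)
  in_range <- known
  in_range[known] <- sites$position[known] <=
    nchar(seqs[sites$protein_id[known]])
  if (!all(in_range)) {
    if (!lenient) {
      bad <- which(!in_range)[1]
      stop_data("site outside proteome: ",
                site_key(sites$protein_id[bad], sites$position[bad],
                         sites$residue[bad]))
    }
    warning(sum(!in_range), " site(s) outside the proteome dropped")
    sites <- sites[in_range, , drop = FALSE]
  }
  out <- matrix(0L, nrow = nrow(sites), ncol = length(AA20),
                dimnames = list(NULL, AA20))
  for (i in seq_len(nrow(sites))) {
    s <- seqs[[sites$protein_id[i]]]
    p <- sites$position[i]
    L <- nchar(s)
    lo <- max(1L, p - window)
    hi <- min(L, p + window)
    flank <- strsplit(substr(s, lo, hi), "", fixed = TRUE)[[1]]
    flank <- flank[-(p - lo + 1L)]
    counts <- table(factor(flank, levels = AA20))
    out[i, ] <- as.integer(counts)
  }
  out
}

#' Flanking amino-acid composition of a set of phosphosites
#'
#' Pools the residues in the `window` positions on each side of every
#' site (10 residues at the default window of 5, fewer near protein
#' termini; the phosphorylated residue itself is never counted) and
#' reports counts and prevalences (percent of all pooled flank
#' residues). Differences in this profile between enrichment strategies
#' (e.g. the acidic D/E excess of TiO2 affinity relative to
#' anti-phosphotyrosine immunoprecipitation) are the signature of
#' enrichment bias.
#'
#' @param sites A site set (`site_dataset` or data frame).
#' @param proteome Named character vector of protein sequences.
#' @param window Number of flanking residues on each side (default 5).
#' @param lenient Drop sites outside the proteome instead of erroring.
#' @return An object of class `flank_profile`: list with `counts` (named
#'   integer vector over the 20 standard amino acids), `total`,
#'   `prevalence` (percent), `window`, `n_sites`.
#' @export
flank_composition <- function(sites, proteome, window = 5, lenient = FALSE) {
  cm <- flank_counts_matrix(sites, proteome, window = window,
                            lenient = lenient)
  counts <- colSums(cm)
  total <- sum(counts)
  prevalence <- if (total > 0) 100 * counts / total else counts * 0
  structure(list(counts = setNames(as.integer(counts), AA20),
                 total = as.integer(total),
                 prevalence = prevalence,
                 window = window, n_sites = nrow(cm)),
            class = "flank_profile")
}

#' @export
print.flank_profile <- function(x, ...) {
  cat("Flank composition of", x$n_sites, "sites (window", x$window,
      "; ", x$total, "residues)\n")
  top <- sort(x$prevalence, decreasing = TRUE)[1:5]
  cat("  top residues:",
      paste(sprintf("%s %.1f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Randomization test for differences in flank composition
#'
#' Compares the pooled flank prevalence of every amino acid between two
#' site sets (e.g. sites found by two enrichment strategies). The test
#' statistic per residue is the absolute difference in prevalence; the
#' null distribution is built by randomly reassigning sites to the two
#' groups while keeping the group sizes fixed. Raw p-values use the
#' add-one permutation estimator (1 + exceedances) / (1 + permutations)
#' and are Bonferroni-corrected over the residues actually observed in
#' the pooled flanks.
#'
#' @param sites_a,sites_b Site sets (each a `site_dataset` or data frame).
#' @param proteome Named character vector of protein sequences.
#' @param window Flank window on each side (default 5).
#' @param n_permutations Number of random reassignments (default 10000).
#' @param alpha Significance level applied to the adjusted p-values
#'   (default 0.01).
#' @param seed Optional integer seed.
#' @param lenient Drop sites outside the proteome instead of erroring.
#' @return An object of class `composition_test` whose `table` element is
#'   a data frame with one row per observed residue: `residue`,
#'   `prevalence_a`, `prevalence_b`, `abs_difference`, `p`, `p_adjusted`,
#'   `significant`.
#' @export
composition_randomization_test <- function(sites_a, sites_b, proteome,
                                           window = 5,
                                           n_permutations = 10000,
                                           alpha = 0.01, seed = NULL,
                                           lenient = FALSE) {
  if (n_permutations < 1) stop_data("n_permutations must be >= 1")
  ca <- flank_counts_matrix(sites_a, proteome, window, lenient)
  cb <- flank_counts_matrix(sites_b, proteome, window, lenient)
  if (nrow(ca) == 0 || nrow(cb) == 0) stop_data("both site sets must be non-empty")
  C <- rbind(ca, cb)
  n <- nrow(C)
  tot_all <- sum(C)
  col_all <- colSums(C)
  prev <- function(colsum, total) if (total > 0) 100 * colsum / total else colsum * 0
  prev_a <- prev(colSums(ca), sum(ca))
  prev_b <- prev(colSums(cb), sum(cb))
  obs <- abs(prev_a - prev_b)
  # Null: reassign sites to groups, group sizes fixed. The pooled rows
  # are put in a canonical order and the smaller group size is sampled
  # (the absolute-difference statistic does not care which side the
  # sampled split lands on), so the result is exactly symmetric in the
  # two inputs for a given seed. Blocks are evaluated as an
  # indicator-matrix product for speed.
  C <- C[do.call(order, as.data.frame(C)), , drop = FALSE]
  row_tot <- rowSums(C)
  k_draw <- min(nrow(ca), nrow(cb))
  exceed <- numeric(length(AA20))
  block <- 2000L
  with_seed(seed, {
    done <- 0L
    while (done < n_permutations) {
      b <- min(block, n_permutations - done)
      P <- matrix(0, nrow = b, ncol = n)
      for (j in seq_len(b)) P[j, sample.int(n, k_draw)] <- 1
      sum_a <- P %*% C                      # b x 20 flank counts, group a
      tot_a <- as.vector(P %*% row_tot)
      sum_b <- rep(col_all, each = b) - sum_a
      tot_b <- tot_all - tot_a
      pa <- 100 * sum_a / tot_a
      pb <- 100 * sum_b / tot_b
      stat <- abs(pa - pb)
      exceed <- exceed +
        colSums(stat >= rep(obs, each = b) - 1e-12)
      done <- done + b
    }
  })
  tested <- col_all > 0
  n_tested <- sum(tested)
  p_raw <- (1 + exceed) / (1 + n_permutations)
  p_adj <- pmin(1, p_raw * n_tested)
  tab <- data.frame(residue = AA20,
                    prevalence_a = as.numeric(prev_a),
                    prevalence_b = as.numeric(prev_b),
                    abs_difference = as.numeric(obs),
                    p = p_raw,
                    p_adjusted = p_adj,
                    stringsAsFactors = FALSE)[tested, , drop = FALSE]
  tab$significant <- tab$p_adjusted < alpha
  rownames(tab) <- NULL
  structure(list(table = tab, n_permutations = n_permutations,
                 alpha = alpha, n_residues_tested = n_tested,
                 n_sites_a = nrow(ca), n_sites_b = nrow(cb)),
            class = "composition_test")
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf(
    "Flank composition randomization test: %d vs %d sites, %d permutations, %d residues tested\n",
    x$n_sites_a, x$n_sites_b, x$n_permutations, x$n_residues_tested))
  sig <- x$table[x$table$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    cat("  no residue significant at alpha =", x$alpha, "\n")
  } else {
    for (i in seq_len(nrow(sig))) {
      cat(sprintf("  %s: %.1f%% vs %.1f%% (p_adj = %.3g)\n",
                  sig$residue[i], sig$prevalence_a[i], sig$prevalence_b[i],
                  sig$p_adjusted[i]))
    }
  }
  invisible(x)
}

#' Common-reference correction for enrichment-strategy bias
#'
#' The overlap between two phosphoproteomics datasets confounds dataset
#' incompleteness with enrichment bias. Comparing each dataset to a
#' large common reference separates the two: the ratio of the fractional
#' overlaps (fraction of dataset A's sites found in the reference,
#' divided by the same fraction for dataset B) estimates the
#' multiplicative correction to apply to an observed A-vs-B style
#' overlap had both been generated with the same technique.
#'
#' @param dataset_a,dataset_b Site sets (`site_dataset` or data frame).
#' @param reference A site set acting as the common benchmark.
#' @return An object of class `correction_result`: list with `frac_a`,
#'   `frac_b`, `factor`, and the set/intersection sizes.
#' @examples
#' # 38% vs 16% reference overlap -> correction factor 38/16 = 2.4
#' @export
common_reference_correction <- function(dataset_a, dataset_b, reference) {
  ka <- with(as_sites(dataset_a), site_key(protein_id, position, residue))
  kb <- with(as_sites(dataset_b), site_key(protein_id, position, residue))
  kr <- with(as_sites(reference), site_key(protein_id, position, residue))
  if (length(ka) == 0 || length(kb) == 0) stop_data("empty dataset")
  if (length(kr) == 0) stop_data("empty reference")
  ia <- sum(ka %in% kr)
  ib <- sum(kb %in% kr)
  frac_a <- ia / length(ka)
  frac_b <- ib / length(kb)
  if (frac_b == 0) stop_data("dataset B has no overlap with the reference; factor undefined")
  structure(list(frac_a = frac_a, frac_b = frac_b,
                 factor = frac_a / frac_b,
                 n_a = length(ka), n_b = length(kb), n_reference = length(kr),
                 n_a_in_reference = ia, n_b_in_reference = ib),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf(
    "Reference overlap: A %d/%d (%.0f%%), B %d/%d (%.0f%%); correction factor %.2g\n",
    x$n_a_in_reference, x$n_a, 100 * x$frac_a,
    x$n_b_in_reference, x$n_b, 100 * x$frac_b, x$factor))
  invisible(x)
}

#' Category term enrichment of a phosphoprotein set
#'
#' For every annotation term, tests whether proteins carrying the term
#' are overrepresented among phosphoproteins relative to the whole
#' proteome. Overrepresentation is expressed as fold increase on a log2
#' scale, log2(k/n) - log2(K/N), where k of the n phosphoproteins and K
#' of the N proteome proteins carry the term; significance is a
#' one-sided Fisher exact test with Benjamini-Hochberg correction across
#' terms.
#'
#' @param phospho_proteins Character vector of phosphoprotein ids (must
#'   be a subset of `proteome_proteins`).
#' @param proteome_proteins Character vector of all protein ids.
#' @param annotations Data frame with columns `protein_id`, `term` (see
#'   [read_annotation_table()]).
#' @return An object of class `term_enrichment`: a data frame with
#'   columns `term`, `k`, `n`, `K`, `N`, `fold`, `p`, `p_adjusted`.
#' @export
term_enrichment <- function(phospho_proteins, proteome_proteins,
                            annotations) {
  phospho <- unique(as.character(phospho_proteins))
  proteome <- unique(as.character(proteome_proteins))
  if (!all(phospho %in% proteome)) {
    stop_data("phosphoproteins must be a subset of the proteome proteins")
  }
  ann <- annotations[annotations$protein_id %in% proteome, , drop = FALSE]
  terms <- unique(as.character(ann$term))
  n <- length(phospho)
  N <- length(proteome)
  rows <- lapply(terms, function(tm) {
    members <- unique(ann$protein_id[ann$term == tm])
    K <- length(members)
    if (K == 0) {
      message("term '", tm, "' has no proteome members; skipped")
      return(NULL)
    }
    k <- sum(phospho %in% members)
    fold <- log2(k / n) - log2(K / N)
    m <- matrix(c(k, n - k, K - k, N - n - (K - k)), nrow = 2)
    p <- fisher.test(m, alternative = "greater")$p.value
    data.frame(term = tm, k = k, n = n, K = K, N = N, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p = numeric(0), p_adjusted = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("term_enrichment", "data.frame")
    return(out)
  }
  out$p_adjusted <- p.adjust(out$p, method = "BH")
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("term_enrichment", "data.frame")
  out
}
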