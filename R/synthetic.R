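# Synthetic ground-truth generators: proteomes, phosphoproteomes with
# heterogeneous detectability, biased enrichment experiments, and
# diverged ortholog pairs with a controlled site-conservation rate.

#' Generate a random proteome
#'
#' Sequences are i.i.d. draws from `aa_frequencies` (default: average
#' eukaryotic amino-acid composition); lengths are geometric around
#' `mean_length` with a minimum of 20 residues.
#'
#' @param n_proteins Number of proteins.
#' @param mean_length Mean sequence length (>= 21).
#' @param aa_frequencies Named numeric vector over the 20 standard amino
#'   acids summing to 1; defaults to a realistic background composition.
#' @param seed Optional integer seed.
#' @return Named character vector of sequences (ids `P0001`, ...).
#' @export
generate_proteome <- function(n_proteins = 100, mean_length = 300,
                              aa_frequencies = NULL, seed = NULL) {
  if (n_proteins < 1) stop_data("n_proteins must be >= 1")
  freq <- aa_frequencies %||% AA_BACKGROUND
  if (is.null(names(freq)) || !setequal(names(freq), AA20)) {
    stop_data("aa_frequencies must be named over the 20 standard amino acids")
  }
  if (any(freq < 0) || abs(sum(freq) - 1) > 1e-6) {
    stop_data("aa_frequencies must be non-negative and sum to 1")
  }
  freq <- freq[AA20]
  if (mean_length < 21) stop_data("mean_length must be >= 21")
  with_seed(seed, {
    lens <- 20L + rgeom(n_proteins, prob = 1 / (mean_length - 19))
    seqs <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = freq), collapse = "")
    }, character(1))
    names(seqs) <- sprintf("P%04d", seq_len(n_proteins))
    seqs
  })
}

# All S/T/Y positions of a proteome as a site data frame.
sty_positions <- function(proteome) {
  rows <- lapply(names(proteome), function(id) {
    chars <- strsplit(proteome[[id]], "", fixed = TRUE)[[1]]
    idx <- which(chars %in% PHOSPHO_RESIDUES)
    if (length(idx) == 0) return(NULL)
    data.frame(protein_id = id, position = idx, residue = chars[idx],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Generate a ground-truth phosphoproteome
#'
#' Each S/T/Y position of the proteome becomes a true phosphosite
#' independently with probability `site_fraction`. Every true site gets
#' a positive detection weight (an abundance/stoichiometry proxy) drawn
#' i.i.d. log-normal with `sdlog = weight_dispersion`; dispersion 0
#' gives homogeneous weights, the regime in which the Chao1 estimator
#' is consistent, while large dispersion reproduces the detection
#' heterogeneity that makes Chao1 a moving lower bound.
#'
#' @param proteome Named character vector of sequences.
#' @param site_fraction Per-position phosphorylation probability in
#'   (0, 1].
#' @param weight_dispersion Log-normal sdlog of detection weights
#'   (>= 0).
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_truth`: list with `proteome`,
#'   `true_sites` (data frame), `detection_weight` (numeric, one per
#'   true site), `parameters`, `seed`.
#' @export
generate_phosphoproteome <- function(proteome, site_fraction = 0.05,
                                     weight_dispersion = 1, seed = NULL) {
  if (site_fraction <= 0 || site_fraction > 1) {
    stop_data("site_fraction must be in (0, 1]")
  }
  if (weight_dispersion < 0) stop_data("weight_dispersion must be >= 0")
  sty <- sty_positions(proteome)
  if (nrow(sty) == 0) stop_data("proteome contains no S/T/Y residues")
  with_seed(seed, {
    keep <- runif(nrow(sty)) < site_fraction
    sites <- sty[keep, , drop = FALSE]
    rownames(sites) <- NULL
    w <- if (weight_dispersion == 0) rep(1, nrow(sites)) else
      rlnorm(nrow(sites), meanlog = 0, sdlog = weight_dispersion)
    structure(list(proteome = proteome, true_sites = sites,
                   detection_weight = w,
                   parameters = list(site_fraction = site_fraction,
                                     weight_dispersion = weight_dispersion),
                   seed = seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic phosphoproteome:", nrow(x$true_sites), "true sites on",
      length(x$proteome), "proteins (site_fraction",
      x$parameters$site_fraction, ", dispersion",
      x$parameters$weight_dispersion, ")\n")
  invisible(x)
}

#' Describe an enrichment strategy
#'
#' An enrichment profile determines which true sites an experiment tends
#' to observe: `residue_selectivity` multiplies the detection weight per
#' central residue (an anti-phosphotyrosine strategy is `c(S = 0,
#' T = 0, Y = 1)`), `flank_bias` adds per-letter log-weights evaluated
#' on the +/- 5 flank composition (a TiO2-like acidic preference is
#' `c(D = 1, E = 1)`), and `depth` is the number of observation draws
#' per experiment.
#'
#' @param residue_selectivity Named non-negative multipliers for S, T,
#'   Y; at least one must be positive.
#' @param flank_bias Named numeric log-weights per amino-acid letter
#'   (default: none).
#' @param depth Number of observation draws (default 1000).
#' @return An object of class `enrichment_profile`.
#' @export
enrichment_profile <- function(residue_selectivity = c(S = 1, T = 1, Y = 1),
                               flank_bias = numeric(0), depth = 1000) {
  sel <- setNames(rep(0, 3), PHOSPHO_RESIDUES)
  sel[names(residue_selectivity)] <- residue_selectivity
  if (any(sel < 0)) stop_data("residue selectivities must be >= 0")
  if (all(sel == 0)) stop_data("at least one residue must be selectable")
  if (length(flank_bias) > 0 &&
      (is.null(names(flank_bias)) || !all(names(flank_bias) %in% AA20))) {
    stop_data("flank_bias must be named with standard amino-acid letters")
  }
  if (depth < 1) stop_data("depth must be >= 1")
  structure(list(residue_selectivity = sel, flank_bias = flank_bias,
                 depth = depth),
            class = "enrichment_profile")
}

#' Simulate one enrichment experiment
#'
#' Draws `profile$depth` observations from the true phosphosites with
#' probability proportional to detection_weight x residue selectivity x
#' exp(sum of flank_bias over the +/- 5 flank), then collapses them to
#' at most one observation per site (a site either is or is not reported
#' by a source). The result is a single-source [site_dataset()];
#' simulate several sources to build replicate structure.
#'
#' @param truth A `synthetic_truth`.
#' @param profile An [enrichment_profile()].
#' @param source_id Label of the simulated replicate/experiment.
#' @param seed Optional integer seed.
#' @return A `site_dataset` with one source.
#' @export
simulate_experiment <- function(truth, profile, source_id = "exp1",
                                seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(profile, "enrichment_profile"))
  sites <- truth$true_sites
  if (nrow(sites) == 0) stop_data("truth contains no sites")
  w <- truth$detection_weight *
    profile$residue_selectivity[sites$residue]
  if (length(profile$flank_bias) > 0) {
    cm <- flank_counts_matrix(sites, truth$proteome, window = 5)
    bias <- setNames(rep(0, length(AA20)), AA20)
    bias[names(profile$flank_bias)] <- profile$flank_bias
    w <- w * exp(as.vector(cm %*% bias))
  }
  if (all(w == 0)) stop_data("no selectable site under this profile")
  with_seed(seed, {
    draws <- sample.int(nrow(sites), size = profile$depth, replace = TRUE,
                        prob = w)
    idx <- sort(unique(draws))
    obs <- sites[idx, , drop = FALSE]
    obs$source_id <- source_id
    site_dataset(obs)
  })
}

#' Simulate a replicated experiment
#'
#' Convenience wrapper running [simulate_experiment()] for several
#' sources and pooling the observations into one dataset.
#'
#' @param truth A `synthetic_truth`.
#' @param profile An [enrichment_profile()].
#' @param n_sources Number of replicates/publications to simulate.
#' @param seed Optional integer seed.
#' @return A `site_dataset` whose multiplicities count the simulated
#'   sources detecting each site.
#' @export
simulate_replicates <- function(truth, profile, n_sources, seed = NULL) {
  if (n_sources < 1) stop_data("n_sources must be >= 1")
  with_seed(seed, {
    obs <- do.call(rbind, lapply(seq_len(n_sources), function(i) {
      simulate_experiment(truth, profile,
                          source_id = sprintf("rep%02d", i))$observations
    }))
    site_dataset(obs)
  })
}

#' Generate a diverged ortholog proteome with known site conservation
#'
#' Copies every protein of a ground truth into a target species,
#' applying point substitutions at rate `substitution_rate` and short
#' indels (1-3 residues) at rate `indel_rate` per position. Each true
#' query phosphosite is chosen *conserved* independently with
#' probability `conservation_prob`; conserved positions are protected
#' from substitution and deletion and re-emitted as true phosphosites of
#' the target. The true alignments are recorded during simulation, so
#' downstream conservation analysis can be validated without running an
#' aligner.
#'
#' @param truth A `synthetic_truth`.
#' @param substitution_rate,indel_rate Per-position rates in [0, 1).
#' @param conservation_prob Per-site retention probability in [0, 1].
#' @param seed Optional integer seed.
#' @return A list of class `ortholog_simulation` with `target_proteome`,
#'   `orthologs` (query_id/target_id data frame), `alignments` (list of
#'   [aligned_pair()]), `target_sites` (data frame), and
#'   `conserved` (logical per true query site).
#' @export
generate_ortholog_pair <- function(truth, substitution_rate = 0.2,
                                   indel_rate = 0.02,
                                   conservation_prob = 0.3, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    stop_data("substitution_rate and indel_rate must be in [0, 1)")
  }
  if (conservation_prob < 0 || conservation_prob > 1) {
    stop_data("conservation_prob must be in [0, 1]")
  }
  proteome <- truth$proteome
  sites <- truth$true_sites
  with_seed(seed, {
    conserved <- runif(nrow(sites)) < conservation_prob
    target_seqs <- character(length(proteome))
    names(target_seqs) <- paste0(names(proteome), "_ort")
    alignments <- vector("list", length(proteome))
    tgt_rows <- list()
    for (pi in seq_along(proteome)) {
      qid <- names(proteome)[pi]
      tid <- paste0(qid, "_ort")
      chars <- strsplit(proteome[[pi]], "", fixed = TRUE)[[1]]
      L <- length(chars)
      prot_sites <- which(conserved & sites$protein_id == qid)
      protected <- rep(FALSE, L)
      protected[sites$position[prot_sites]] <- TRUE
      qrow <- character(0)
      trow <- character(0)
      tpos_of <- integer(L)   # target position of each query position (0 = deleted)
      tlen <- 0L
      for (j in seq_len(L)) {
        u <- runif(1)
        if (!protected[j] && u < indel_rate) {
          # deletion in target
          qrow <- c(qrow, chars[j]); trow <- c(trow, "-")
          tpos_of[j] <- 0L
        } else {
          ch <- chars[j]
          if (!protected[j] && runif(1) < substitution_rate) {
            ch <- sample(setdiff(AA20, chars[j]), 1)
          }
          qrow <- c(qrow, chars[j]); trow <- c(trow, ch)
          tlen <- tlen + 1L
          tpos_of[j] <- tlen
        }
        if (runif(1) < indel_rate) {
          # insertion in target
          k <- sample.int(3, 1)
          ins <- sample(AA20, k, replace = TRUE)
          qrow <- c(qrow, rep("-", k)); trow <- c(trow, ins)
          tlen <- tlen + k
        }
      }
      target_seqs[[tid]] <- paste(trow[trow != "-"], collapse = "")
      alignments[[pi]] <- aligned_pair(qid, tid,
                                       paste(qrow, collapse = ""),
                                       paste(trow, collapse = ""))
      if (length(prot_sites) > 0) {
        tgt_rows[[length(tgt_rows) + 1L]] <- data.frame(
          protein_id = tid,
          position = tpos_of[sites$position[prot_sites]],
          residue = sites$residue[prot_sites],
          stringsAsFactors = FALSE)
      }
    }
    target_sites <- if (length(tgt_rows) > 0) do.call(rbind, tgt_rows) else
      data.frame(protein_id = character(0), position = integer(0),
                 residue = character(0), stringsAsFactors = FALSE)
    rownames(target_sites) <- NULL
    structure(list(
      target_proteome = target_seqs,
      orthologs = data.frame(query_id = names(proteome),
                             target_id = names(target_seqs),
                             stringsAsFactors = FALSE),
      alignments = alignments,
      target_sites = target_sites,
      conserved = conserved
    ), class = "ortholog_simulation")
  })
}

#' @export
print.ortholog_simulation <- function(x, ...) {
  cat("Simulated ortholog proteome:", length(x$target_proteome),
      "proteins;", sum(x$conserved), "of", length(x$conserved),
      "true sites conserved\n")
  invisible(x)
}
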