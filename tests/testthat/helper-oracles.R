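# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive (enumeration / closed forms) and share
# no code with the implementation they check.

# Closed-form expected number of unique sites after k draws without
# replacement from a pool with the given multiplicities:
# E[U(k)] = U - sum_s C(N - m_s, k) / C(N, k)
expected_unique_closed_form <- function(mult, k) {
  N <- sum(mult)
  length(mult) - sum(choose(N - mult, k)) / choose(N, k)
}

# A dataset with prescribed per-site multiplicities: site i is observed
# by sources src01..src<m_i>.
dataset_from_multiplicities <- function(mult, protein = "prot") {
  obs <- do.call(rbind, lapply(seq_along(mult), function(i) {
    data.frame(protein_id = protein, position = i * 3L, residue = "S",
               source_id = sprintf("src%02d", seq_len(mult[i])),
               stringsAsFactors = FALSE)
  }))
  site_dataset(obs)
}

# n distinct sites, one per protein, as a bare site data frame.
make_site_set <- function(n, prefix = "q", residue = "Y") {
  data.frame(protein_id = sprintf("%s%04d", prefix, seq_len(n)),
             position = 10L, residue = residue, stringsAsFactors = FALSE)
}

# Exhaustive randomization p-values for the flank-composition test on a
# tiny instance: every assignment of the pooled sites into groups of the
# original sizes is enumerated. Returns the per-residue exact p
# (proportion of assignments with |prevalence difference| >= observed).
exhaustive_composition_p <- function(sites_a, sites_b, proteome,
                                     window = 5) {
  count_one <- function(sites) {
    out <- setNames(rep(0, 20), phossat:::AA20)
    for (i in seq_len(nrow(sites))) {
      s <- proteome[[sites$protein_id[i]]]
      p <- sites$position[i]
      lo <- max(1, p - window); hi <- min(nchar(s), p + window)
      fl <- strsplit(substr(s, lo, hi), "")[[1]][-(p - lo + 1)]
      for (ch in fl) if (ch %in% names(out)) out[ch] <- out[ch] + 1
    }
    out
  }
  all_sites <- rbind(sites_a[, c("protein_id", "position", "residue")],
                     sites_b[, c("protein_id", "position", "residue")])
  counts <- t(vapply(seq_len(nrow(all_sites)),
                     function(i) count_one(all_sites[i, , drop = FALSE]),
                     numeric(20)))
  na <- nrow(sites_a)
  n <- nrow(all_sites)
  stat_for <- function(idx_a) {
    ca <- colSums(counts[idx_a, , drop = FALSE])
    cb <- colSums(counts[-idx_a, , drop = FALSE])
    abs(100 * ca / sum(ca) - 100 * cb / sum(cb))
  }
  obs <- stat_for(seq_len(na))
  assignments <- utils::combn(n, na, simplify = FALSE)
  stats <- t(vapply(assignments, stat_for, numeric(20)))
  colMeans(stats >= rep(obs, each = nrow(stats)) - 1e-12)
}

# One-sided (enrichment) Fisher p by direct enumeration of the
# hypergeometric tail for the 2x2 table with cells
# [a, b; c, d] and fixed margins.
hypergeom_tail_p <- function(a, b, c, d) {
  row1 <- a + b; col1 <- a + c; n <- a + b + c + d
  xs <- max(0, col1 + row1 - n):min(row1, col1)
  xs <- xs[xs >= a]
  sum(dhyper(xs, col1, n - col1, row1))
}

# Build a deterministic conservation scenario: `n_sites` query sites on
# identical ortholog pairs, of which the first `n_conserved` are
# phosphorylated in the target. Exercises the full mapping machinery.
build_overlap_scenario <- function(n_sites, n_conserved,
                                   sites_per_protein = 2) {
  n_prot <- ceiling(n_sites / sites_per_protein)
  seqs <- setNames(rep(strrep("ACDEFGHIKYLMNPQRSTVWYAAYKL", 2), n_prot),
                   sprintf("q%04d", seq_len(n_prot)))
  y_pos <- which(strsplit(seqs[[1]], "")[[1]] == "Y")
  stopifnot(length(y_pos) >= sites_per_protein)
  qs <- do.call(rbind, lapply(seq_len(n_prot), function(i) {
    data.frame(protein_id = names(seqs)[i],
               position = y_pos[seq_len(sites_per_protein)],
               residue = "Y", stringsAsFactors = FALSE)
  }))[seq_len(n_sites), ]
  tgt_ids <- sub("^q", "t", names(seqs))
  orth <- data.frame(query_id = names(seqs), target_id = tgt_ids,
                     stringsAsFactors = FALSE)
  alns <- lapply(seq_len(n_prot), function(i) {
    aligned_pair(names(seqs)[i], tgt_ids[i], seqs[[i]], seqs[[i]])
  })
  tsites <- qs[seq_len(n_conserved), , drop = FALSE]
  tsites$protein_id <- sub("^q", "t", tsites$protein_id)
  list(query_sites = qs, target_sites = tsites, orthologs = orth,
       alignments = alns)
}
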