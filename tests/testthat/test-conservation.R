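test_that("global alignment matches small hand-computed cases", {
  # identical sequences align without gaps at the diagonal score
  pair <- align_pair("MKSY", "MKSY")
  expect_equal(pair$query_row, "MKSY")
  expect_equal(pair$target_row, "MKSY")
  # BLOSUM62 diagonal: M 5, K 5, S 4, Y 7
  expect_equal(pair$score, 5 + 5 + 4 + 7)

  # one-gap case verified against the 3x4 dynamic-programming table
  pair2 <- align_pair("MKY", "MKAY")
  expect_equal(pair2$query_row, "MK-Y")
  expect_equal(pair2$target_row, "MKAY")

  expect_error(align_pair("", "MKY"), "empty")
  expect_error(align_pair("MKZ1", "MKY"), "non-amino-acid")
})

test_that("site mapping through alignment columns", {
  # identical sequences: every site maps to itself
  pair <- aligned_pair("q", "t", "MKSYT", "MKSYT")
  tsites <- data.frame(protein_id = "t", position = 4, residue = "Y")
  m <- map_site(list(protein_id = "q", position = 4, residue = "Y"),
                pair, tsites)
  expect_equal(m$status, "conserved")
  expect_equal(m$target_position, 4)

  # gapped query row: S at query position 3 sits in column 4 ->
  # target position 4
  pair2 <- aligned_pair("q", "t", "MK-SY", "MKASY")
  m2 <- map_site(list(protein_id = "q", position = 3, residue = "S"),
                 pair2, tsites[0, ])
  expect_equal(m2$target_position, 4)
  expect_equal(m2$status, "aligned_not_phosphorylated")
  m3 <- map_site(list(protein_id = "q", position = 3, residue = "S"),
                 pair2,
                 data.frame(protein_id = "t", position = 4, residue = "S"))
  expect_equal(m3$status, "conserved")

  # strict residue mode requires the same letter
  m4 <- map_site(list(protein_id = "q", position = 3, residue = "S"),
                 pair2,
                 data.frame(protein_id = "t", position = 4, residue = "T"),
                 strict_residue = TRUE)
  expect_equal(m4$status, "aligned_not_phosphorylated")

  # gap in the target at the site column
  pair3 <- aligned_pair("q", "t", "MKSY", "MK-Y")
  m5 <- map_site(list(protein_id = "q", position = 3, residue = "S"),
                 pair3, tsites)
  expect_equal(m5$status, "gap_in_target")

  expect_error(map_site(list(protein_id = "q", position = 9, residue = "S"),
                        pair3, tsites), "exceeds")
})

test_that("mapping through an alignment and back returns the original position", {
  set.seed(13)
  prot <- generate_proteome(5, 60, seed = 14)
  truth <- generate_phosphoproteome(prot, 0.5, seed = 15)
  sim <- generate_ortholog_pair(truth, 0.3, 0.05, 1, seed = 16)
  for (pair in sim$alignments[1:3]) {
    flipped <- aligned_pair(pair$target_id, pair$query_id,
                            pair$target_row, pair$query_row)
    q <- strsplit(pair$query_row, "")[[1]]
    t <- strsplit(pair$target_row, "")[[1]]
    cols <- which(q != "-" & t != "-")
    for (col in sample(cols, min(5, length(cols)))) {
      qpos <- sum(q[1:col] != "-")
      fwd <- map_site(list(protein_id = pair$query_id, position = qpos,
                           residue = "S"), pair,
                      data.frame(protein_id = character(0),
                                 position = integer(0),
                                 residue = character(0)))
      back <- map_site(list(protein_id = pair$target_id,
                            position = fwd$target_position,
                            residue = "S"), flipped,
                       data.frame(protein_id = character(0),
                                  position = integer(0),
                                  residue = character(0)))
      expect_equal(back$target_position, qpos)
    }
  }
})

test_that("cross-species overlap counts every query site in the denominator", {
  qs <- make_site_set(5)
  empty_orth <- data.frame(query_id = character(0), target_id = character(0))
  res <- cross_species_overlap(qs, qs, empty_orth, list())
  expect_equal(res$fraction_conserved, 0)
  expect_true(all(res$mappings$status == "no_ortholog"))

  sc <- build_overlap_scenario(20, 6)
  res2 <- cross_species_overlap(sc$query_sites, sc$target_sites,
                                sc$orthologs, sc$alignments)
  expect_equal(res2$n_conserved, 6)
  expect_equal(res2$fraction_conserved, 6 / 20)

  # invariant under permutation of query input order
  perm <- sample(nrow(sc$query_sites))
  res3 <- cross_species_overlap(sc$query_sites[perm, ], sc$target_sites,
                                sc$orthologs, sc$alignments)
  expect_equal(res3$n_conserved, res2$n_conserved)
  expect_equal(res3$fraction_conserved, res2$fraction_conserved)

  # missing alignment degrades to no_alignment, still in the denominator
  res4 <- cross_species_overlap(sc$query_sites, sc$target_sites,
                                sc$orthologs, sc$alignments[-1])
  expect_true(any(res4$mappings$status == "no_alignment"))
  expect_equal(res4$n_query_sites, 20)
})

test_that("category enrichment Fisher test matches the hypergeometric oracle", {
  # published-style counts: 9 conserved (7 in kinases) of 268 (25 in kinases)
  ce <- category_enrichment_counts(268, 25, 9, 7)
  expect_lt(ce$p_value, 1e-06)
  expect_equal(ce$p_value, hypergeom_tail_p(7, 2, 18, 241),
               tolerance = 1e-12)

  # category covering all sites is degenerate
  sc <- build_overlap_scenario(10, 3)
  res <- cross_species_overlap(sc$query_sites, sc$target_sites,
                               sc$orthologs, sc$alignments)
  expect_warning(all_cat <- category_enrichment(
    res, unique(sc$query_sites$protein_id)), "degenerate")
  expect_equal(all_cat$p_value, 1)

  # exhaustive agreement for all tables with N <= 30
  set.seed(17)
  for (i in 1:60) {
    N <- sample(2:30, 1)
    ncons <- sample(0:N, 1)
    ncat <- sample(0:N, 1)
    ncc <- sample(max(0, ncons + ncat - N):min(ncons, ncat), 1)
    tab_ok <- ncons > 0 && ncons < N && ncat > 0 && ncat < N
    if (!tab_ok) next
    ce2 <- category_enrichment_counts(N, ncat, ncons, ncc)
    oracle <- hypergeom_tail_p(ncc, ncons - ncc, ncat - ncc,
                               N - ncons - ncat + ncc)
    expect_equal(ce2$p_value, oracle, tolerance = 1e-12)
  }

  expect_error(category_enrichment_counts(10, 3, 2, 5), "inconsistent")
})
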