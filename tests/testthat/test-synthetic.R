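test_that("proteome generator honours composition and is reproducible", {
  single <- generate_proteome(1, 30, aa_frequencies = setNames(
    c(1, rep(0, 19)), phossat:::AA20), seed = 1)
  expect_true(grepl("^A+$", single[[1]]))
  expect_gte(nchar(single[[1]]), 20)

  p1 <- generate_proteome(20, 150, seed = 2)
  p2 <- generate_proteome(20, 150, seed = 2)
  expect_identical(p1, p2)

  # letter frequencies recovered within 3 SE over ~1e5 residues
  big <- generate_proteome(350, 300, seed = 3)
  chars <- strsplit(paste(big, collapse = ""), "")[[1]]
  n <- length(chars)
  expect_gt(n, 9e4)
  freq <- table(factor(chars, levels = phossat:::AA20)) / n
  expected <- phossat:::AA_BACKGROUND[phossat:::AA20]
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) < 3.5 * se))

  expect_error(generate_proteome(0), "n_proteins")
  expect_error(generate_proteome(5, 100, aa_frequencies = c(A = 1)),
               "20 standard")
})

test_that("phosphoproteome generator selects S/T/Y sites binomially", {
  prot <- generate_proteome(30, 200, seed = 4)
  # limiting case: every S/T/Y is a site
  all_sites <- generate_phosphoproteome(prot, 1, seed = 5)
  sty <- sum(vapply(strsplit(prot, ""), function(ch)
    sum(ch %in% c("S", "T", "Y")), numeric(1)))
  expect_equal(nrow(all_sites$true_sites), sty)
  expect_true(all(all_sites$true_sites$residue %in% c("S", "T", "Y")))

  # dispersion 0 gives homogeneous weights
  flat <- generate_phosphoproteome(prot, 1, weight_dispersion = 0, seed = 5)
  expect_true(all(flat$detection_weight == flat$detection_weight[1]))

  # realized count within 3 SE of the binomial expectation
  frac <- 0.3
  truth <- generate_phosphoproteome(prot, frac, seed = 6)
  se <- sqrt(sty * frac * (1 - frac))
  expect_lt(abs(nrow(truth$true_sites) - sty * frac), 3.5 * se)

  # sites agree with the proteome letters
  with(truth$true_sites, {
    letters_at <- unname(substring(prot[protein_id], position, position))
    expect_equal(letters_at, residue)
  })

  expect_error(generate_phosphoproteome(prot, 0), "site_fraction")
  expect_error(generate_phosphoproteome(c(x = "AAAA"), 0.5), "S/T/Y")
})

test_that("simulated experiments respect the enrichment profile", {
  prot <- generate_proteome(40, 200, seed = 7)
  truth <- generate_phosphoproteome(prot, 0.3, seed = 8)

  # tyrosine-only profile never yields S/T sites
  yp <- enrichment_profile(residue_selectivity = c(S = 0, T = 0, Y = 1),
                           depth = 200)
  ds <- simulate_experiment(truth, yp, "anti_yp", seed = 9)
  expect_true(all(unique_sites(ds)$residue == "Y"))

  # saturating depth observes every selectable site (homogeneous weights)
  flat <- generate_phosphoproteome(prot, 0.3, weight_dispersion = 0,
                                   seed = 8)
  deep <- enrichment_profile(depth = 50 * nrow(flat$true_sites))
  full <- simulate_experiment(flat, deep, "deep", seed = 10)
  expect_equal(nrow(unique_sites(full)), nrow(flat$true_sites))

  # observations are deduplicated per source
  expect_lte(pool_size(ds), 200)
  expect_equal(anyDuplicated(with(ds$observations,
                                  paste(protein_id, position, residue))), 0)

  # same seed, same dataset
  expect_identical(simulate_experiment(truth, yp, "a", seed = 11),
                   simulate_experiment(truth, yp, "a", seed = 11))

  y_only_truth <- truth
  keep <- truth$true_sites$residue != "Y"
  y_only_truth$true_sites <- truth$true_sites[keep, ]
  y_only_truth$detection_weight <- truth$detection_weight[keep]
  expect_error(simulate_experiment(y_only_truth, yp, "x"), "selectable")
})

test_that("acidic flank bias shifts sampled flank composition toward D/E", {
  prot <- generate_proteome(60, 250, seed = 12)
  truth <- generate_phosphoproteome(prot, 0.3, weight_dispersion = 0.5,
                                    seed = 13)
  truth_fp <- flank_composition(truth$true_sites, prot)
  truth_de <- sum(truth_fp$prevalence[c("D", "E")])
  hits <- vapply(1:20, function(s) {
    biased <- simulate_experiment(
      truth, enrichment_profile(flank_bias = c(D = 0.8, E = 0.8),
                                depth = 300),
      "tio2", seed = 100 + s)
    fp <- flank_composition(unique_sites(biased), prot)
    sum(fp$prevalence[c("D", "E")]) > truth_de
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ortholog simulation keeps its promises", {
  prot <- generate_proteome(12, 120, seed = 14)
  truth <- generate_phosphoproteome(prot, 0.4, seed = 15)

  # no divergence, full conservation: identical proteomes
  clean <- generate_ortholog_pair(truth, 0, 0, 1, seed = 16)
  expect_equal(unname(clean$target_proteome), unname(prot))
  expect_true(all(clean$conserved))
  res <- cross_species_overlap(truth$true_sites, clean$target_sites,
                               clean$orthologs, clean$alignments)
  expect_equal(res$fraction_conserved, 1)

  # zero conservation probability: nothing conserved
  none <- generate_ortholog_pair(truth, 0.2, 0.02, 0, seed = 17)
  res0 <- cross_species_overlap(truth$true_sites, none$target_sites,
                                none$orthologs, none$alignments)
  expect_equal(res0$fraction_conserved, 0)

  # alignment rows reproduce both proteomes when gaps are removed
  div <- generate_ortholog_pair(truth, 0.3, 0.05, 0.5, seed = 18)
  for (pair in div$alignments) {
    expect_equal(gsub("-", "", pair$query_row),
                 unname(prot[pair$query_id]))
    expect_equal(gsub("-", "", pair$target_row),
                 unname(div$target_proteome[pair$target_id]))
  }
  # target sites carry the query residue letter at the mapped position
  ts <- div$target_sites
  expect_equal(unname(substring(div$target_proteome[ts$protein_id],
                                ts$position, ts$position)),
               ts$residue)

  expect_identical(generate_ortholog_pair(truth, 0.3, 0.05, 0.5, seed = 18),
                   div)
})
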