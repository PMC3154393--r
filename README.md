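# phossat

Saturation, richness, enrichment-bias and cross-species conservation
analysis of phosphoproteomics datasets.

High-throughput MS phosphoproteomics never sees a complete
phosphoproteome: sites are lost at every workflow step, and different
phosphopeptide enrichment chemistries (anti-phosphotyrosine antibodies,
TiO2, IMAC) each capture their own biased slice of it. For anyone doing
comparative analysis — across replicates, techniques, conditions or
species — this raises two questions this package answers
quantitatively: *how complete is a dataset*, and *how much of the
(lack of) overlap between datasets is technique, not biology*.

## What it computes

Let a dataset be a multiset of site observations, where the
multiplicity m_s of site s is the number of sources (replicates or
publications) reporting it, N = Σ m_s the observation pool size, and U
the number of unique sites.

* **Saturation**: exact replicate-subset union curves
  (`replicate_saturation()`); pooled-draw rarefaction curves averaged
  over random permutations of the pool (`pooled_rarefaction()`), whose
  mean satisfies E[U(k)] = U − Σ_s C(N−m_s, k)/C(N, k); tail novelty
  (`tail_novelty()`); matched-draw comparisons between pools with a
  permutation p-value (`matched_unique_comparison()`).
* **Richness**: the Chao1 lower-bound estimator
  S_Chao1 = S_obs + f1²/(2 f2) with the standard bias-corrected
  fallback at f2 = 0 (`chao1()`), and a jackknife consistency
  diagnostic that detects the detection-probability heterogeneity under
  which Chao1 systematically underestimates
  (`jackknife_consistency()`).
* **Enrichment bias**: flanking amino-acid composition in the ±5
  window (`flank_composition()`); a group-label randomization test per
  residue with Bonferroni correction
  (`composition_randomization_test()`); the common-reference correction
  factor (frac_A in reference)/(frac_B in reference)
  (`common_reference_correction()`); GO-slim-style category fold
  enrichment log2(k/n) − log2(K/N) with one-sided Fisher tests and BH
  correction (`term_enrichment()`).
* **Conservation**: mapping of phosphosites between species through
  ortholog tables and pairwise alignments (`map_site()`,
  `cross_species_overlap()`), a built-in BLOSUM62 global aligner for
  self-contained use (`align_pair()`), and Fisher enrichment of protein
  categories in the conserved fraction (`category_enrichment()`).
* **Synthetic ground truth**: generators for proteomes,
  phosphoproteomes with tunable detection heterogeneity, biased
  enrichment experiments and diverged ortholog pairs with a controlled
  conservation rate (`generate_proteome()`,
  `generate_phosphoproteome()`, `simulate_experiment()`,
  `generate_ortholog_pair()`), so every analysis validates as a
  round trip.

Inputs are plain files: TSV site tables (`protein_id`, `position`,
`residue`, `source_id`), FASTA proteomes, aligned FASTA pairs, and
two-column ortholog/annotation TSVs. A command-line entry point
(`inst/cli/phossat`, or `phossat::run()` from R) exposes the analyses
as `saturate`, `richness`, `bias`, `conserve` and `simulate`
subcommands with seeds recorded in a JSON run manifest.

## Worked example

```r
library(phossat)

proteome <- generate_proteome(n_proteins = 50, mean_length = 250, seed = 7)
truth <- generate_phosphoproteome(proteome, site_fraction = 0.2,
                                  weight_dispersion = 1.5, seed = 8)
ds <- simulate_replicates(truth, enrichment_profile(depth = 250),
                          n_sources = 5, seed = 9)
ds
#> Phosphosite dataset: 180 unique sites, 456 observations, 5 source(s)
#> Multiplicity: min 1 / median 2 / max 5

chao1(ds)
#> Chao1 (classic): 240.4 estimated sites (observed 180; f1 = 65, f2 = 35)

jackknife_consistency(ds, fraction = 0.5, n_repeats = 100, seed = 10)
#> Jackknife Chao1 at fraction 0.50: mean 201.1 (sd 20.4) vs full-data 240.4 over 100 repeats
#>   subset estimates are systematically lower: detection heterogeneity likely
```

The truth here held 255 sites with strongly heterogeneous detection
weights (log-normal, sdlog 1.5). Chao1 underestimates (240 < 255), and
the half-data jackknife mean (201) sits well below the full-data
estimate — the signature that the estimator's equal-detectability
assumption is violated and its value is only a lower bound that will
keep growing with more data. With `weight_dispersion = 0` the same
pipeline recovers the true site count to within a few percent.

```r
curve <- pooled_rarefaction(ds, n_repeats = 100, seed = 11)
tail_novelty(curve, 0.10)$percent_increase
#> [1] 4.1      # % new sites in the final 10% of draws (11.1% if unsaturated)

sim <- generate_ortholog_pair(truth, substitution_rate = 0.2,
                              indel_rate = 0.02, conservation_prob = 0.3,
                              seed = 12)
cross_species_overlap(truth$true_sites, sim$target_sites,
                      sim$orthologs, sim$alignments)
#> Cross-species overlap: 77 of 255 query sites conserved (30.2%)
```

The mapped conservation fraction (30.2%) recovers the simulated
per-site conservation probability of 0.3.

## Documentation

The methods vignette
(`vignettes/phosphoproteome-completeness.Rmd`) describes the models,
their assumptions, the synthetic generator's scope and the numerical
design choices; every exported function has full help.
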