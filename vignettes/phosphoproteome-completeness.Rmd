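---
title: "Assessing completeness and enrichment bias in phosphoproteomics datasets"
author: "phossat"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Assessing completeness and enrichment bias in phosphoproteomics datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phossat)
```

## The problem

High-throughput phosphoproteomics never observes a complete
phosphoproteome. Phosphosites are lost at every step of the workflow —
lysis, digestion, phosphopeptide enrichment, chromatography, MS
identification — and different enrichment chemistries (antibody-based
anti-phosphotyrosine purification, TiO2 affinity, IMAC) each select
their own, partially overlapping slice of the site inventory. Two
consequences matter for comparative analysis. First, a site observed in
one dataset but not another may reflect biology or may simply be missing
data; second, the observed overlap between two datasets confounds
incompleteness with technique bias. `phossat` implements a set of
statistics that quantify both effects and a synthetic-data generator
that lets every statistic be validated against a known ground truth.

The unit of analysis throughout is the *site observation*: one
phosphosite (protein, 1-based position, S/T/Y residue) reported by one
*source*, where a source is a technical replicate or a publication. A
dataset is a multiset of such observations; the number of distinct
sources reporting a site is its *multiplicity*, and the multiplicity
distribution is the input to all saturation and richness analysis. A
site is counted at most once per source: neither replicate site lists
nor publication-derived databases carry meaningful within-source
recurrence, so duplicated (site, source) rows are collapsed on input.
How multiply-phosphorylated peptides were collapsed into site-level
observations upstream of the site table is outside the model; the site
table is taken at face value.

## Saturation analysis

Two complementary views are provided.

`replicate_saturation()` is exact: for R replicates it enumerates every
k-subset (k = 1..R) and reports the union size of each, so with four
replicates there are 4, 6, 4 and 1 subsets at k = 1..4. A flat profile
means additional replicates stop contributing new sites. Enumeration is
capped at R = 20.

`pooled_rarefaction()` handles datasets whose sources are heterogeneous
(e.g. a database pooling hundreds of publications). The observation
pool holds one entry per (site, source) observation; each of
`n_repeats` rounds permutes the pool uniformly and draws it to
exhaustion without replacement, recording unique sites discovered so
far. Draws are without replacement — the curve must reach (1, 1) when
the pool is exhausted — and averaging is over full permutations rather
than independent subsamples per grid point, so a single pass yields the
whole trajectory. Curves are evaluated every `ceiling(pool_size/grid)`
draws (default grid 100; exact per-draw evaluation for pools of at most
100 observations) to keep large pools tractable. The x-axis counts
*draws* (observations), not distinct sites. With every multiplicity
equal to 1 the curve is exactly the diagonal; any repeated observation
lifts it above. The averaged curve matches the closed form
E[U(k)] = U − Σ_s C(N − m_s, k)/C(N, k), which the test suite checks by
enumeration on small pools.

`tail_novelty()` summarises a curve as the relative gain in unique
sites over the final fraction of draws (default 10%); an unsaturated
(diagonal) dataset gives 100·(0.1/0.9) ≈ 11.1%, a saturated one gives
0%. `matched_unique_comparison()` draws the same number of observations
from two pools and compares mean unique counts; the p-value is the
one-sided add-one permutation estimate of how often the comparison pool
looks at least as saturated as the focal pool's mean. This construction
concentrates near 0.5 for identical pools (it compares against a mean,
not a paired draw), so it should be read as a significance measure for
a *directional* saturation difference, not as a calibrated uniform
p-value under the null. The default of 1000 trials resolves p-values
down to about 0.001.

## Richness estimation and its failure mode

`chao1()` treats sites as species and multiplicities as abundances:
with S_obs observed sites, f1 singletons and f2 doubletons, the classic
estimate is S_obs + f1²/(2·f2), falling back to the bias-corrected form
S_obs + f1(f1−1)/(2(f2+1)) when f2 = 0 (the variant used is recorded in
the result). The estimator assumes every site is equally detectable.

`jackknife_consistency()` probes that assumption by recomputing Chao1
on random subsets of *observations* (floor(fraction · pool_size) of
them; subsampling unique sites instead would destroy the multiplicity
distribution the estimator needs). Under homogeneous detection the
subset estimates converge to the full-data estimate — from slightly
above, because the f1²/(2f2) correction is convex and therefore biased
upward in small samples — and never fall systematically below it. Under
heterogeneous detection (some sites vastly easier to observe than
others) the subset estimates sit *below* the full-data estimate: the
estimate grows with sampling effort, revealing that the full-data value
is only a lower bound, not an inventory size. The package's synthetic
round trip reproduces both regimes (see below). Defaults are fraction
0.5 and 100 repeats.

## Enrichment bias

`flank_composition()` measures amino-acid prevalence in the ±5-residue
window around each site (truncated at protein termini; the central
phosphorylated residue is never counted), pooled over all sites of a
set — one prevalence per residue per strategy, matching how such
comparisons are tabulated. `composition_randomization_test()` compares
two site sets residue by residue with the absolute prevalence
difference as statistic; the null reassigns sites to groups at random
with group sizes fixed (default 10000 permutations), p-values use the
add-one estimator (avoiding p = 0), and Bonferroni correction runs over
the residues actually observed in the pooled flanks (at most 20). The
statistic is two-sided because both enrichments and depletions are of
interest. Internally the pooled per-site count rows are put in a
canonical order and the smaller group size is sampled, which makes the
result exactly symmetric in the two inputs at a fixed seed.

`common_reference_correction()` quantifies technique bias directly:
each dataset's fraction of sites present in a large common reference is
computed, and the ratio of the two fractions estimates the
multiplicative correction to apply to an observed between-technique
overlap. All three site collections must already live on one proteome
identifier space; reconciling isoform or assembly differences between
datasets is the caller's responsibility.

`term_enrichment()` reports, per annotation term, the fold increase
log2(k/n) − log2(K/N) of a term among n phosphoproteins (k annotated)
relative to the N-protein proteome (K annotated), with one-sided Fisher
exact p-values and Benjamini–Hochberg adjustment across terms. Terms
with no proteome members are skipped with a log message; a term with
k = 0 yields fold −Inf, which is reported as such rather than clipped.

## Cross-species conservation

A query site is *conserved* when a pairwise alignment of its protein
with an ortholog places it in the same column as a residue that is
itself phosphorylated in the target dataset. `map_site()` performs the
column arithmetic on ungapped 1-based coordinates;
`cross_species_overlap()` aggregates over a whole dataset, with
statuses `no_ortholog`, `no_alignment`, `gap_in_target`,
`aligned_not_phosphorylated`, `conserved`. Three conventions matter:

* the denominator of the conserved fraction is *all* query sites,
  including those without orthologs or alignments;
* any phosphosite at the aligned position counts regardless of S/T/Y
  identity (`strict_residue = TRUE` restores letter matching);
* with many-to-many ortholog tables a site is mapped through every
  listed ortholog and called conserved if any mapping succeeds.

`category_enrichment()` tests overrepresentation of a protein category
(canonically: kinases) among conserved sites with a one-sided Fisher
exact test on the site-level 2×2 table; `category_enrichment_counts()`
accepts published marginal counts directly, since published totals do
not always correspond to a site table one can recompute from.

`align_pair()` provides global Needleman–Wunsch alignment (BLOSUM62,
gap open 10 / extend 1, via Biostrings) so tests and small analyses are
self-contained; externally computed alignments (e.g. Muscle) are
preferred for real data and simply take precedence when supplied.

## The synthetic-data generator

The generator produces data whose true parameters are known, so each
analysis can be validated as a round trip:

* `generate_proteome()` — i.i.d. sequences from a realistic average
  amino-acid composition; lengths geometric around `mean_length`
  (minimum 20).
* `generate_phosphoproteome()` — every S/T/Y position becomes a true
  site independently with probability `site_fraction`; detection
  weights are i.i.d. log-normal with `sdlog = weight_dispersion`.
  Dispersion 0 is the homogeneous, Chao1-consistent regime; dispersion
  around 2 produces the strong heterogeneity that drives systematic
  Chao1 underestimation. The log-normal was chosen as the smallest
  model with a single heterogeneity knob; it is not a mechanistic
  abundance model.
* `simulate_experiment()` — draws `depth` observations with probability
  proportional to detection weight × residue selectivity ×
  exp(flank-bias score over the ±5 window), then keeps each site at
  most once per source. Depth therefore controls saturation directly.
  An anti-phosphotyrosine-like strategy is `residue_selectivity =
  c(S = 0, T = 0, Y = 1)`; a TiO2-like acidic preference is
  `flank_bias = c(D = 1, E = 1)`.
* `generate_ortholog_pair()` — copies each protein with point
  substitutions and short (1–3 residue) indels; each true site is
  retained in the target species with probability `conservation_prob`,
  and retained sites are protected from substitution and deletion. The
  *true* alignments are emitted by construction, so conservation
  round trips are exact and do not depend on aligner quality; the
  built-in aligner is exercised by its own tests.

What the generator does **not** emulate: peptide-level effects
(digestion, missed cleavages, co-eluting multiply-phosphorylated
peptides), spectral identification error and FDR, correlated detection
between neighbouring sites, and realistic protein family structure.
Passing round trips therefore demonstrate the statistics are computed
correctly and are sensitive to the effects they target — not that real
datasets satisfy the generators' independence assumptions. An optional
false-site injection knob was considered and deliberately left out: no
defensible default rate exists, and a false-positive process is easy to
emulate by appending fabricated singleton sites to a dataset.

## Numerical and design choices

* Randomness: every stochastic function takes an explicit `seed` and
  restores the caller's RNG state; identical seeds give bit-identical
  results.
* Validation: a site whose residue letter disagrees with the attached
  proteome is a hard error by default — silent coordinate slippage is a
  classic source of irreproducible site counts — with `lenient = TRUE`
  downgrading to drop-and-warn.
* Permutation p-values use (1 + exceedances)/(1 + permutations), and
  exceedance comparisons use a 1e-12 slack so that a zero observed
  difference yields p = 1 rather than depending on floating-point
  noise.
* Degenerate 2×2 margins in `category_enrichment()` return p = 1 with a
  warning instead of erroring, since empty categories arise routinely
  in small studies.
* `tail_novelty()` interpolates the averaged curve linearly between
  grid points; on pools of at most 100 observations the curve is exact
  per draw and no interpolation error arises.

Problem sizes in the shipped validation suite were chosen so that every
stochastic check has comfortable statistical margin at desk scale:
rarefaction oracles on pools of up to 12 observations with 3000
repeats; Chao1 recovery on ~500-site truths over 50 studies (within 15%
on average, and in practice within ~1%); randomization-test calibration
over 200 null splits of 80 sites; bias detection at group sizes above
300; conservation recovery over ~600 sites against a 3-binomial-SE
band.

## Limitations

Chao1 is the only richness estimator provided, used here as a
diagnostic of dataset incompleteness rather than a trustworthy
inventory size — which is precisely the conclusion its jackknife
failure mode supports. No curve fitting or extrapolation of saturation
curves is offered: the fitted functional form would determine the
asymptote, making any extrapolated total an artifact of that choice.
Orthology inference and multiple sequence alignment are consumed as
data, never computed. Position reconciliation across proteome versions
is out of scope; all inputs must share identifier spaces.
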