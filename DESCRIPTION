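Package: phossat
Title: Saturation, Richness, Bias and Conservation Analysis for Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the completeness of phosphoproteomics
    datasets and the biases introduced by phosphopeptide enrichment
    strategies. Implements replicate and pooled-draw saturation
    (rarefaction) analysis of phosphosite observation tables, Chao1
    richness estimation of the phosphoproteome with a jackknife
    consistency diagnostic, flanking amino-acid composition comparison
    between enrichment strategies with a randomization test, a
    common-reference correction for technique-induced overlap loss,
    category (e.g. GO slim) fold-enrichment statistics, and
    ortholog/alignment-based mapping of phosphosites between species with
    Fisher exact enrichment of the conserved fraction. A synthetic-data
    generator produces proteomes, phosphoproteomes, biased experiments
    and diverged ortholog pairs with known ground truth, so every
    analysis stage can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
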