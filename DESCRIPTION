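Package: posscreen
Title: Genome-Wide Branch-Site Positive-Selection Screening with
    Alignment-Quality and cDNA Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects episodic positive selection on designated foreground
    lineages with the branch-site codon model (modified Model A), including
    likelihood-ratio testing against the omega2 = 1 null, Benjamini-Hochberg
    false-discovery-rate control across genes, and Bayes Empirical Bayes
    identification of selected sites. Candidate sites are then screened by
    two false-positive filters: sum-of-pairs penalty scoring of +/-15-residue
    alignment windows around each site, and validation of the site codon
    against independently sequenced cDNA fragments. Ships a codon-sequence
    simulator (GY94 substitution process with Model A site classes and a
    foreground branch), alignment-corruption operators emulating
    misalignment, sequencing and annotation error, and generators for cDNA
    fragments and proteome sets, so the whole screen is testable without
    genome downloads. Includes reciprocal-best-hit one-to-one ortholog
    calling with an identity floor and longest-transcript selection.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
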