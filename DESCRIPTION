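Package: phyloburst
Title: Detection of Bursts of Amino Acid Replacements on Short Phylogenetic Edges
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects episodes of rapid protein evolution ("bursts") in which
    several amino acid replacements accumulate in a single gene within a very
    short internal edge of a phylogenetic tree. Implements Nei-Gojobori (1986)
    synonymous/non-synonymous site counting and substitution classification,
    marginal ancestral codon reconstruction under a reversible codon model via
    the pruning algorithm, a Poisson test of non-synonymous substitution counts
    against a neutral expectation scaled by edge length in dS units, with
    Benjamini-Hochberg correction and alignment-quality filters, a synonymous
    burst negative control, a synthetic codon-evolution generator with
    ground-truth substitution records for validation, and small
    population-genetic calculators for interpreting detected bursts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings
Config/testthat/edition: 3
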