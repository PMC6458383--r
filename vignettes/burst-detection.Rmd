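---
title: "Detecting bursts of amino acid replacements on short phylogenetic edges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bursts of amino acid replacements on short phylogenetic edges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyloburst)
```

## The problem

Protein evolution can proceed gradually or through episodes in which many
amino acid replacements accumulate in one gene over a very short time — a
*burst*. Detecting a burst requires a time interval short enough that an
excess of changes within it is statistically surprising. Phylogenies of
densely sampled, closely related species (for example lake species flocks,
or primate clades in whole-genome alignments) contain very short *internal*
edges — segments ancestral to more than one extant species — that provide
such intervals. Restricting attention to internal edges also protects
against sequencing and alignment artefacts: a derived state shared by
several species cannot be a single bad read.

`phyloburst` implements this scan end to end: edge-run enumeration,
ancestral codon reconstruction, substitution mapping, the Poisson burst
test with multiple-testing control and quality filters, a synonymous
negative control, a synthetic codon-evolution generator for validation,
and small population-genetic calculators for interpreting hits.

## The statistic

Time on the tree is measured in dS units: expected synonymous substitutions
per synonymous site, the neutral clock. For a gene $g$ and a run $R$ of one
or two consecutive internal edges with combined length $\mathrm{dS}(R) <
0.005$, the number $k$ of non-synonymous substitutions mapped onto $R$ is
compared with the neutral (dN = dS) expectation

$$\lambda = \mathrm{dS}(R) \cdot N_g,$$

where $N_g$ is the gene's Nei–Gojobori non-synonymous site count. The
p-value is the upper Poisson tail $P(X \ge k)$, $X \sim
\mathrm{Poisson}(\lambda)$, and all gene × run tests in a scan form one
Benjamini–Hochberg family. Two points matter:

* **Edge lengths are pooled.** A single gene carries on the order of one
  synonymous substitution on a 0.005 dS edge, so per-gene edge lengths are
  hopelessly noisy. $\mathrm{dS}(R)$ is instead estimated from the
  synonymous substitutions of *all* genes on the run, divided by the summed
  synonymous site count, with a Jukes–Cantor correction.
* **Fractional counts are floored.** Multi-nucleotide codon changes are
  classified by equal-weight averaging over the orderings of their
  single-nucleotide steps (the unweighted Nei–Gojobori convention), so
  substitution counts can be fractional (e.g. 6.5). The Poisson tail needs
  an integer; the default policy takes the floor, which can only understate
  significance. `round` and `ceiling` are available in `scan_config()`.

Filters mirror a conservative analysis protocol: alignments with more than
50% gap-containing codon columns are excluded (exactly 50% is retained —
exclusion is strict); only gapless columns enter the statistics; sites
whose ancestral reconstruction has MAP posterior below 0.8 at either run
endpoint are removed and the gene's site counts recomputed without them;
and a gene whose own synonymous divergence on the run significantly exceeds
the pooled estimate (BH-adjusted synonymous tail ≤ 0.001) is flagged as a
possible paralogue or pseudogene. The same synonymous tail, thresholded at
the scan's α, doubles as a negative control: a neutral clock should produce
no synonymous bursts, and any such detection raises a warning on the scan.
Filters that require raw sequencing reads or genome annotations
(read-mapping consistency, repeated-domain exclusion, positional
conservation, manual curation) are outside the package's scope and are
listed as pending in the report header.

## Ancestral reconstruction

Substitutions are placed on edges by comparing MAP codons of marginal
ancestral reconstructions at the edge endpoints (a leaf endpoint uses its
observed codon with posterior 1). The reconstruction uses the pruning
algorithm under a reversible 61-state codon model: HKY-style nucleotide
exchangeability with transition/transversion ratio κ (default 2), a
non-synonymous multiplier ω (default 1 — the scan's null), and equal codon
frequencies by default. Because the downstream statistic consumes only
event counts and dS lengths, the reconstruction model does not need to be
finely tuned; any standard codon model serves, and the defaults are
declared rather than estimated.

The generator, the transition matrices and the simulator all share one
branch-length convention: the rate matrix is scaled so that one unit of
branch length yields one expected synonymous substitution per Nei–Gojobori
synonymous site at stationarity. Synonymous rates carry no ω factor, so
this calibration keeps dS meaningful for any ω, and tree edge lengths given
in dS are used directly as evolutionary times. Transition matrices come
from the eigendecomposition of the symmetrized reversible generator
(computed once per model; detailed-balance asymmetry beyond 1e-10 is an
error rather than a silent fallback). MAP ties break towards the
lexicographically smallest codon, making reconstructions deterministic.

Two practical caveats, both visible in the test suite:

* **Root-incident edges are confounded.** For an edge whose parent is the
  root, a substitution can be placed on either root edge; the likelihood
  prefers the longer one. Bursts simulated on a short root-incident edge
  are therefore mapped to its longer sister and missed. This is a property
  of the method (shared with any reconstruction-based mapping), not of the
  implementation; power analyses here inject bursts on short internal
  edges away from the root.
* **Parallel changes merge.** Identical substitutions on the two child
  edges of a node are reconstructed, parsimoniously, as a single event on
  the parent edge. This slightly inflates mapped counts on short internal
  edges; the null scans below show the effect is far too small to produce
  false bursts.

## The synthetic generator

`simulate_alignment()` draws each gene's root sequence from the stationary
codon frequencies and evolves it along every branch by Gillespie event
sampling from the codon model, recording every substitution (gene, edge,
site, from → to codon, synonymy). `inject_burst()` adds k single-nucleotide
non-synonymous changes at distinct sites on a chosen edge, scattered
through the protein as observed bursts are; sites untouched by other
events are used so the derived allele segregates exactly with the edge's
descendant species, and truth replay (`replay_truth()`) verifies
alignment/truth consistency. Burst injection is instantaneous on the edge:
the statistic is blind to within-edge ordering, so ordering is not
modelled.

The `gammarid` preset emulates a densely sampled clade: 10 taxa, 200 genes
of 150–300 codons, and six internal edges below 0.005 dS (0.0007–0.004,
mirroring the range on which real bursts have been reported), including
two consecutive short pairs so that two-edge runs occur. The `primate`
preset has 11 deeper taxa and exactly three short internal edges. Gene
lengths of a few hundred codons and per-clade gene counts in the hundreds
keep every validation suite affordable on a single CPU; these sizes are
stated here once and used throughout the tests.

What the generator does *not* emulate: incomplete lineage sorting, gene
conversion, GC-biased fixation, rate variation among sites and lineages,
alignment error. Passing tests therefore validate the statistical
machinery under its own model assumptions; on real data the posterior
filter, the dS-consistency filter and the external-evidence filters have
to carry the weight of these violations.

## Validation results computed by the test suite

The acceptance tests (in `tests/testthat/test-acceptance.R`) compute:

* **Oracle equivalence.** Pruning likelihoods and marginal posteriors match
  a brute-force enumeration over all joint internal-node states on trees of
  2–5 leaves to a relative error below 1e-10.
* **Type-I error.** Fifty seeded null scans (ω = 1, 200 genes each,
  gammarid preset) must average fewer than 0.05 detected genes per scan at
  α = 0.05 after BH; the synonymous control must be equally silent. The
  Poisson tail's discreteness at small λ makes the test strongly
  conservative here.
* **Detectability.** Bursts of 8 injected non-synonymous substitutions in
  genes of at most 300 codons, placed on short internal edges
  (0.0008–0.0010 dS, the regime of most observed bursts), must be
  recovered in at least 95% of fifty seeded replicates with fewer than
  0.05 false gene discoveries per scan. Detection of a minimal 8-
  substitution burst is genuinely marginal towards the 0.005 dS cap, where
  λ approaches 3; observed bursts on ~0.004 dS edges involved 10–39
  substitutions.
* **Estimator self-consistency.** Pooled edge dS estimates over 100 genes
  recover every nominal preset edge length within three Monte-Carlo
  standard errors.
* **Counting identity.** N + S = 3L exactly for every simulated gene.

The worked population-genetic arithmetic (fixation probability 4·Ne·μ·s,
generations per edge and per substitution, burst rate per protein per dS,
and the binomial enrichment tail) is asserted at its printed precision;
"approximately" figures in prose are one-significant-figure roundings,
implemented in `prose_round()`.

## A worked example

```{r example, eval = FALSE}
tr <- gammarid_tree()
cfg <- generator_config(tr, n_genes = 60, gene_length = c(150, 300),
                        seed = 11,
                        bursts = data.frame(gene = 1, edge = 13, k = 10))
sim <- simulate_alignment(cfg)
scan <- scan_bursts(tr, sim$alignments)
scan
write_burst_report(scan, "report.tsv", dataset = "synthetic clade")
```

## Design decisions and open points

* Edge runs are contiguous descending paths of at most `max_run_edges`
  (default 2) internal edges with combined length strictly below
  `max_edge_ds`; all qualifying sub-paths are enumerated, not only maximal
  ones, since a burst may sit inside a longer chain. Non-adjacent edges are
  never merged.
* All columns are 1-based, in code and reports alike; R indexing makes a
  0-based internal convention a source of bugs rather than clarity.
* The BH family is all gene × run tests of one scan; scanning clades
  separately gives separate families. Whether N sites should be counted
  before or after the posterior-based site exclusion is ambiguous in
  principle; the scan recomputes N after exclusion, which shrinks k and λ
  together and is the conservative reading.
* Unrooted trees are rejected rather than auto-rooted, because the
  direction of ancestral reconstruction must be explicit
  (`parse_newick(rooted = TRUE)` accepts an explicitly rooted
  multifurcation).
* A run whose pooled dS estimate is zero (no synonymous event in any gene —
  only possible at toy dataset sizes) cannot be tested: such gene × run
  pairs get p = NA, are flagged `zero_ds`, never reach significance and are
  excluded from the BH family, rather than degenerating to p = 0.
* The genetic code is the standard nuclear code; a different code would
  change site counts and classifications and is not currently exposed.

## Limitations

The null model is a homogeneous Poisson clock; overdispersion of the
molecular clock, mutation-rate heterogeneity along the genome, and
selection on synonymous sites all violate it, which is why the method is
suited to flagging radical outliers rather than measuring mild rate
variation. Reconstruction-based mapping slightly redistributes events near
the root and merges parallel changes. Maximum-likelihood dN/dS (codeml-
style ω estimation) and joint ancestral reconstruction are out of scope;
the per-gene dN/dS column in reports is the counting-based estimate.
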