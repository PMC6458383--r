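# The burst statistic and the scan pipeline.
#
# For each gene and each short internal edge run, the number of
# non-synonymous substitutions k mapped onto the run is tested against a
# neutral Poisson expectation with mean
#
#     lambda = dS(run) * N(gene),
#
# where dS(run) is the run length in synonymous-substitutions-per-synonymous-
# site units estimated from *all* genes pooled (a single gene carries too few
# synonymous sites to measure a short edge), and N(gene) is the gene's
# Nei-Gojobori non-synonymous site count. Upper-tail p-values over all
# (gene x run) tests are Benjamini-Hochberg adjusted as one family. A
# synonymous-substitution scan with lambda = dS(run) * S(gene) runs alongside
# as a negative control; the same synonymous tail doubles as the per-gene dS
# consistency filter against paralogue/pseudogene contamination.

#' Upper-tail Poisson probability
#'
#' `P(X >= k)` for `X ~ Poisson(lambda)`: the probability of observing this
#' many or more substitutions under the neutral expectation.
#'
#' @param k Non-negative integer count (vectorized).
#' @param lambda Poisson mean (> 0).
#' @return p-value in (0, 1\].
#' @examples
#' poisson_tail(0, 2)    # 1
#' poisson_tail(2, 1)    # 1 - 2/e
#' @export
poisson_tail <- function(k, lambda) {
  if (any(lambda <= 0)) stop("lambda must be > 0", call. = FALSE)
  if (any(k < 0) || any(k != floor(k))) {
    stop("k must be a non-negative integer", call. = FALSE)
  }
  stats::ppois(k - 1, lambda, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order
#' (delegates to [stats::p.adjust()] after validation).
#'
#' @param p Non-empty vector of p-values in \[0, 1\].
#' @return Adjusted p-values, elementwise >= `p` and <= 1.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector", call. = FALSE)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Pooled edge dS estimate
#'
#' Edge length in dS units from all genes jointly: the total synonymous
#' substitution count mapped onto the edge divided by the total synonymous
#' site count, Jukes-Cantor corrected. Individual genes are never used to
#' length a short edge: a single gene's handful of synonymous sites cannot
#' measure dS of order 0.005 with any precision.
#'
#' @param sd_by_gene Synonymous substitutions on the edge, per gene.
#' @param s_by_gene Synonymous site counts, per gene (same order).
#' @return dS estimate (>= 0).
#' @examples
#' estimate_edge_ds(150, 30000)  # 0.005 -> 0.0050167 after JC
#' @export
estimate_edge_ds <- function(sd_by_gene, s_by_gene) {
  stopifnot(length(sd_by_gene) == length(s_by_gene))
  S <- sum(s_by_gene)
  if (S <= 0) stop("zero total synonymous sites", call. = FALSE)
  jc_correct(sum(sd_by_gene) / S)
}

#' Gap filter for alignments
#'
#' Excludes alignments in which more than `max_gap_fraction` of codon columns
#' contain gaps (strictly more than: an alignment at exactly the threshold is
#' retained). Retained alignments are subsequently restricted to gapless
#' columns for all statistics.
#'
#' @param alignments List of `codon_alignment` objects.
#' @param max_gap_fraction Maximum tolerated gap-column fraction
#'   (default 0.5).
#' @return A list with `retained`, `excluded` (both lists of alignments) and
#'   `gap_fraction` (named vector over all inputs).
#' @export
filter_gap_alignments <- function(alignments, max_gap_fraction = 0.5) {
  fr <- vapply(alignments, gap_fraction, numeric(1))
  names(fr) <- vapply(alignments, `[[`, character(1), "gene")
  keep <- fr <= max_gap_fraction
  list(retained = alignments[keep], excluded = alignments[!keep],
       gap_fraction = fr)
}

#' Per-gene dS consistency test
#'
#' Upper-tail Poisson test of a gene's synonymous substitution count on an
#' edge run against the expectation from the pooled edge dS. A gene whose own
#' synonymous divergence on the run significantly exceeds the pooled estimate
#' is suspect (anciently diverged paralogue or pseudogene rather than an
#' orthologue); within a scan the flag is raised when the BH-adjusted p-value
#' drops to `alpha` or below.
#'
#' @param sd_on_run Gene's synonymous substitution count on the run
#'   (fractional counts are floored).
#' @param s_gene Gene's synonymous site count (> 0).
#' @param run_ds Pooled dS length of the run.
#' @param alpha Flag threshold applied to the (here unadjusted) p-value
#'   (default 0.001).
#' @return A list with `p` and `pass` (`TRUE` when the gene is consistent).
#' @export
ds_consistency_test <- function(sd_on_run, s_gene, run_ds, alpha = 0.001) {
  stopifnot(s_gene > 0, run_ds >= 0)
  k <- floor(sd_on_run)
  lambda <- run_ds * s_gene
  p <- if (lambda > 0) poisson_tail(k, lambda) else as.numeric(k == 0)
  list(p = p, pass = p > alpha)
}

#' Scan configuration
#'
#' Bundles the thresholds of the scan pipeline with their defaults.
#'
#' @param max_edge_ds Strict cap on (combined) edge-run length, dS units
#'   (default 0.005).
#' @param min_posterior Minimum ancestral MAP posterior for a site to count
#'   (default 0.8).
#' @param max_gap_fraction Gap-column fraction above which an alignment is
#'   excluded (default 0.5).
#' @param alpha Significance level on BH-adjusted p-values (default 0.05).
#' @param ds_alpha dS-consistency flag level on adjusted synonymous tails
#'   (default 0.001).
#' @param max_run_edges Maximum consecutive edges per run (default 2).
#' @param rounding How fractional substitution counts become the integer k of
#'   the Poisson test: `"floor"` (default, never overstates significance),
#'   `"round"`, or `"ceiling"`.
#' @param kappa,omega Reconstruction model parameters (defaults 2 and 1).
#' @return A `scan_config` list.
#' @export
scan_config <- function(max_edge_ds = 0.005, min_posterior = 0.8,
                        max_gap_fraction = 0.5, alpha = 0.05,
                        ds_alpha = 0.001, max_run_edges = 2L,
                        rounding = c("floor", "round", "ceiling"),
                        kappa = 2, omega = 1) {
  rounding <- match.arg(rounding)
  stopifnot(max_edge_ds > 0, min_posterior >= 0, min_posterior <= 1,
            max_gap_fraction >= 0, max_gap_fraction <= 1,
            alpha > 0, alpha < 1, ds_alpha > 0, ds_alpha < 1,
            max_run_edges >= 1)
  structure(list(
    max_edge_ds = max_edge_ds, min_posterior = min_posterior,
    max_gap_fraction = max_gap_fraction, alpha = alpha,
    ds_alpha = ds_alpha, max_run_edges = as.integer(max_run_edges),
    rounding = rounding, kappa = kappa, omega = omega
  ), class = "scan_config")
}

.round_k <- function(x, rounding) {
  switch(rounding, floor = floor(x), round = round(x), ceiling = ceiling(x))
}

#' Scan a gene set for bursts of non-synonymous substitutions
#'
#' Full pipeline: gap filter, marginal ancestral reconstruction per gene,
#' substitution mapping onto every edge of every short internal run (sites
#' with endpoint MAP posterior below `min_posterior` are dropped and the
#' gene's site counts recomputed without them), pooled edge dS estimation,
#' per (gene x run) Poisson test of the non-synonymous count, BH adjustment
#' over all tests in the scan, and the dS-consistency filter. The identical
#' machinery applied to synonymous counts serves as negative control and is
#' reported separately; any significant synonymous burst raises a warning on
#' the result.
#'
#' @param tree Rooted `phylo` with dS branch lengths.
#' @param alignments List of `codon_alignment` objects (the gene set).
#' @param config A [scan_config()].
#' @return An object of class `burst_scan`: `tests` (all gene x run rows:
#'   counts, `lambda`, `p`, `p_adj`, consistency columns, `significant`),
#'   `candidates` (significant rows passing filters, sorted by adjusted p),
#'   `control` (synonymous scan rows), `edge_ds` (pooled per-edge estimates),
#'   `runs`, `gene_stats`, `excluded_genes`, `config`.
#' @export
scan_bursts <- function(tree, alignments, config = scan_config()) {
  stopifnot(inherits(config, "scan_config"))
  if (!length(alignments)) stop("no alignments supplied", call. = FALSE)

  gf <- filter_gap_alignments(alignments, config$max_gap_fraction)
  alns <- gf$retained
  if (!length(alns)) stop("all alignments excluded by the gap filter", call. = FALSE)

  runs <- enumerate_edge_runs(tree, config$max_edge_ds, config$max_run_edges)
  if (!nrow(runs)) stop("tree has no qualifying internal edge runs", call. = FALSE)
  run_edges <- sort(unique(unlist(runs$edges)))
  all_edges <- seq_len(nrow(tree$edge))

  model <- codon_model(kappa = config$kappa, omega = config$omega)
  engine <- .phylo_engine(tree, model)
  tb <- codon_tables()

  genes <- vapply(alns, `[[`, character(1), "gene")
  names(alns) <- genes
  n_gene <- length(alns)

  # Per gene: reconstruct on gapless columns, map events on every edge
  # (candidate runs feed the statistic; the rest feed the per-gene dN/dS of
  # the report).
  per_gene <- vector("list", n_gene)
  for (g in seq_len(n_gene)) {
    aln <- alns[[g]]
    cols <- gapless_columns(aln)
    if (!length(cols)) {
      per_gene[g] <- list(NULL)
      next
    }
    rec <- marginal_posteriors(tree, aln, model, columns = cols,
                               engine = engine, keep_posteriors = FALSE)
    st <- rec$tip_states
    site_n <- colMeans(matrix(tb$nonsyn_sites[st], nrow(st)))
    site_s <- colMeans(matrix(tb$syn_sites[st], nrow(st)))
    ev <- vector("list", length(all_edges))
    excl <- vector("list", length(all_edges))
    for (e in all_edges) {
      m <- .map_subs_core(rec, tree, e, config$min_posterior)
      ev[[e]] <- m
      excl[[e]] <- m$excluded_sites
    }
    per_gene[[g]] <- list(
      gene = aln$gene, columns = cols, site_n = site_n, site_s = site_s,
      N = sum(site_n), S = sum(site_s), events = ev, excluded = excl
    )
  }
  keep <- !vapply(per_gene, is.null, logical(1))
  per_gene <- per_gene[keep]
  genes <- genes[keep]

  # Pooled per-edge dS from all genes.
  s_tot_genes <- vapply(per_gene, `[[`, numeric(1), "S")
  edge_ds <- vapply(run_edges, function(e) {
    sd_by_gene <- vapply(per_gene, function(pg) sum(pg$events[[e]]$sd),
                         numeric(1))
    estimate_edge_ds(sd_by_gene, s_tot_genes)
  }, numeric(1))
  names(edge_ds) <- as.character(run_edges)
  sum_ev <- function(pg, edges, what) {
    tot <- 0
    for (e in edges) tot <- tot + sum(pg$events[[e]][[what]])
    tot
  }

  # Test every gene x run.
  n_tests <- length(per_gene) * nrow(runs)
  col_gene <- character(n_tests)
  col_run <- integer(n_tests)
  num <- matrix(0, n_tests, 10,
                dimnames = list(NULL, c("run_ds", "nd", "sd", "k", "k_syn",
                                        "n_sites", "s_sites", "lambda",
                                        "lambda_syn", "sites_excluded")))
  r <- 0L
  for (pg in per_gene) {
    for (j in seq_len(nrow(runs))) {
      edges <- runs$edges[[j]]
      run_ds <- sum(edge_ds[as.character(edges)])
      excluded <- unique(unlist(pg$excluded[edges]))
      if (length(excluded)) {
        surv <- !(pg$columns %in% excluded)
        N <- sum(pg$site_n[surv])
        S <- sum(pg$site_s[surv])
      } else {
        N <- pg$N
        S <- pg$S
      }
      nd <- sum_ev(pg, edges, "nd")
      sd_ <- sum_ev(pg, edges, "sd")
      r <- r + 1L
      col_gene[r] <- pg$gene
      col_run[r] <- j
      num[r, ] <- c(run_ds, nd, sd_,
                    .round_k(nd, config$rounding),
                    .round_k(sd_, config$rounding),
                    N, S, run_ds * N, run_ds * S, length(excluded))
    }
  }
  tests <- data.frame(gene = col_gene, run = col_run,
                      run_label = runs$label[col_run],
                      n_edges = runs$n_edges[col_run],
                      num, stringsAsFactors = FALSE)
  # A run whose pooled dS estimate is zero carries no synonymous signal at
  # all; its non-synonymous test is not assessable (p = NA, flagged, outside
  # the BH family) rather than degenerate at p = 0.
  tests$zero_ds <- tests$run_ds <= 0
  tests$p <- ifelse(tests$zero_ds,
                    ifelse(tests$k == 0, 1, NA_real_),
                    stats::ppois(tests$k - 1, tests$lambda, lower.tail = FALSE))
  tests$p_syn <- ifelse(tests$lambda_syn > 0,
                        stats::ppois(tests$k_syn - 1, tests$lambda_syn,
                                     lower.tail = FALSE),
                        as.numeric(tests$k_syn == 0))

  ok <- !is.na(tests$p)
  tests$p_adj <- NA_real_
  tests$p_adj[ok] <- bh_adjust(tests$p[ok])
  tests$p_syn_adj <- bh_adjust(tests$p_syn)
  tests$ds_consistent <- tests$p_syn_adj > config$ds_alpha
  tests$significant <- ok & tests$p_adj < config$alpha & tests$ds_consistent
  tests$significant[is.na(tests$significant)] <- FALSE

  candidates <- tests[ok & tests$p_adj < config$alpha, , drop = FALSE]
  candidates <- candidates[order(candidates$p_adj), , drop = FALSE]

  control <- tests[, c("gene", "run", "run_label", "run_ds", "sd", "k_syn",
                       "s_sites", "lambda_syn", "p_syn", "p_syn_adj")]
  control$significant <- control$p_syn_adj < config$alpha
  syn_warn <- sum(control$significant)

  gene_stats <- data.frame(
    gene = vapply(per_gene, `[[`, character(1), "gene"),
    n_codons = vapply(per_gene, function(pg) length(pg$columns), integer(1)),
    N = vapply(per_gene, `[[`, numeric(1), "N"),
    S = vapply(per_gene, `[[`, numeric(1), "S"),
    stringsAsFactors = FALSE
  )

  out <- structure(
    list(tests = tests, candidates = candidates, control = control,
         edge_ds = edge_ds, runs = runs, gene_stats = gene_stats,
         gap_fraction = gf$gap_fraction,
         excluded_genes = vapply(gf$excluded, `[[`, character(1), "gene"),
         per_gene = per_gene, tree = tree, config = config,
         synonymous_bursts = syn_warn),
    class = "burst_scan"
  )
  if (syn_warn > 0) {
    warning(syn_warn, " significant synonymous burst(s) in the negative ",
            "control scan; the neutral model or the data are suspect")
  }
  out
}

#' @export
print.burst_scan <- function(x, ...) {
  cat("Burst scan: ", nrow(x$gene_stats), " genes x ", nrow(x$runs),
      " edge runs (", nrow(x$tests), " tests)\n", sep = "")
  cat("  significant non-synonymous bursts (alpha = ", x$config$alpha, "): ",
      sum(x$tests$significant), "\n", sep = "")
  cat("  synonymous control detections: ", x$synonymous_bursts, "\n", sep = "")
  if (length(x$excluded_genes)) {
    cat("  genes excluded by gap filter: ", length(x$excluded_genes), "\n",
        sep = "")
  }
  sig <- x$candidates[x$candidates$significant, , drop = FALSE]
  if (nrow(sig)) {
    cat("\n")
    print(sig[, c("gene", "run_label", "run_ds", "nd", "sd", "p_adj")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Write the per-burst report table
#'
#' Serializes the significant candidates in the shape of a per-burst results
#' table: clade/dataset label, edge run, run length in dS, gene, substitution
#' counts, the gene's overall dN/dS excluding the burst run, and the adjusted
#' p-value. Filters that require raw reads or genome annotations (read
#' mapping, repeated-domain exclusion, positional conservation, manual
#' curation) are not implemented here and are listed as pending in a comment
#' line of the report.
#'
#' @param scan A `burst_scan`.
#' @param path Output TSV path.
#' @param dataset Label for the dataset/clade column.
#' @return The report data.frame, invisibly.
#' @export
write_burst_report <- function(scan, path, dataset = "dataset") {
  sig <- scan$candidates[scan$candidates$significant, , drop = FALSE]
  gene_of <- vapply(scan$per_gene, `[[`, character(1), "gene")
  dnds <- vapply(seq_len(nrow(sig)), function(i) {
    pg <- scan$per_gene[[match(sig$gene[i], gene_of)]]
    all_events <- data.frame(
      edge = rep(seq_along(pg$events),
                 vapply(pg$events, function(e) length(e$nd), integer(1))),
      nd = unlist(lapply(pg$events, `[[`, "nd")),
      sd = unlist(lapply(pg$events, `[[`, "sd"))
    )
    gd <- gene_dnds(all_events, pg$N, pg$S,
                    exclude_edges = scan$runs$edges[[sig$run[i]]])
    if (isTRUE(gd$undefined)) NA_real_ else gd$dnds
  }, numeric(1))
  rep_df <- data.frame(
    dataset = rep(dataset, nrow(sig)),
    edge_run = sig$run_label,
    run_ds = sig$run_ds,
    gene = sig$gene,
    nonsyn_substitutions = sig$nd,
    syn_substitutions = sig$sd,
    dnds_excluding_run = dnds,
    adjusted_p = sig$p_adj,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# pending external filters: read-mapping paralogue ",
                    "check, repeated-domain exclusion, genomic-position ",
                    "conservation, manual curation"), con)
  utils::write.table(rep_df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(rep_df)
}
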