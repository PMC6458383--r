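# The burst statistic: Poisson tail, BH adjustment, pooled edge dS, the gap
# and dS-consistency filters, and the end-to-end scan on small datasets.

test_that("poisson tail matches closed forms", {
  expect_equal(poisson_tail(0, 0.3), 1)
  expect_equal(poisson_tail(0, 50), 1)
  expect_equal(poisson_tail(2, 1), 1 - 2 * exp(-1))
  # partial sum of the first six Poisson terms at lambda = 0.5
  expect_equal(poisson_tail(6, 0.5),
               1 - sum(exp(-0.5) * 0.5^(0:5) / factorial(0:5)))
  expect_equal(poisson_tail(6, 0.5), 1.42e-5, tolerance = 1e-2)
  expect_error(poisson_tail(2, 0), "lambda")
  expect_error(poisson_tail(-1, 1), "integer")
  expect_error(poisson_tail(2.5, 1), "integer")
})

test_that("poisson tail is monotone in k and in lambda", {
  ks <- 0:12
  expect_true(all(diff(poisson_tail(ks, 0.7)) < 0))
  lams <- c(0.1, 0.5, 1, 2, 5)
  expect_true(all(diff(poisson_tail(rep(4, 5), lams)) > 0))
})

test_that("BH adjustment reproduces hand-worked step-up cases", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(c(0.001, 0.5)), c(0.002, 0.5))
  # order preserved, elementwise >= input, capped at 1
  set.seed(2)
  p <- runif(40)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_equal(order(adj[order(p)]), seq_along(p))  # monotone on sorted input
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("pooled edge dS applies the JC correction to the pooled ratio", {
  expect_equal(estimate_edge_ds(150, 30000), -0.75 * log(1 - 4 * 0.005 / 3))
  expect_equal(estimate_edge_ds(150, 30000), 0.0050167, tolerance = 1e-4)
  expect_equal(estimate_edge_ds(c(0, 0), c(100, 200)), 0)
  # linearity of the uncorrected proportion
  p1 <- 1 - exp(estimate_edge_ds(30, 30000) / -0.75)
  p2 <- 1 - exp(estimate_edge_ds(60, 30000) / -0.75)
  expect_equal(p2 * 0.75 / 0.75, 2 * p1, tolerance = 1e-12)
  expect_error(estimate_edge_ds(5, 0), "synonymous sites")
})

test_that("gap filter excludes strictly above the threshold", {
  make <- function(gap_cols, total = 10) {
    s <- rep("AAA", total)
    s[gap_cols] <- "---"
    codon_alignment(c(a = paste(s, collapse = ""),
                      b = strrep("AAA", total)),
                    gene = paste0("g", length(gap_cols)))
  }
  alns <- list(make(integer(0)), make(1:5), make(1:6))
  gf <- filter_gap_alignments(alns, max_gap_fraction = 0.5)
  expect_equal(length(gf$retained), 2)   # 0% and exactly 50% retained
  expect_equal(length(gf$excluded), 1)   # 60% excluded
  expect_equal(unname(gf$gap_fraction), c(0, 0.5, 0.6))
})

test_that("dS consistency test flags excess synonymous divergence", {
  ok <- ds_consistency_test(0, s_gene = 100, run_ds = 0.004)
  expect_equal(ok$p, 1)
  expect_true(ok$pass)
  bad <- ds_consistency_test(20, s_gene = 40, run_ds = 0.0125)
  expect_lt(bad$p, 1e-20)
  expect_false(bad$pass)
  # a count at the (small) expectation is unremarkable
  at_exp <- ds_consistency_test(1, s_gene = 200, run_ds = 0.005)
  expect_gt(at_exp$p, 0.001)
  expect_true(at_exp$pass)
})

test_that("scan detects an injected burst and not a tiny one", {
  tr <- gammarid_tree()
  # edge 13: 0.0010 dS internal edge ancestral to t6 and t7
  cfg <- generator_config(tr, n_genes = 40, gene_length = c(150, 300),
                          seed = 501,
                          bursts = data.frame(gene = 1, edge = 13, k = 10))
  sim <- simulate_alignment(cfg)
  scan <- suppressWarnings(scan_bursts(tr, sim$alignments))
  tt <- scan$tests
  on_edge <- vapply(scan$runs$edges, function(e) 13 %in% e, logical(1))
  hit <- tt$significant & tt$gene == "gene_0001" & tt$run %in%
    scan$runs$run[on_edge]
  expect_true(any(hit))
  expect_lt(min(tt$p_adj[hit]), 0.05)

  # the same dataset with a 2-substitution burst: raw tail alone is too weak
  cfg2 <- generator_config(tr, n_genes = 40, gene_length = c(150, 300),
                           seed = 501,
                           bursts = data.frame(gene = 1, edge = 13, k = 2))
  sim2 <- simulate_alignment(cfg2)
  scan2 <- suppressWarnings(scan_bursts(tr, sim2$alignments))
  t2 <- scan2$tests
  hit2 <- t2$significant & t2$gene == "gene_0001"
  expect_false(any(hit2))
})

test_that("posterior-filter recomputation shrinks k and lambda together", {
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 10,
                                             gene_length = 150, seed = 77))
  strict <- scan_config(min_posterior = 0.999)
  loose <- scan_config(min_posterior = 0)
  s1 <- suppressWarnings(scan_bursts(tr, sim$alignments, strict))
  s0 <- suppressWarnings(scan_bursts(tr, sim$alignments, loose))
  key <- function(x) paste(x$gene, x$run)
  m <- match(key(s1$tests), key(s0$tests))
  expect_true(all(s1$tests$k <= s0$tests$k[m]))
  expect_true(all(s1$tests$n_sites <= s0$tests$n_sites[m]))
  expect_true(any(s1$tests$sites_excluded > 0))
  expect_true(all(s0$tests$sites_excluded == 0))
})

test_that("rounding policy floors fractional counts by default", {
  expect_equal(phyloburst:::.round_k(6.5, "floor"), 6)
  expect_equal(phyloburst:::.round_k(6.5, "ceiling"), 7)
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 6,
                                             gene_length = 120, seed = 15))
  scan <- suppressWarnings(scan_bursts(tr, sim$alignments))
  expect_true(all(scan$tests$k <= scan$tests$nd))
  expect_true(all(scan$tests$k == floor(scan$tests$nd)))
})

test_that("adjusted p-values dominate raw ones and flags are coherent", {
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 12,
                                             gene_length = 150, seed = 23))
  scan <- suppressWarnings(scan_bursts(tr, sim$alignments))
  tt <- scan$tests
  ok <- !is.na(tt$p_adj)
  expect_true(all(tt$p_adj[ok] >= tt$p[ok]))
  expect_true(all(tt$p_adj[ok] <= 1))
  expect_true(all(tt$lambda[tt$run_ds > 0 & tt$n_sites > 0] > 0))
  expect_true(all(tt$significant[ok] ==
                    (tt$p_adj[ok] < 0.05 & tt$ds_consistent[ok])))
  # untestable zero-dS runs are flagged and never significant
  expect_true(all(!tt$significant[!ok]))
  expect_true(all(tt$zero_ds[!ok]))
  # control table mirrors the synonymous side
  expect_equal(scan$control$p_syn, tt$p_syn)
})

test_that("burst report has the per-burst table shape", {
  tr <- gammarid_tree()
  cfg <- generator_config(tr, n_genes = 30, gene_length = c(150, 300),
                          seed = 31,
                          bursts = data.frame(gene = 2, edge = 13, k = 12))
  sim <- simulate_alignment(cfg)
  scan <- suppressWarnings(scan_bursts(tr, sim$alignments))
  path <- withr::local_tempfile(fileext = ".tsv")
  rep_df <- write_burst_report(scan, path, dataset = "synthetic clade")
  expect_true(file.exists(path))
  expect_named(rep_df, c("dataset", "edge_run", "run_ds", "gene",
                         "nonsyn_substitutions", "syn_substitutions",
                         "dnds_excluding_run", "adjusted_p"))
  expect_true("gene_0002" %in% rep_df$gene)
  got <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#")
  expect_equal(nrow(got), nrow(rep_df))
})
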