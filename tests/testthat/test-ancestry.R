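# Codon model, pruning likelihood against the brute-force enumeration
# oracle, marginal posteriors, and substitution mapping.

test_that("codon model is a proper dS-scaled reversible generator", {
  m <- codon_model(kappa = 2, omega = 0.5)
  expect_equal(rowSums(m$Q), rep(0, 61), tolerance = 1e-12)
  # detailed balance
  pi_ <- m$freqs
  expect_equal(pi_ * m$Q, t(pi_ * m$Q), tolerance = 1e-12)
  # dS scaling: synonymous flow equals mean NG86 synonymous sites per codon
  tb <- codon_tables()
  nb <- tb$neighbors
  syn_flow <- sum(pi_[nb$from] * m$Q[cbind(nb$from, nb$to)] * nb$syn)
  expect_equal(syn_flow, sum(pi_ * tb$syn_sites))
  expect_equal(m$syn_flow, syn_flow)
  expect_equal(subs_per_codon(m, 2), 2 * m$total_flow)
})

test_that("transition matrices are stochastic and converge to stationarity", {
  m <- codon_model()
  P <- transition_matrix(m, 0.05)
  expect_equal(rowSums(P), rep(1, 61), tolerance = 1e-12)
  expect_true(all(P >= 0))
  expect_equal(transition_matrix(m, 0), diag(61))
  Pinf <- transition_matrix(m, 1e4)
  expect_equal(Pinf, matrix(m$freqs, 61, 61, byrow = TRUE), tolerance = 1e-9)
})

test_that("zero-length two-leaf likelihood equals the stationary frequency", {
  tr <- two_leaf_tree(0, 0)
  m <- codon_model()
  lik <- prune_likelihood(tr, c(A = "TTT", B = "TTT"), m)
  expect_equal(lik, m$freqs[codon_tables()$codon_index[["TTT"]]])
  # long branches: leaves become independent draws from the stationary law
  tr2 <- two_leaf_tree(1e4, 1e4)
  lik2 <- prune_likelihood(tr2, c(A = "TTT", B = "GGG"), m)
  expect_equal(lik2, prod(m$freqs[codon_tables()$codon_index[c("TTT", "GGG")]]),
               tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration on 2-5 leaf trees", {
  m <- codon_model(kappa = 2.5, omega = 0.7)
  trees <- list(two_leaf_tree(), balanced4_tree(), caterpillar5_tree())
  seeds <- c(11, 12, 13)
  for (i in seq_along(trees)) {
    for (s in seeds + 10 * i) {
      leaf <- random_leaf_codons(trees[[i]], s)
      oracle <- brute_force_site(trees[[i]], leaf, m)
      got <- prune_likelihood(trees[[i]], leaf, m)
      expect_equal(got, oracle$likelihood, tolerance = 1e-10)
    }
  }
})

test_that("marginal posteriors equal brute-force enumeration", {
  m <- codon_model()
  tr <- balanced4_tree()
  for (s in c(31, 32, 33)) {
    leaf <- random_leaf_codons(tr, s)
    aln <- codon_alignment(leaf, gene = "oracle")
    rec <- marginal_posteriors(tr, aln, m)
    for (node in rec$internal_nodes) {
      oracle <- brute_force_site(tr, leaf, m, node = node)$posterior
      got <- rec$posteriors[[match(node, rec$internal_nodes)]][, 1]
      expect_equal(got, oracle, tolerance = 1e-10)
    }
  }
})

test_that("posteriors sum to one and MAP clears the uniform floor", {
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 2,
                                             gene_length = 40, seed = 71))
  m <- codon_model()
  rec <- marginal_posteriors(tr, sim$alignments[[1]], m)
  for (pp in rec$posteriors) {
    expect_equal(colSums(pp), rep(1, ncol(pp)), tolerance = 1e-9)
  }
  expect_true(all(rec$map_posterior >= 1 / 61))
})

test_that("zero-length star tree pins the root posterior on the shared codon", {
  tr <- parse_newick("(A:0,B:0,C:0);", rooted = TRUE)
  aln <- codon_alignment(c(A = "TTT", B = "TTT", C = "TTT"))
  rec <- marginal_posteriors(tr, aln, codon_model())
  i <- codon_tables()$codon_index[["TTT"]]
  expect_equal(unname(rec$map[1, 1]), unname(i))
  expect_equal(unname(rec$map_posterior[1, 1]), 1)
})

test_that("all-gap site falls back to a flagged uniform posterior", {
  tr <- balanced4_tree()
  aln <- codon_alignment(c(A = "---TTT", B = "---TTT",
                           C = "---TTT", D = "---TTT"))
  rec <- marginal_posteriors(tr, aln, codon_model(),
                             columns = seq_len(2))
  expect_equal(rec$all_gap_sites, 1L)
  expect_equal(rec$posteriors[[1]][, 1], codon_model()$freqs,
               tolerance = 1e-9)
})

test_that("MAP recovers the true simulated ancestor at short divergences", {
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 5,
                                             gene_length = 200, seed = 404))
  m <- codon_model()
  acc <- vapply(seq_len(5), function(g) {
    rec <- marginal_posteriors(tr, sim$alignments[[g]], m)
    truth_nodes <- sim$node_states[[g]]
    hits <- 0L
    tot <- 0L
    for (i in seq_along(rec$internal_nodes)) {
      v <- rec$internal_nodes[i]
      hits <- hits + sum(rec$map[i, ] == truth_nodes[[v]])
      tot <- tot + length(truth_nodes[[v]])
    }
    hits / tot
  }, numeric(1))
  expect_gte(mean(acc), 0.95)
})

test_that("substitution mapping emits events and honours the posterior gate", {
  tr <- balanced4_tree()
  aln <- codon_alignment(c(A = "TTTGTA", B = "TTTGTA",
                           C = "TTCGTA", D = "TTCGTA"))
  rec <- marginal_posteriors(tr, aln, codon_model())
  # the inner edges separate the TTT-like and TTC-like clades; without the
  # posterior gate exactly one synonymous change maps somewhere on the tree
  all_ev <- do.call(rbind, lapply(seq_len(nrow(tr$edge)), function(e) {
    map_substitutions(rec, tr, e, min_posterior = 0)$events
  }))
  expect_equal(sum(all_ev$sd), 1)
  expect_equal(sum(all_ev$nd), 0)
  # an impossible threshold drops every event and excludes its site instead
  strict <- map_substitutions(rec, tr, all_ev$edge[1], min_posterior = 1)
  expect_equal(nrow(strict$events), 0)
  expect_true(all_ev$site[1] %in% strict$excluded_sites)
  expect_error(map_substitutions(rec, tr, 1, min_posterior = 1.5), "0, 1")
})

test_that("path-averaged fractions propagate into mapped events", {
  # three TTT leaves pin the ancestral state; the TTT -> GTA change on the
  # external edge to D averages its two orderings into Nd = 1.5, Sd = 0.5
  tr <- balanced4_tree()
  aln <- codon_alignment(c(A = "TTT", B = "TTT", C = "TTT", D = "GTA"))
  rec <- marginal_posteriors(tr, aln, codon_model())
  edge_to_d <- which(tr$edge[, 2] == which(tr$tip.label == "D"))
  ev <- map_substitutions(rec, tr, edge_to_d, min_posterior = 0)$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$from, "TTT")
  expect_equal(ev$to, "GTA")
  expect_equal(ev$nd, 1.5)
  expect_equal(ev$sd, 0.5)
})

test_that("lowering the posterior threshold never loses events", {
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 3,
                                             gene_length = 120, seed = 88))
  m <- codon_model()
  for (g in 1:3) {
    rec <- marginal_posteriors(tr, sim$alignments[[g]], m)
    counts <- vapply(c(0.95, 0.8, 0.5, 0), function(thr) {
      sum(vapply(seq_len(nrow(tr$edge)), function(e) {
        nrow(map_substitutions(rec, tr, e, min_posterior = thr)$events)
      }, numeric(1)))
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("mapped events track simulated counts on short internal edges", {
  tr <- gammarid_tree()
  sim <- simulate_alignment(generator_config(tr, n_genes = 100,
                                             gene_length = 150, seed = 202))
  m <- codon_model()
  engine <- phyloburst:::.phylo_engine(tr, m)
  # edge 13: short internal edge deep in the tree (0.0010 dS)
  mapped <- 0
  for (g in seq_along(sim$alignments)) {
    rec <- marginal_posteriors(tr, sim$alignments[[g]], m, engine = engine,
                               keep_posteriors = FALSE)
    mapped <- mapped + nrow(map_substitutions(rec, tr, 13)$events)
  }
  simulated <- sum(sim$truth$edge == 13)
  expect_lt(abs(mapped - simulated), 3 * sqrt(max(simulated, 1)))
})
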