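# Marginal ancestral codon reconstruction on a fixed rooted tree by the
# pruning algorithm, and mapping of substitutions onto edges from the MAP
# reconstructions of the edge endpoints. This stage stands in for the
# ancestral-reconstruction step that burst detection needs; only event
# counts and edge lengths feed the downstream statistic.

# Internal: precompute everything that depends on (tree, model) but not on
# the alignment: per-edge transition matrices, traversal orders, child lists.
.phylo_engine <- function(tree, model) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "codon_model"))
  et <- edge_table(tree)
  n_nodes <- max(tree$edge)
  P <- lapply(et$length, function(t) transition_matrix(model, t))
  children_edges <- lapply(seq_len(n_nodes), function(v) which(et$parent == v))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  # postorder over internal nodes: reverse preorder of parents
  post_nodes <- rev(unique(et$parent))  # cladewise order => parents in preorder
  list(tree = tree, et = et, P = P, children_edges = children_edges,
       root = root, post_nodes = post_nodes, n_tip = length(tree$tip.label),
       model = model)
}

# Internal: 61 x L one-hot leaf partials for one taxon (uniform where gapped).
.leaf_partials <- function(states, n_states) {
  L <- length(states)
  M <- matrix(0, n_states, L)
  obs <- which(!is.na(states))
  M[cbind(states[obs], obs)] <- 1
  if (length(obs) < L) M[, setdiff(seq_len(L), obs)] <- 1
  M
}

# Internal core: down (postorder) and up (preorder) passes for one gene.
# Returns per-internal-node posteriors, per-site log-likelihood.
.prune_gene <- function(engine, states) {
  # states: taxa x L integer matrix, rows ordered as tree tip numbers
  n_states <- length(engine$model$freqs)
  L <- ncol(states)
  et <- engine$et
  n_nodes <- max(engine$tree$edge)

  down <- vector("list", n_nodes)   # conditional likelihoods below node
  msg <- vector("list", nrow(et))   # P_e %*% down[child(e)]
  logscale <- matrix(0, 1, L)

  for (tip in seq_len(engine$n_tip)) {
    down[[tip]] <- .leaf_partials(states[tip, ], n_states)
  }
  for (v in engine$post_nodes) {
    D <- NULL
    for (e in engine$children_edges[[v]]) {
      msg[[e]] <- engine$P[[e]] %*% down[[et$child[e]]]
      D <- if (is.null(D)) msg[[e]] else D * msg[[e]]
    }
    sc <- colSums(D)
    sc[sc == 0] <- 1
    down[[v]] <- D / rep(sc, each = n_states)
    logscale <- logscale + log(sc)
  }

  pi_ <- engine$model$freqs
  site_lik <- colSums(pi_ * down[[engine$root]])
  loglik <- log(site_lik) + as.numeric(logscale)

  # Up pass: outside partials, root outward (cladewise edge order is preorder)
  up <- vector("list", n_nodes)
  up[[engine$root]] <- matrix(pi_, n_states, L)
  internal_nodes <- unique(et$parent)
  for (e in seq_len(nrow(et))) {
    u <- et$parent[e]
    v <- et$child[e]
    if (v <= engine$n_tip) next
    sib <- up[[u]]
    for (f in engine$children_edges[[u]]) {
      if (f != e) sib <- sib * msg[[f]]
    }
    Uv <- crossprod(engine$P[[e]], sib)
    sc <- colSums(Uv)
    sc[sc == 0] <- 1
    up[[v]] <- Uv / rep(sc, each = n_states)
  }

  posteriors <- vector("list", n_nodes)
  for (v in internal_nodes) {
    post <- up[[v]] * down[[v]]
    tot <- colSums(post)
    tot[tot == 0] <- 1
    posteriors[[v]] <- post / rep(tot, each = n_states)
  }
  list(posteriors = posteriors, loglik = loglik, site_lik_scaled = site_lik)
}

# Internal: leaf state matrix ordered by tree tip numbers.
.tip_states <- function(tree, aln, columns) {
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree leaf set and alignment taxon set differ", call. = FALSE)
  }
  states <- .codon_state_matrix(aln, columns)
  states[match(tree$tip.label, aln$taxa), , drop = FALSE]
}

#' Phylogenetic likelihood of codon sites by the pruning algorithm
#'
#' Computes the likelihood of one or more codon alignment columns on a rooted
#' tree under a codon model, by the postorder conditional-likelihood
#' recursion with per-branch transition matrices. Gaps are treated as missing
#' data (uniform partial likelihood).
#'
#' @param tree Rooted `phylo` with dS branch lengths; leaf set must equal the
#'   alignment taxon set.
#' @param aln A `codon_alignment`, or a named character vector giving one
#'   codon per taxon (a single site).
#' @param model A `codon_model`.
#' @param columns Codon columns to evaluate (default all).
#' @return Numeric vector of per-site likelihoods.
#' @export
prune_likelihood <- function(tree, aln, model, columns = NULL) {
  if (!inherits(aln, "codon_alignment")) {
    aln <- codon_alignment(aln, gene = "site")
  }
  if (is.null(columns)) columns <- seq_len(aln$n_codons)
  engine <- .phylo_engine(tree, model)
  states <- .tip_states(tree, aln, columns)
  res <- .prune_gene(engine, states)
  exp(res$loglik)
}

#' Marginal ancestral codon reconstruction
#'
#' For every internal node and codon site, computes the posterior
#' distribution over the 61 sense codons given the tip data (the marginal
#' reconstruction: inside times outside partial likelihoods, normalized), the
#' MAP codon and its posterior probability. MAP ties are broken towards the
#' lexicographically smallest codon.
#'
#' @inheritParams prune_likelihood
#' @param engine Optional precomputed internal engine (used by the scanner to
#'   share per-edge transition matrices across genes).
#' @param keep_posteriors Keep the full 61-state posterior matrices
#'   (default `TRUE`); the scanner sets `FALSE` since it only consumes the
#'   MAP states and their posteriors.
#' @return An object of class `ancestral_reconstruction`: `map` and
#'   `map_posterior` (internal-node x site matrices, rows named by ape node
#'   number), `posteriors` (list over internal nodes of 61 x sites matrices),
#'   `columns`, `loglik` (per-site log-likelihood), `all_gap_sites` (columns
#'   with no observed codon, where posteriors fall back to the prior).
#' @export
marginal_posteriors <- function(tree, aln, model, columns = NULL,
                                engine = NULL, keep_posteriors = TRUE) {
  if (is.null(engine)) engine <- .phylo_engine(tree, model)
  if (is.null(columns)) columns <- seq_len(aln$n_codons)
  states <- .tip_states(engine$tree, aln, columns)
  res <- .prune_gene(engine, states)

  internal_nodes <- sort(unique(engine$et$parent))
  L <- length(columns)
  map <- matrix(NA_integer_, length(internal_nodes), L,
                dimnames = list(internal_nodes, NULL))
  map_post <- matrix(NA_real_, length(internal_nodes), L,
                     dimnames = list(internal_nodes, NULL))
  for (i in seq_along(internal_nodes)) {
    pp <- res$posteriors[[internal_nodes[i]]]
    map[i, ] <- max.col(t(pp), ties.method = "first")  # smallest state wins
    map_post[i, ] <- pp[cbind(map[i, ], seq_len(L))]
  }
  all_gap <- which(colSums(!is.na(states)) == 0L)
  structure(
    list(map = map, map_posterior = map_post,
         posteriors = if (keep_posteriors) res$posteriors[internal_nodes],
         internal_nodes = internal_nodes,
         columns = columns, loglik = res$loglik,
         all_gap_sites = columns[all_gap],
         gene = aln$gene, tip_states = states),
    class = "ancestral_reconstruction"
  )
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat("Marginal ancestral reconstruction for '", x$gene, "': ",
      length(x$internal_nodes), " internal nodes x ", length(x$columns),
      " sites; mean MAP posterior ",
      format(mean(x$map_posterior), digits = 3), "\n", sep = "")
  invisible(x)
}

# Internal: MAP state + posterior of one edge endpoint (leaf => observed
# codon with posterior 1; gapped leaf codon => NA state).
.endpoint_states <- function(rec, node, n_tip) {
  if (node <= n_tip) {
    st <- rec$tip_states[node, ]
    list(state = st, post = ifelse(is.na(st), NA_real_, 1))
  } else {
    i <- match(node, rec$internal_nodes)
    list(state = rec$map[i, ], post = rec$map_posterior[i, ])
  }
}

#' Map substitutions onto a tree edge from ancestral reconstructions
#'
#' Emits one substitution event per site at which the MAP codons of the two
#' edge endpoints differ (a leaf endpoint contributes its observed codon with
#' posterior 1). Sites whose minimum endpoint posterior falls below
#' `min_posterior` yield no event and are additionally reported as excluded,
#' so that downstream statistics can be recomputed without them.
#'
#' @param rec An `ancestral_reconstruction`.
#' @param tree The tree used for the reconstruction.
#' @param edge Edge index (row of [edge_table()]).
#' @param min_posterior Posterior threshold in \[0, 1\] below which a site is
#'   excluded (default 0.8).
#' @return A list with `events` (data.frame: `gene`, `edge`, `site`, `from`,
#'   `to`, `nd`, `sd`, `ndiff`, `posterior`) and `excluded_sites` (integer
#'   vector of excluded codon columns).
#' @export
map_substitutions <- function(rec, tree, edge, min_posterior = 0.8) {
  m <- .map_subs_core(rec, tree, edge, min_posterior)
  tb <- codon_tables()
  events <- data.frame(
    gene = rep(rec$gene, length(m$site)),
    edge = rep(edge, length(m$site)),
    site = m$site,
    from = tb$codons[m$from],
    to = tb$codons[m$to],
    nd = m$nd,
    sd = m$sd,
    ndiff = tb$ndiff[cbind(m$from, m$to)],
    posterior = m$posterior,
    stringsAsFactors = FALSE
  )
  list(events = events, excluded_sites = m$excluded_sites)
}

#' Export a reconstruction or an event table as TSV
#'
#' `write_reconstruction_tsv()` writes one row per internal node and codon
#' site (node, site, MAP codon, posterior); `write_events_tsv()` writes a
#' substitution event data.frame as produced by [map_substitutions()].
#'
#' @param rec An `ancestral_reconstruction`.
#' @param events An event data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reconstruction_tsv <- function(rec, path) {
  tb <- codon_tables()
  df <- data.frame(
    node = rep(rec$internal_nodes, times = length(rec$columns)),
    site = rep(rec$columns, each = length(rec$internal_nodes)),
    map_codon = tb$codons[as.vector(rec$map)],
    posterior = as.vector(rec$map_posterior)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reconstruction_tsv
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Internal fast path: substitution mapping without data.frame assembly.
.map_subs_core <- function(rec, tree, edge, min_posterior) {
  if (!is.numeric(min_posterior) || min_posterior < 0 || min_posterior > 1) {
    stop("min_posterior must be in [0, 1]", call. = FALSE)
  }
  tb <- codon_tables()
  stopifnot(edge >= 1, edge <= nrow(tree$edge))
  n_tip <- length(tree$tip.label)

  pa <- .endpoint_states(rec, tree$edge[edge, 1], n_tip)
  ch <- .endpoint_states(rec, tree$edge[edge, 2], n_tip)
  minp <- pmin(pa$post, ch$post)

  observed <- !is.na(pa$state) & !is.na(ch$state)
  low <- observed & minp < min_posterior
  hit <- which(observed & !low & pa$state != ch$state)

  idx <- cbind(pa$state[hit], ch$state[hit])
  list(site = rec$columns[hit], from = pa$state[hit], to = ch$state[hit],
       nd = tb$nd[idx], sd = tb$sd[idx], posterior = minp[hit],
       excluded_sites = rec$columns[low])
}
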