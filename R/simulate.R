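# Synthetic codon evolution along a phylogeny, with ground-truth
# substitution records and optional burst injection. The generator emulates
# the structure of clade-wise orthologue datasets — many genes of a few
# hundred codons on one tree per clade containing very short internal edges
# — so every stage of the burst pipeline can be validated against known
# truth without any real transcriptome data.

#' Generator configuration
#'
#' @param tree Rooted `phylo` with branch lengths in dS units.
#' @param n_genes Number of genes to simulate.
#' @param gene_length Codon length range `c(min, max)` (sampled uniformly),
#'   or a single fixed length.
#' @param omega Baseline non-synonymous/synonymous rate ratio (default 1,
#'   the neutral null).
#' @param kappa Transition/transversion ratio (default 2).
#' @param freqs Stationary codon frequencies (default equal).
#' @param bursts Optional data.frame with columns `gene` (index), `edge`
#'   (edge index) and `k` (non-synonymous substitutions to inject).
#' @param gap_rate Per-codon-column probability of injecting gaps
#'   (default 0).
#' @param seed Mandatory integer master seed; per-gene substreams are
#'   derived from it deterministically.
#' @return A `generator_config` list.
#' @export
generator_config <- function(tree, n_genes, gene_length = c(150L, 300L),
                             omega = 1, kappa = 2, freqs = NULL,
                             bursts = NULL, gap_rate = 0, seed) {
  stopifnot(inherits(tree, "phylo"), n_genes >= 1)
  if (missing(seed) || !is.numeric(seed)) {
    stop("a numeric seed is mandatory", call. = FALSE)
  }
  if (length(gene_length) == 1L) gene_length <- rep(gene_length, 2L)
  stopifnot(gene_length[1] >= 1, gene_length[2] >= gene_length[1])
  if (!is.null(bursts)) {
    stopifnot(is.data.frame(bursts),
              all(c("gene", "edge", "k") %in% names(bursts)))
    if (any(bursts$gene < 1 | bursts$gene > n_genes)) {
      stop("burst spec references a gene outside 1..n_genes", call. = FALSE)
    }
    if (any(bursts$edge < 1 | bursts$edge > nrow(tree$edge))) {
      stop("burst spec references a non-existent edge", call. = FALSE)
    }
    if (any(bursts$k > 3 * gene_length[1])) {
      stop("burst k exceeds 3 x minimum gene length", call. = FALSE)
    }
  }
  structure(list(
    tree = ape::reorder.phylo(tree, "cladewise"), n_genes = as.integer(n_genes),
    gene_length = as.integer(gene_length), omega = omega, kappa = kappa,
    freqs = freqs, bursts = bursts, gap_rate = gap_rate,
    seed = as.integer(seed)
  ), class = "generator_config")
}

# Internal: per-state exit rates and target sampling tables from a model.
.gillespie_tables <- function(model) {
  Q <- model$Q
  n <- nrow(Q)
  exit <- -diag(Q)
  targets <- vector("list", n)
  for (i in seq_len(n)) {
    js <- which(Q[i, ] > 0 & seq_len(n) != i)
    targets[[i]] <- list(to = js, w = Q[i, js])
  }
  list(exit = exit, targets = targets)
}

# Internal: evolve integer codon states along one branch of length t (dS),
# Gillespie event sampling; returns new states + event records as a matrix
# with columns (site, from, to), rows in event order.
.evolve_branch <- function(states, t, gt) {
  ev <- matrix(0L, 16L, 3L)
  n_ev <- 0L
  if (t > 0) {
    time <- 0
    rates <- gt$exit[states]
    tot <- sum(rates)
    repeat {
      if (tot <= 0) break
      time <- time + stats::rexp(1, tot)
      if (time > t) break
      site <- sample.int(length(states), 1L, prob = rates)
      tg <- gt$targets[[states[site]]]
      to <- if (length(tg$to) == 1L) tg$to else
        tg$to[sample.int(length(tg$to), 1L, prob = tg$w)]
      n_ev <- n_ev + 1L
      if (n_ev > nrow(ev)) ev <- rbind(ev, matrix(0L, nrow(ev), 3L))
      ev[n_ev, ] <- c(site, states[site], to)
      states[site] <- to
      tot <- tot - rates[site]
      rates[site] <- gt$exit[to]
      tot <- tot + rates[site]
    }
  }
  ev <- ev[seq_len(n_ev), , drop = FALSE]
  colnames(ev) <- c("site", "from", "to")
  list(states = states, events = ev)
}

#' Simulate codon alignments along a phylogeny with full event truth
#'
#' Draws each gene's root sequence from the stationary codon frequencies and
#' evolves it along every branch by Gillespie-style event sampling from the
#' codon model (branch lengths in dS units; `omega` multiplies
#' non-synonymous rates). Every substitution event is recorded. Bursts
#' listed in the configuration are injected afterwards via [inject_burst()].
#'
#' @param config A [generator_config()].
#' @return An object of class `codon_simulation`: `alignments` (list of
#'   `codon_alignment`), `truth` (data.frame of events: `gene`, `edge`,
#'   `site`, `from`, `to`, `pos`, `from_base`, `to_base`, `syn`, `injected`),
#'   `node_states` (per gene, list over all tree nodes of codon state
#'   vectors), `tree`, `config`.
#' @export
simulate_alignment <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  tree <- config$tree
  model <- codon_model(kappa = config$kappa, omega = config$omega,
                       freqs = config$freqs)
  gt <- .gillespie_tables(model)
  tb <- codon_tables()
  et <- edge_table(tree)
  n_tip <- length(tree$tip.label)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]

  set.seed(config$seed)
  gene_seeds <- sample.int(.Machine$integer.max, config$n_genes)

  alignments <- vector("list", config$n_genes)
  node_states <- vector("list", config$n_genes)
  truth_rows <- vector("list", config$n_genes)

  for (g in seq_len(config$n_genes)) {
    set.seed(gene_seeds[g])
    L <- if (config$gene_length[1] == config$gene_length[2]) {
      config$gene_length[1]
    } else {
      sample(seq(config$gene_length[1], config$gene_length[2]), 1L)
    }
    nodes <- vector("list", max(tree$edge))
    nodes[[root]] <- sample.int(length(model$freqs), L, replace = TRUE,
                                prob = model$freqs)
    gene_events <- vector("list", nrow(et))
    for (e in seq_len(nrow(et))) {  # cladewise = parents before children
      ev <- .evolve_branch(nodes[[et$parent[e]]], et$length[e], gt)
      nodes[[et$child[e]]] <- ev$states
      if (nrow(ev$events)) {
        gene_events[[e]] <- cbind(edge = e, ev$events)
      }
    }
    gene_events <- do.call(rbind, gene_events)
    gene_name <- sprintf("gene_%04d", g)
    leaf_seqs <- vapply(seq_len(n_tip), function(tip) {
      paste(tb$codons[nodes[[tip]]], collapse = "")
    }, character(1))
    names(leaf_seqs) <- tree$tip.label
    aln <- codon_alignment(leaf_seqs, gene = gene_name)
    if (config$gap_rate > 0) {
      gap_cols <- which(stats::runif(L) < config$gap_rate)
      if (length(gap_cols)) {
        for (col in gap_cols) {
          victims <- which(stats::runif(n_tip) < 0.5)
          if (!length(victims)) victims <- sample.int(n_tip, 1L)
          aln$codons[victims, col] <- "---"
        }
        aln <- codon_alignment(aln$codons, gene = gene_name)
      }
    }
    alignments[[g]] <- aln
    node_states[[g]] <- nodes
    truth_rows[[g]] <- if (!is.null(gene_events) && nrow(gene_events)) {
      data.frame(gene = g, edge = gene_events[, "edge"],
                 site = gene_events[, "site"], from = gene_events[, "from"],
                 to = gene_events[, "to"], injected = FALSE)
    } else NULL
  }

  truth <- do.call(rbind, truth_rows)
  if (is.null(truth)) {
    truth <- data.frame(gene = integer(0), edge = integer(0),
                        site = integer(0), from = integer(0),
                        to = integer(0), injected = logical(0))
  }
  truth <- .annotate_truth(truth, tb)
  names(alignments) <- vapply(alignments, `[[`, character(1), "gene")

  sim <- structure(
    list(alignments = alignments, truth = truth, node_states = node_states,
         tree = tree, config = config),
    class = "codon_simulation"
  )
  if (!is.null(config$bursts)) {
    set.seed(config$seed + 1L)
    burst_seeds <- sample.int(.Machine$integer.max, nrow(config$bursts))
    for (b in seq_len(nrow(config$bursts))) {
      sim <- inject_burst(sim, gene = config$bursts$gene[b],
                          edge = config$bursts$edge[b],
                          k = config$bursts$k[b], seed = burst_seeds[b])
    }
  }
  sim
}

# Internal: decorate truth rows (integer codon states) with codon strings,
# changed position, bases and synonymy.
.annotate_truth <- function(truth, tb) {
  if (!nrow(truth)) {
    truth$from_codon <- character(0)
    truth$to_codon <- character(0)
    truth$pos <- integer(0)
    truth$from_base <- character(0)
    truth$to_base <- character(0)
    truth$syn <- logical(0)
    return(truth)
  }
  from_c <- tb$codons[truth$from]
  to_c <- tb$codons[truth$to]
  cm <- do.call(rbind, strsplit(tb$codons, ""))
  d1 <- cm[truth$from, 1] != cm[truth$to, 1]
  d2 <- cm[truth$from, 2] != cm[truth$to, 2]
  pos <- ifelse(d1, 1L, ifelse(d2, 2L, 3L))
  truth$from_codon <- from_c
  truth$to_codon <- to_c
  truth$pos <- as.integer(pos)
  truth$from_base <- substr(from_c, pos, pos)
  truth$to_base <- substr(to_c, pos, pos)
  truth$syn <- tb$aa[truth$from] == tb$aa[truth$to]
  rownames(truth) <- NULL
  truth
}

#' @export
print.codon_simulation <- function(x, ...) {
  cat("Codon simulation: ", length(x$alignments), " genes on ",
      length(x$tree$tip.label), " taxa; ", nrow(x$truth), " events (",
      sum(x$truth$injected), " injected)\n", sep = "")
  invisible(x)
}

#' Inject a burst of non-synonymous substitutions on an edge
#'
#' Places `k` additional single-nucleotide non-synonymous substitutions at
#' distinct, uniformly chosen codon sites on the given edge, scattered
#' through the protein. Sites are drawn from columns untouched by any other
#' event in the gene, so the derived allele is carried by exactly the species
#' descending from the edge; the derived state propagates consistently to
#' all descendant nodes and leaf sequences.
#'
#' @param sim A `codon_simulation`.
#' @param gene Gene index.
#' @param edge Edge index (row of [edge_table()]).
#' @param k Number of non-synonymous events to inject.
#' @param seed Integer seed for site and target choice.
#' @return The updated `codon_simulation`.
#' @export
inject_burst <- function(sim, gene, edge, k, seed) {
  stopifnot(inherits(sim, "codon_simulation"), k >= 1)
  tb <- codon_tables()
  tree <- sim$tree
  et <- edge_table(tree)
  stopifnot(edge >= 1, edge <= nrow(et))
  aln <- sim$alignments[[gene]]
  nodes <- sim$node_states[[gene]]
  L <- aln$n_codons

  used <- unique(sim$truth$site[sim$truth$gene == gene])
  free <- setdiff(setdiff(seq_len(L), used), aln$gap_columns)
  if (length(free) < k) {
    stop("only ", length(free), " untouched sites available; cannot inject ",
         k, " events", call. = FALSE)
  }
  set.seed(seed)
  sites <- sort(sample(free, k))

  child <- et$child[edge]
  desc_nodes <- .subtree_nodes(tree, child)
  n_tip <- length(tree$tip.label)

  new_rows <- vector("list", k)
  nonsyn <- !tb$neighbors$syn
  for (i in seq_len(k)) {
    s <- sites[i]
    from <- nodes[[child]][s]
    cand <- which(tb$neighbors$from == from & nonsyn)
    to <- tb$neighbors$to[cand[sample.int(length(cand), 1L)]]
    for (v in desc_nodes) nodes[[v]][s] <- to
    new_rows[[i]] <- data.frame(gene = gene, edge = edge, site = s,
                                from = from, to = to, injected = TRUE)
  }
  for (tip in intersect(desc_nodes, seq_len(n_tip))) {
    aln$codons[match(tree$tip.label[tip], aln$taxa), sites] <-
      tb$codons[nodes[[tip]][sites]]
  }

  sim$node_states[[gene]] <- nodes
  sim$alignments[[gene]] <- codon_alignment(aln$codons, gene = aln$gene)
  sim$truth <- rbind(sim$truth, .annotate_truth(do.call(rbind, new_rows), tb))
  rownames(sim$truth) <- NULL
  sim
}

# Internal: node and its descendants (node numbers).
.subtree_nodes <- function(tree, v) {
  out <- v
  stack <- v
  while (length(stack)) {
    u <- stack[[1]]
    stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == u, 2]
    out <- c(out, kids)
    stack <- c(stack, kids[kids > length(tree$tip.label)])
  }
  sort(unique(out))
}

#' Realized per-edge dS from simulation truth
#'
#' Synonymous event counts per edge divided by the total synonymous site
#' count of the simulated genes — the generator-side counterpart of
#' [estimate_edge_ds()], computed from truth rather than reconstruction.
#'
#' @param sim A `codon_simulation`.
#' @param jc Apply the Jukes-Cantor correction (default `FALSE`: raw
#'   proportion).
#' @return Named numeric vector over edge indices.
#' @export
realized_edge_ds <- function(sim, jc = FALSE) {
  S_tot <- sum(vapply(sim$alignments, function(a) ng86_sites(a)$S, numeric(1)))
  n_edges <- nrow(sim$tree$edge)
  syn <- sim$truth[sim$truth$syn & !sim$truth$injected, ]
  counts <- tabulate(syn$edge, nbins = n_edges)
  p <- counts / S_tot
  out <- if (jc) jc_correct(p) else p
  names(out) <- seq_len(n_edges)
  out
}

#' Replay truth events from the root
#'
#' Reconstructs every node sequence of a gene by applying the recorded
#' events edge by edge from the root sequence, and compares the resulting
#' leaf sequences with the emitted alignment. Used to assert that truth and
#' alignment are mutually consistent.
#'
#' @param sim A `codon_simulation`.
#' @param gene Gene index.
#' @return `TRUE` when every leaf sequence is reproduced exactly (otherwise
#'   an error describing the first mismatch).
#' @export
replay_truth <- function(sim, gene) {
  tree <- sim$tree
  et <- edge_table(tree)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  tb <- codon_tables()
  tr <- sim$truth[sim$truth$gene == gene, ]
  nodes <- vector("list", max(tree$edge))
  nodes[[root]] <- sim$node_states[[gene]][[root]]
  for (e in seq_len(nrow(et))) {
    st <- nodes[[et$parent[e]]]
    ev <- tr[tr$edge == e, ]
    if (nrow(ev)) {
      for (i in seq_len(nrow(ev))) st[ev$site[i]] <- ev$to[i]
    }
    nodes[[et$child[e]]] <- st
  }
  aln <- sim$alignments[[gene]]
  for (tip in seq_along(tree$tip.label)) {
    got <- tb$codons[nodes[[tip]]]
    want <- aln$codons[match(tree$tip.label[tip], aln$taxa), ]
    gapped <- grepl("-", want, fixed = TRUE)
    if (!all(got[!gapped] == want[!gapped])) {
      stop("replay mismatch for gene ", gene, ", tip ",
           tree$tip.label[tip], call. = FALSE)
    }
  }
  TRUE
}
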