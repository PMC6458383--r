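# Rooted phylogenies with branch lengths in dS units (expected synonymous
# substitutions per synonymous site), and enumeration of the short internal
# edge runs on which bursts are sought.
#
# Trees are ape "phylo" objects kept in cladewise (preorder) edge order.
# An edge is *internal* when its child node is an internal node, i.e. the
# edge is ancestral to more than one extant species; this is what shields
# burst calls from single-sequence artefacts.

#' Parse a rooted Newick tree with branch lengths
#'
#' @param text Newick string.
#' @param rooted Set `TRUE` to accept a tree whose root is multifurcating
#'   (which ape reports as unrooted) as explicitly rooted. By default an
#'   unrooted tree is an error: the direction of ancestral reconstruction
#'   must not be guessed.
#' @return A rooted `phylo` object in cladewise order.
#' @examples
#' tr <- parse_newick("((A:0.01,B:0.01):0.004,(C:0.01,D:0.01):0.004);")
#' edge_table(tr)
#' @export
parse_newick <- function(text, rooted = FALSE) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("malformed Newick string", call. = FALSE)
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("Newick tree is missing branch lengths", call. = FALSE)
  }
  if (any(tr$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (!ape::is.rooted(tr) && !isTRUE(rooted)) {
    stop("tree is unrooted; provide a rooted tree (or set rooted = TRUE ",
         "for an explicitly rooted multifurcation)", call. = FALSE)
  }
  ape::reorder.phylo(tr, "cladewise")
}

#' Read a rooted Newick tree from a file
#' @param path Path to a Newick file.
#' @inheritParams parse_newick
#' @return A rooted `phylo` object.
#' @export
read_rooted_tree <- function(path, rooted = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""),
               rooted = rooted)
}

#' Write a tree to a Newick string or file
#' @param tree A `phylo` object.
#' @param path Optional output file; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}

#' Edge table of a rooted tree
#'
#' @param tree A rooted `phylo` object.
#' @return A data.frame with one row per edge (row order = cladewise edge
#'   order, which is the preorder used for run enumeration): `edge` (index
#'   into `tree$edge`), `parent`, `child` (ape node numbers), `length`
#'   (dS units), `internal` (logical: child is an internal node), and
#'   `child_label` (leaf name, or clade spelled as sorted leaf names).
#' @export
edge_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  labels <- vapply(child, function(v) {
    if (v <= n_tip) return(tree$tip.label[v])
    tips <- .clade_tips(tree, v)
    paste(sort(tree$tip.label[tips]), collapse = ",")
  }, character(1))
  data.frame(
    edge = seq_len(nrow(tree$edge)),
    parent = tree$edge[, 1],
    child = child,
    length = tree$edge.length,
    internal = child > n_tip,
    child_label = labels,
    stringsAsFactors = FALSE
  )
}

# Internal: tip numbers descending from node v.
.clade_tips <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) return(v)
  out <- integer(0)
  stack <- v
  while (length(stack)) {
    u <- stack[[1]]
    stack <- stack[-1]
    kids <- tree$edge[tree$edge[, 1] == u, 2]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  sort(out)
}

#' Enumerate candidate edge runs
#'
#' A run is a single internal edge, or a path of consecutive internal edges
#' (each the parent of the next), whose combined length is strictly below
#' `max_ds`. External edges never participate. All contiguous sub-paths under
#' the cap are returned, not only maximal ones, in deterministic order:
#' preorder position of the first edge, then run length.
#'
#' @param tree A rooted `phylo` object with dS branch lengths.
#' @param max_ds Strict upper bound on combined run length (dS units).
#' @param max_run_edges Maximum number of consecutive edges per run
#'   (default 2).
#' @return A data.frame with one row per run: `run` (index), `edges`
#'   (list-column of edge indices, parent first), `n_edges`, `ds` (combined
#'   length), `label` (human-readable edge path).
#' @examples
#' tr <- parse_newick("((((A:1,B:1):0.0007,C:1):0.004,D:1):1,(E:1,F:1):1);")
#' enumerate_edge_runs(tr, max_ds = 0.005)
#' @export
enumerate_edge_runs <- function(tree, max_ds, max_run_edges = 2L) {
  stopifnot(max_ds > 0, max_run_edges >= 1L)
  et <- edge_table(tree)
  internal_edges <- which(et$internal)

  # children edges of each edge (edges whose parent node is this edge's child)
  kids_of_edge <- lapply(seq_len(nrow(et)), function(e) {
    which(et$parent == et$child[e] & et$internal)
  })

  runs <- list()
  extend <- function(path, len) {
    if (len < max_ds) {
      runs[[length(runs) + 1L]] <<- list(edges = path, ds = len)
    } else if (length(path) == 1L) {
      return(invisible())  # single edge too long; extensions only grow
    }
    if (length(path) < max_run_edges && len < max_ds) {
      for (f in kids_of_edge[[path[length(path)]]]) {
        extend(c(path, f), len + et$length[f])
      }
    }
  }
  for (e in internal_edges) extend(e, et$length[e])

  if (!length(runs)) {
    return(data.frame(run = integer(0), edges = I(list()),
                      n_edges = integer(0), ds = numeric(0),
                      label = character(0)))
  }
  first <- vapply(runs, function(r) r$edges[1L], integer(1))
  n_edges <- vapply(runs, function(r) length(r$edges), integer(1))
  ord <- order(first, n_edges)
  runs <- runs[ord]
  data.frame(
    run = seq_along(runs),
    edges = I(lapply(runs, `[[`, "edges")),
    n_edges = n_edges[ord],
    ds = vapply(runs, `[[`, numeric(1), "ds"),
    label = vapply(runs, function(r) {
      paste(et$child_label[r$edges], collapse = " + ")
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
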