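# Standard genetic code and precomputed codon machinery.
#
# Everything downstream (site counting, path classification, the codon model,
# the simulator) works on integer codon indices 1..61 over the sense codons,
# ordered lexicographically in A < C < G < T. Stop codons (TAA, TAG, TGA in
# the standard code) are excluded from the state space.

DNA_BASES <- c("A", "C", "G", "T")

# NCBI standard code, codons enumerated with bases in T, C, A, G order.
.STANDARD_CODE_AA <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.build_genetic_code <- function() {
  tcag <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = tcag, b2 = tcag, b1 = tcag,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aa <- strsplit(.STANDARD_CODE_AA, "")[[1]]
  names(aa) <- codons
  aa[order(names(aa))]
}

.pb_cache <- new.env(parent = emptyenv())

#' Codon tables for the standard genetic code
#'
#' Returns the precomputed machinery shared by all codon-level operations:
#' the sense-codon state space, per-codon Nei-Gojobori site counts, the
#' single-nucleotide neighbour structure and the pairwise path-averaged
#' substitution classification.
#'
#' @return A list with elements
#'   \describe{
#'     \item{code}{named character vector, all 64 codons to one-letter amino
#'       acids (`*` = stop), codons sorted A < C < G < T.}
#'     \item{codons}{character vector of the 61 sense codons (state order).}
#'     \item{aa}{amino acid of each sense codon.}
#'     \item{codon_index}{named integer vector mapping codon string to state.}
#'     \item{syn_sites}{numeric 61-vector: NG86 synonymous sites per codon.}
#'     \item{nonsyn_sites}{numeric 61-vector: `3 - syn_sites`.}
#'     \item{neighbors}{data.frame of all single-nucleotide changes between
#'       sense codons: `from`, `to` (state indices), `pos` (1..3),
#'       `from_base`, `to_base`, `syn`, `transition`.}
#'     \item{nd, sd, ndiff}{61 x 61 matrices: path-averaged non-synonymous and
#'       synonymous step counts, and nucleotide difference count, per ordered
#'       codon pair.}
#'   }
#' @export
codon_tables <- function() {
  if (!is.null(.pb_cache$tables)) {
    return(.pb_cache$tables)
  }
  code <- .build_genetic_code()
  codons <- names(code)[code != "*"]
  n <- length(codons)
  aa <- unname(code[codons])
  codon_index <- seq_len(n)
  names(codon_index) <- codons

  codon_mat <- do.call(rbind, strsplit(codons, ""))

  # Neighbour structure: all 9 single-nucleotide changes per sense codon.
  nb <- vector("list", n * 9L)
  k <- 0L
  for (i in seq_len(n)) {
    for (pos in 1:3) {
      for (b in DNA_BASES) {
        if (b == codon_mat[i, pos]) next
        trip <- codon_mat[i, ]
        trip[pos] <- b
        to_codon <- paste(trip, collapse = "")
        if (code[[to_codon]] == "*") next  # changes to stops are disregarded
        k <- k + 1L
        nb[[k]] <- data.frame(
          from = i, to = codon_index[[to_codon]], pos = pos,
          from_base = codon_mat[i, pos], to_base = b,
          syn = aa[i] == code[[to_codon]],
          transition = .is_transition(codon_mat[i, pos], b),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  neighbors <- do.call(rbind, nb[seq_len(k)])

  # NG86 sites with stop renormalization: each position contributes the
  # fraction of its non-stop changes that are synonymous, so S + N = 3 exactly.
  syn_sites <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (pos in 1:3) {
      rows <- neighbors$from == i & neighbors$pos == pos
      m <- sum(rows)
      if (m > 0) s <- s + sum(neighbors$syn[rows]) / m
    }
    syn_sites[i] <- s
  }

  pair <- .build_pair_classification(codons, code, codon_mat)

  .pb_cache$tables <- list(
    code = code, codons = codons, aa = aa, codon_index = codon_index,
    syn_sites = syn_sites, nonsyn_sites = 3 - syn_sites,
    neighbors = neighbors,
    nd = pair$nd, sd = pair$sd, ndiff = pair$ndiff
  )
  .pb_cache$tables
}

.is_transition <- function(a, b) {
  (a %in% c("A", "G") && b %in% c("A", "G")) ||
    (a %in% c("C", "T") && b %in% c("C", "T"))
}

# Path-averaged substitution classification for every ordered sense-codon
# pair: enumerate all orderings of the differing positions, drop orderings
# passing through a stop codon, average syn / non-syn step counts.
.build_pair_classification <- function(codons, code, codon_mat) {
  n <- length(codons)
  nd <- matrix(0, n, n)
  sd <- matrix(0, n, n)
  ndiff <- matrix(0L, n, n)

  perms <- list(
    list(1L),
    list(c(1L, 2L), c(2L, 1L)),
    list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
         c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )

  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      diff_pos <- which(codon_mat[i, ] != codon_mat[j, ])
      d <- length(diff_pos)
      ndiff[i, j] <- ndiff[j, i] <- d
      if (d == 0L) next
      tot_n <- 0
      tot_s <- 0
      n_ok <- 0L
      for (ord in perms[[d]]) {
        cur <- codon_mat[i, ]
        pn <- 0L
        ps <- 0L
        ok <- TRUE
        for (p in diff_pos[ord]) {
          nxt <- cur
          nxt[p] <- codon_mat[j, p]
          to_codon <- paste(nxt, collapse = "")
          if (code[[to_codon]] == "*") {
            ok <- FALSE
            break
          }
          if (code[[paste(cur, collapse = "")]] == code[[to_codon]]) {
            ps <- ps + 1L
          } else {
            pn <- pn + 1L
          }
          cur <- nxt
        }
        if (ok) {
          tot_n <- tot_n + pn
          tot_s <- tot_s + ps
          n_ok <- n_ok + 1L
        }
      }
      if (n_ok == 0L) {
        # No stop-free ordering exists (does not arise for the standard code
        # with d <= 3, but guard anyway): split evenly.
        tot_n <- d
        tot_s <- 0
        n_ok <- 1L
      }
      nd[i, j] <- nd[j, i] <- tot_n / n_ok
      sd[i, j] <- sd[j, i] <- tot_s / n_ok
    }
  }
  list(nd = nd, sd = sd, ndiff = ndiff)
}

# Internal: codon string(s) -> state index, erroring on stops/unknown.
.codon_to_index <- function(codon) {
  tb <- codon_tables()
  codon <- toupper(codon)
  idx <- tb$codon_index[codon]
  if (anyNA(idx)) {
    bad <- codon[is.na(idx)]
    stop("not a sense codon: ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(idx)
}
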