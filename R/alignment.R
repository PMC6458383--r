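# Codon alignments: one gene, aligned nucleotide sequences over {A,C,G,T,-},
# viewed as codon columns. Gap bookkeeping is at codon-column resolution: a
# column is a "gap column" if any taxon has any gap character in its triplet.
# Columns are 1-based throughout (reports and internals alike).

#' Construct a codon alignment
#'
#' @param seqs Named character vector of aligned nucleotide sequences
#'   (equal lengths, length divisible by 3), or a character matrix of codons
#'   (taxa in rows) with 3-character entries.
#' @param gene Gene identifier.
#' @param stop_codons What to do when an ungapped sequence contains an
#'   internal stop codon: `"error"` (default) aborts naming the offender,
#'   `"mask"` replaces the codon with a gap.
#' @return An object of class `codon_alignment` with elements `gene`, `taxa`,
#'   `n_codons`, `codons` (taxa x columns character matrix of triplets),
#'   `gap_columns` (1-based indices of columns containing any gap).
#' @examples
#' aln <- codon_alignment(c(s1 = "ATGTTT", s2 = "ATGTTC"), gene = "g1")
#' gap_fraction(aln)
#' @export
codon_alignment <- function(seqs, gene = "gene", stop_codons = c("error", "mask")) {
  stop_codons <- match.arg(stop_codons)
  if (is.matrix(seqs)) {
    codons <- toupper(seqs)
  } else {
    if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
      stop("sequences must have unique taxon names", call. = FALSE)
    }
    seqs <- toupper(seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L) {
      stop("ragged alignment: sequence lengths ", paste(unique(lens), collapse = ", "),
           call. = FALSE)
    }
    if (lens[1] == 0L) stop("empty alignment", call. = FALSE)
    if (lens[1] %% 3L != 0L) {
      stop("alignment length ", lens[1], " is not divisible by 3", call. = FALSE)
    }
    n_codons <- lens[1] %/% 3L
    starts <- 3L * (seq_len(n_codons) - 1L) + 1L
    m <- vapply(seqs, function(s) substring(s, starts, starts + 2L),
                character(n_codons))
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    codons <- t(m)
    rownames(codons) <- names(seqs)
  }
  if (ncol(codons) == 0L) stop("empty alignment", call. = FALSE)

  ok_chars <- grepl("^[ACGT-]{3}$", codons)
  if (!all(ok_chars)) {
    stop("unexpected characters in codons: ",
         paste(utils::head(unique(codons[!ok_chars]), 5), collapse = ", "),
         call. = FALSE)
  }

  tb <- codon_tables()
  is_stop <- matrix(codons %in% names(tb$code)[tb$code == "*"], nrow(codons))
  if (any(is_stop)) {
    if (stop_codons == "error") {
      w <- which(is_stop, arr.ind = TRUE)[1, ]
      stop("internal stop codon in '", rownames(codons)[w[1]],
           "' at codon column ", w[2], call. = FALSE)
    }
    codons[is_stop] <- "---"
  }

  has_gap <- grepl("-", codons, fixed = TRUE)
  gap_columns <- which(apply(matrix(has_gap, nrow(codons)), 2, any))

  structure(
    list(gene = gene, taxa = rownames(codons), n_codons = ncol(codons),
         codons = codons, gap_columns = gap_columns),
    class = "codon_alignment"
  )
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment '", x$gene, "': ", length(x$taxa), " taxa, ",
      x$n_codons, " codon columns (", length(x$gap_columns),
      " with gaps)\n", sep = "")
  invisible(x)
}

#' Fraction of codon columns containing a gap
#' @param aln A `codon_alignment`.
#' @return Numeric scalar in \[0, 1\].
#' @export
gap_fraction <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  length(aln$gap_columns) / aln$n_codons
}

#' Indices of gapless codon columns
#' @param aln A `codon_alignment`.
#' @return Integer vector of 1-based column indices.
#' @export
gapless_columns <- function(aln) {
  setdiff(seq_len(aln$n_codons), aln$gap_columns)
}

# Internal: taxa x columns integer matrix of codon states (NA where the
# codon contains a gap).
.codon_state_matrix <- function(aln, columns = NULL) {
  tb <- codon_tables()
  if (is.null(columns)) columns <- seq_len(aln$n_codons)
  m <- aln$codons[, columns, drop = FALSE]
  idx <- tb$codon_index[m]
  out <- matrix(unname(idx), nrow = nrow(m),
                dimnames = list(aln$taxa, NULL))
  out
}

#' Read a codon alignment from a FASTA file
#'
#' Thin wrapper over [ape::read.FASTA()] with codon-alignment validation:
#' equal sequence lengths, length divisible by 3, gap columns indexed.
#'
#' @param path Path to an aligned FASTA file.
#' @param gene Gene identifier; defaults to the file name without extension.
#' @param stop_codons Passed to [codon_alignment()].
#' @return A `codon_alignment`.
#' @export
read_codon_fasta <- function(path, gene = NULL,
                             stop_codons = c("error", "mask")) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(gene)) gene <- sub("\\.[^.]*$", "", basename(path))
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("no sequences in ", path, call. = FALSE)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  codon_alignment(seqs, gene = gene, stop_codons = stop_codons)
}

#' Write a codon alignment to a FASTA file
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_fasta <- function(aln, path) {
  seqs <- apply(aln$codons, 1, paste, collapse = "")
  lines <- character(2L * length(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", aln$taxa)
  lines[c(FALSE, TRUE)] <- seqs
  writeLines(lines, path)
  invisible(path)
}
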