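# Nei-Gojobori (1986) counting machinery: synonymous / non-synonymous site
# counts, path-averaged classification of codon changes, the weak/strong
# substitution spectrum, and counting-based gene dN/dS with the Jukes-Cantor
# multiple-hit correction.

#' Nei-Gojobori synonymous and non-synonymous site counts
#'
#' Each codon position contributes to the synonymous site count the fraction
#' of its possible single-nucleotide changes that are synonymous; changes to
#' stop codons are removed from the denominator, so every sense codon
#' contributes exactly 3 sites in total. Gapped and non-sense codons are
#' skipped.
#'
#' @param x A nucleotide string (length divisible by 3), a character vector
#'   of codons, or a `codon_alignment` (sites are then averaged over taxa).
#' @param columns For an alignment, which codon columns to count
#'   (default: all gapless columns).
#' @return A list with `N` (non-synonymous sites), `S` (synonymous sites)
#'   and `codons` (ungapped codons counted; for an alignment, the number of
#'   columns counted).
#' @examples
#' ng86_sites("TTT")  # S = 1/3, N = 8/3
#' ng86_sites("ATGGGG")
#' @export
ng86_sites <- function(x, columns = NULL) {
  tb <- codon_tables()
  if (inherits(x, "codon_alignment")) {
    if (is.null(columns)) columns <- gapless_columns(x)
    if (!length(columns)) {
      warning("no columns to count; returning zero sites")
      return(list(N = 0, S = 0, codons = 0L))
    }
    states <- .codon_state_matrix(x, columns)
    per_taxon_s <- rowSums(matrix(tb$syn_sites[states], nrow(states)),
                           na.rm = TRUE)
    per_taxon_n <- rowSums(matrix(tb$nonsyn_sites[states], nrow(states)),
                           na.rm = TRUE)
    return(list(N = mean(per_taxon_n), S = mean(per_taxon_s),
                codons = length(columns)))
  }
  codons <- .as_codon_vector(x)
  if (!length(codons)) stop("empty sequence", call. = FALSE)
  keep <- !grepl("-", codons, fixed = TRUE)
  if (!any(keep)) {
    warning("all-gap sequence; returning zero sites")
    return(list(N = 0, S = 0, codons = 0L))
  }
  idx <- .codon_to_index(codons[keep])
  list(N = sum(tb$nonsyn_sites[idx]), S = sum(tb$syn_sites[idx]),
       codons = sum(keep))
}

.as_codon_vector <- function(x) {
  x <- toupper(x)
  if (length(x) == 1L && nchar(x) > 3L) {
    if (nchar(x) %% 3L != 0L) {
      stop("sequence length ", nchar(x), " is not divisible by 3",
           call. = FALSE)
    }
    starts <- seq(1L, nchar(x), by = 3L)
    x <- substring(x, starts, starts + 2L)
  }
  if (any(nchar(x) != 3L)) stop("codons must have 3 characters", call. = FALSE)
  x
}

#' Classify a codon change into synonymous and non-synonymous steps
#'
#' Codons differing at d nucleotide positions are connected by d! orderings
#' of single-nucleotide steps; orderings passing through a stop codon are
#' excluded, and synonymous / non-synonymous step counts are averaged with
#' equal weight over the remaining orderings (the unweighted Nei-Gojobori
#' convention). The result is symmetric in its arguments and may be
#' fractional.
#'
#' @param from,to Sense codons (3-character strings).
#' @return A list with `Nd` (non-synonymous steps), `Sd` (synonymous steps)
#'   and `ndiff` (number of differing nucleotides); `Nd + Sd == ndiff`.
#' @examples
#' classify_codon_path("TTT", "TTC")  # one synonymous step
#' classify_codon_path("TTT", "GTA")  # Nd = 1.5, Sd = 0.5
#' @export
classify_codon_path <- function(from, to) {
  tb <- codon_tables()
  i <- .codon_to_index(from)
  j <- .codon_to_index(to)
  list(Nd = tb$nd[i, j], Sd = tb$sd[i, j], ndiff = tb$ndiff[i, j])
}

#' Weak/strong substitution spectrum
#'
#' Counts single-nucleotide substitution events into the four exchange
#' categories between weak (A/T) and strong (G/C) bases.
#'
#' @param from,to Character vectors of single nucleotides (equal length),
#'   or a data.frame with columns `from_base` and `to_base` as produced by
#'   the simulator / event mapper.
#' @return Named integer vector with counts for `AT->GC`, `GC->AT`,
#'   `AT->AT`, `GC->GC`; the categories partition the events.
#' @export
substitution_spectrum <- function(from, to = NULL) {
  if (is.data.frame(from)) {
    to <- from$to_base
    from <- from$from_base
  }
  from <- toupper(from)
  to <- toupper(to)
  stopifnot(length(from) == length(to))
  if (!all(c(from, to) %in% DNA_BASES)) {
    stop("events must be single nucleotides in {A,C,G,T}", call. = FALSE)
  }
  if (any(from == to)) stop("event with identical from/to base", call. = FALSE)
  strong_from <- from %in% c("G", "C")
  strong_to <- to %in% c("G", "C")
  c(
    `AT->GC` = sum(!strong_from & strong_to),
    `GC->AT` = sum(strong_from & !strong_to),
    `AT->AT` = sum(!strong_from & !strong_to),
    `GC->GC` = sum(strong_from & strong_to)
  )
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p Proportion of observed substitutions per site, in \[0, 0.75).
#' @return Corrected distance `-(3/4) * log(1 - 4p/3)`; `NaN` with a warning
#'   when `p >= 0.75` (saturation).
#' @export
jc_correct <- function(p) {
  stopifnot(is.numeric(p), all(p >= 0))
  out <- ifelse(p < 0.75, -0.75 * log(1 - 4 * p / 3), NaN)
  if (anyNA(out) || any(is.nan(out))) {
    if (any(p >= 0.75)) warning("proportion at or beyond JC saturation (p >= 0.75)")
  }
  out
}

#' Counting-based gene dN/dS
#'
#' Sums mapped substitution counts over all tree edges except `exclude_edges`
#' (typically the burst-carrying run), converts to proportions per
#' Nei-Gojobori site, applies the Jukes-Cantor correction to each, and
#' returns their ratio. Mirrors the per-gene "overall dN/dS excluding the
#' burst edge" column of the scan report.
#'
#' @param events data.frame of substitution events with columns `edge`, `nd`,
#'   `sd` (fractional counts allowed).
#' @param N,S Non-synonymous and synonymous site counts for the gene.
#' @param exclude_edges Integer vector of edge indices to leave out.
#' @return A list with `dN`, `dS`, `dnds`, and `undefined` (`TRUE` when no
#'   synonymous substitutions remain, in which case `dnds` is `NA`, not an
#'   error).
#' @export
gene_dnds <- function(events, N, S, exclude_edges = integer(0)) {
  stopifnot(N > 0, S > 0)
  if (nrow(events)) {
    keep <- !(events$edge %in% exclude_edges)
    nd <- sum(events$nd[keep])
    sd <- sum(events$sd[keep])
  } else {
    nd <- sd <- 0
  }
  dn <- jc_correct(nd / N)
  ds <- jc_correct(sd / S)
  if (sd == 0) {
    return(list(dN = dn, dS = 0, dnds = NA_real_, undefined = TRUE))
  }
  list(dN = dn, dS = ds, dnds = dn / ds, undefined = FALSE)
}
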