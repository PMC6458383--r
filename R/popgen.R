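# Population-genetic back-of-envelope calculators used to interpret
# detected bursts: how long (in generations) a short edge is, how fast
# advantageous alleles fix, how often bursts happen per protein per unit of
# synonymous divergence, and a binomial enrichment test for functional
# categories among burst-carrying genes. "Approximately" figures in prose
# are produced by one-significant-figure rounding (see [prose_round()]).

#' Per-generation fixation probability of an advantageous mutation
#'
#' Each generation `2 N mu` copies of a mutation arise at a site (census
#' size N, per-nucleotide mutation rate mu) and each eventually fixes with
#' probability `2 s Ne / N`, giving `4 Ne mu s` fixations per generation.
#'
#' @param ne Effective population size (> 0).
#' @param mu Per-nucleotide per-generation mutation rate (> 0).
#' @param s Selection coefficient (>= 0).
#' @param n Optional census population size; a warning (not an error) is
#'   issued when `ne > n`, which is atypical.
#' @return Per-generation fixation probability `4 * ne * mu * s`.
#' @examples
#' fixation_probability(1e5, 1e-8, 1e-2)  # 4e-5
#' @export
fixation_probability <- function(ne, mu, s, n = NULL) {
  stopifnot(ne > 0, mu > 0, s >= 0)
  if (!is.null(n)) {
    stopifnot(n > 0)
    if (ne > n) warning("effective size exceeds census size (ne > n)")
  }
  4 * ne * mu * s
}

#' Generations spanned by an edge of given dS length
#'
#' With synonymous sites evolving at the neutral mutation rate, an edge of
#' length `ds` corresponds to `ds / mu` generations.
#'
#' @param ds Edge length in dS units (>= 0).
#' @param mu Per-nucleotide per-generation mutation rate (> 0).
#' @return A list with `generations` and `approx` (one significant figure).
#' @examples
#' edge_generations(0.004, 1e-8)  # 400000 generations
#' @export
edge_generations <- function(ds, mu) {
  stopifnot(ds >= 0)
  if (mu <= 0) stop("mu must be > 0", call. = FALSE)
  g <- ds / mu
  list(generations = g, approx = prose_round(g))
}

#' Generations available per substitution in a burst
#'
#' @param generations Total generations spanned by the edge (>= 0).
#' @param k Number of substitutions in the burst (>= 1).
#' @return A list with `per_substitution` and `approx` (one significant
#'   figure).
#' @examples
#' generations_per_substitution(4e5, 39)  # ~10000
#' @export
generations_per_substitution <- function(generations, k) {
  stopifnot(generations >= 0, k >= 1)
  g <- generations / k
  list(per_substitution = g, approx = prose_round(g))
}

#' Burst rate per protein per unit of synonymous divergence
#'
#' The number of detected bursts divided by (proteins scanned x total dS
#' length of the short internal edges searched): the probability that a
#' protein undergoes a detectable burst during the time needed for one
#' synonymous substitution per site.
#'
#' @param n_bursts Number of detected bursts (>= 0).
#' @param n_proteins Number of proteins scanned (> 0).
#' @param total_ds Total dS length of the searched edges (> 0).
#' @return A list with `rate` and `approx` (one significant figure).
#' @examples
#' burst_rate(5, 3411, 0.15)  # ~0.01
#' @export
burst_rate <- function(n_bursts, n_proteins, total_ds) {
  stopifnot(n_bursts >= 0)
  if (n_proteins <= 0 || total_ds <= 0) {
    stop("n_proteins and total_ds must be > 0", call. = FALSE)
  }
  r <- n_bursts / (n_proteins * total_ds)
  list(rate = r, approx = prose_round(r))
}

#' Upper-tail binomial enrichment test
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)`: enrichment of a category (e.g.
#' mitochondrial annotation) among burst-carrying genes against its
#' background frequency.
#'
#' @param k Observed category members among the hits (0 <= k <= n).
#' @param n Number of hits.
#' @param p0 Background category frequency in (0, 1).
#' @return Exact upper-tail probability.
#' @examples
#' enrichment_binomial(3, 5, 0.14)  # 0.022
#' @export
enrichment_binomial <- function(k, n, p0) {
  stopifnot(k == floor(k), n == floor(n))
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n", call. = FALSE)
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)", call. = FALSE)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' One-significant-figure rounding for report prose
#'
#' @param x Numeric.
#' @return `signif(x, 1)`.
#' @export
prose_round <- function(x) signif(x, 1)
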