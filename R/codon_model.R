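# Reversible 61-state codon substitution model with HKY-style nucleotide
# exchangeability (transition/transversion ratio kappa), a non-synonymous
# rate multiplier omega, and arbitrary stationary codon frequencies.
#
# The rate matrix is scaled so that *branch lengths are in dS units*: one
# unit of branch length produces, at stationarity, one expected synonymous
# substitution per Nei-Gojobori synonymous site. This makes tree edge
# lengths (given in dS) directly usable as evolutionary times, for any
# omega, because synonymous rates do not depend on omega.

#' Construct a reversible codon substitution model
#'
#' Off-diagonal rates between codons differing at one nucleotide are
#' `pi_j * kappa^[transition] * omega^[non-synonymous]`; all other rates are
#' zero. The matrix is rescaled so branch lengths are in dS units (see
#' [subs_per_codon()]).
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Non-synonymous/synonymous rate ratio (>= 0); `omega = 1` is
#'   the neutral null used by the burst test.
#' @param freqs Stationary codon frequencies over the 61 sense codons in
#'   state order (positive, summing to 1); default equal frequencies.
#' @return An object of class `codon_model`: `Q` (61 x 61 generator, dS
#'   units), `freqs`, `kappa`, `omega`, `syn_flow` (= mean NG86 synonymous
#'   sites per codon, by construction), `nonsyn_flow`, `total_flow` (expected
#'   substitutions per codon per unit dS), plus the eigendecomposition of the
#'   symmetrized generator used by [transition_matrix()].
#' @examples
#' m <- codon_model(kappa = 2, omega = 1)
#' m$total_flow  # substitutions per codon per dS unit
#' @export
codon_model <- function(kappa = 2, omega = 1, freqs = NULL) {
  stopifnot(kappa > 0, omega >= 0)
  tb <- codon_tables()
  n <- length(tb$codons)
  if (is.null(freqs)) {
    freqs <- rep(1 / n, n)
  } else {
    stopifnot(length(freqs) == n, all(freqs > 0))
    freqs <- freqs / sum(freqs)
  }

  nb <- tb$neighbors
  rate <- freqs[nb$to] * ifelse(nb$transition, kappa, 1) *
    ifelse(nb$syn, 1, omega)
  Q <- matrix(0, n, n)
  Q[cbind(nb$from, nb$to)] <- rate

  syn_flow <- sum(freqs[nb$from] * rate * nb$syn)
  sbar <- sum(freqs * tb$syn_sites)  # mean synonymous sites per codon
  if (syn_flow <= 0) stop("degenerate model: zero synonymous flow")
  Q <- Q * (sbar / syn_flow)
  diag(Q) <- -rowSums(Q)

  # Symmetrize (reversibility) and eigendecompose once; transition matrices
  # for any branch length then cost one similarity transform.
  sq <- sqrt(freqs)
  B <- Q * outer(sq, 1 / sq)
  asym <- max(abs(B - t(B)))
  if (asym > 1e-10) {
    stop("rate matrix violates detailed balance (asymmetry ", asym, ")")
  }
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)

  nonsyn_flow <- sum(freqs[nb$from] * Q[cbind(nb$from, nb$to)] * (!nb$syn))
  structure(
    list(Q = Q, freqs = freqs, kappa = kappa, omega = omega,
         syn_flow = sbar, nonsyn_flow = nonsyn_flow,
         total_flow = sbar + nonsyn_flow,
         eig_values = eig$values,
         eig_right = eig$vectors / sq,     # diag(1/sq) %*% U
         eig_left = t(eig$vectors * sq)),  # t(U) %*% diag(sq)
    class = "codon_model"
  )
}

#' @export
print.codon_model <- function(x, ...) {
  cat("Codon model (61 sense codons): kappa =", x$kappa,
      ", omega =", x$omega,
      "\n  branch-length unit: dS;", format(x$total_flow, digits = 4),
      "expected substitutions per codon per dS\n")
  invisible(x)
}

#' Expected substitutions per codon site for a branch of given dS length
#'
#' Pure unit conversion between dS branch lengths and expected substitutions
#' per codon site under the model (synonymous + non-synonymous flow at
#' stationarity).
#'
#' @param model A `codon_model`.
#' @param ds Branch length(s) in dS units.
#' @return Expected substitutions per codon site.
#' @export
subs_per_codon <- function(model, ds) {
  stopifnot(inherits(model, "codon_model"), all(ds >= 0))
  ds * model$total_flow
}

#' Codon transition probability matrix for a branch
#'
#' Computes `expm(Q * t)` through the cached eigendecomposition of the
#' symmetrized reversible generator; tiny negative entries from roundoff are
#' clipped and rows renormalized.
#'
#' @param model A `codon_model`.
#' @param t Branch length in dS units (>= 0).
#' @return 61 x 61 stochastic matrix.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "codon_model"), t >= 0)
  if (t == 0) return(diag(length(model$freqs)))
  P <- model$eig_right %*% (exp(model$eig_values * t) * model$eig_left)
  P[P < 0] <- 0
  P / rowSums(P)
}
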