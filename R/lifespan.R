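# Motif lifespan predictions and Wright-Fisher diffusion formulas.

#' Parameters of the motif-loss prediction
#'
#' @param mu mutation rate per bp per generation (default 1.2e-8).
#' @param k number of disruptible motif positions (default 11, the non-N
#'   sites of the 13-bp hotspot motif).
#' @param T generations over which loss is predicted (default 1e5, about
#'   3 MYR in humans).
#' @param N diploid effective population size (used by the diffusion
#'   formulas; default 10000).
#' @return A validated list of class `"LifespanParams"`.
#' @examples
#' lifespanParams()
#' @export
lifespanParams <- function(mu = 1.2e-8, k = 11, T = 1e5, N = 10000) {
  stopifnot(mu > 0, k > 0, T > 0, N >= 2)
  structure(list(mu = mu, k = k, T = T, N = N), class = "LifespanParams")
}

#' Probability that a motif acquires a disrupting substitution
#'
#' Under the fixation-bias model, conversion of intensity G multiplies the
#' neutral substitution rate by the relative fixation factor
#' `G / (1 - exp(-G))` (its G -> 0 limit is 1), so the probability that at
#' least one of the k disruptible sites substitutes within T generations is
#' `P = 1 - exp(-mu * k * T * G / (1 - exp(-G)))`.
#' Stable at both extremes of G.
#'
#' @param G non-negative conversion coefficient (vectorised).
#' @param params a [lifespanParams()] list.
#' @return Loss probabilities in [0, 1].
#' @examples
#' lossProbability(0)     # neutral: 1 - exp(-mu k T)
#' lossProbability(174)
#' @export
lossProbability <- function(G, params = lifespanParams()) {
  if (any(G < 0)) stop("G must be non-negative")
  fac <- ifelse(G < 1e-10, 1, G / (-expm1(-G)))
  -expm1(-params$mu * params$k * params$T * fac)
}

#' Mean loss probability over a distribution of G
#'
#' Averages [lossProbability()] over a gamma law for G (optionally
#' conditioned to a quantile range, e.g. the top 8% of motifs), by adaptive
#' quadrature on the probability scale. A zero-rate point mass in the
#' distribution contributes `lossProbability(0)` in proportion to its
#' weight (the atom occupies the lowest quantiles).
#'
#' @param dist a [GDistribution-class].
#' @param params a [lifespanParams()] list.
#' @param quantileRange `c(qLo, qHi)` with `0 <= qLo < qHi <= 1`; the
#'   expectation is conditional on G between those quantiles of the full
#'   (atom + gamma) law.
#' @return The mean loss probability (scalar in [0, 1]).
#' @examples
#' d <- gDistribution(shape = 0.28, mean = 28.2)
#' expectedLossFraction(d)                      # all motifs
#' expectedLossFraction(d, quantileRange = c(0.92, 1))  # top 8%
#' @export
expectedLossFraction <- function(dist, params = lifespanParams(),
                                 quantileRange = c(0, 1)) {
  qLo <- quantileRange[1]; qHi <- quantileRange[2]
  if (!(qLo >= 0 && qHi <= 1 && qLo < qHi)) stop("empty quantile range")
  z <- dist@zeroFraction
  shape <- dist@shape
  scale <- if (shape > 0 && dist@mean > 0) dist@mean / shape else 0
  # quantile u of the mixed law: u <= z -> G = 0; else gamma quantile
  qmix <- function(u) {
    out <- numeric(length(u))
    pos <- u > z
    out[pos] <- qgamma((u[pos] - z) / (1 - z), shape = shape, scale = scale)
    out
  }
  if (scale == 0) return(lossProbability(0, params))
  f <- function(u) lossProbability(qmix(u), params)
  integrate(f, qLo, qHi, rel.tol = 1e-9, subdivisions = 400L)$value /
    (qHi - qLo)
}

#' Calibrate a gamma law from a conditional tail mean
#'
#' Solves for the gamma mean M such that the conditional mean of G above
#' its `tailQ` quantile equals `targetTailMean`, at fixed shape, by
#' monotone root finding (the conditional tail mean is linear in the scale,
#' so the root is unique). If `rateMean` is supplied, the implied
#' proportionality constant `c = M / rateMean` is also returned.
#'
#' @param shape gamma shape (e.g. 0.28, inherited from the crossover-rate
#'   fit).
#' @param tailQ tail-defining quantile (e.g. 0.92 for the top 8%).
#' @param targetTailMean target conditional mean of G in the tail.
#' @param rateMean optional mean crossover rate M_X.
#' @return A [GDistribution-class] with the solved mean.
#' @examples
#' calibrateTailMean(0.28, 0.92, 174, rateMean = 5.02)
#' @export
calibrateTailMean <- function(shape, tailQ, targetTailMean,
                              rateMean = NA_real_) {
  stopifnot(shape > 0, tailQ > 0, tailQ < 1, targetTailMean > 0)
  tailMeanOf <- function(M) {
    y0 <- qgamma(tailQ, shape)
    M * (1 - pgamma(y0, shape + 1)) / (1 - tailQ)
  }
  f <- function(M) tailMeanOf(M) - targetTailMean
  hi <- targetTailMean
  if (f(hi) < 0) stop("no root in bracket: tail mean below target at M = ",
                      hi, " (tail mean ", tailMeanOf(hi), ")")
  M <- uniroot(f, c(1e-12, hi), tol = 1e-10 * targetTailMean)$root
  gDistribution(shape = shape, mean = M, rateMean = rateMean)
}

#' Kimura fixation probability of a converted allele
#'
#' Diffusion fixation probability of an allele with population-scaled
#' conversion coefficient G = 4N*g starting at frequency x0:
#' `u = (1 - exp(-G x0)) / (1 - exp(-G))`, with the neutral limit x0.
#'
#' @param G non-negative conversion coefficient (vectorised).
#' @param N diploid population size.
#' @param x0 initial frequency (default a single new mutant, 1/(2N)).
#' @return Fixation probabilities.
#' @examples
#' kimuraFixationProbability(0, 1000)    # 1/(2N)
#' kimuraFixationProbability(20, 1000)
#' @export
kimuraFixationProbability <- function(G, N, x0 = 1 / (2 * N)) {
  stopifnot(N >= 2, all(x0 > 0), all(x0 < 1))
  if (any(G < 0)) stop("G must be non-negative")
  ifelse(G < 1e-10, x0, (-expm1(-G * x0)) / (-expm1(-G)))
}

#' Kimura-Ohta mean fixation time, conditional on fixation
#'
#' Mean number of generations a new semidominant mutant with conversion
#' coefficient G = 4N*g takes to fix, given that it fixes, from the
#' diffusion sojourn-time integrals. With scale density
#' `psi(x) = exp(-G x)` the conditional sojourn density splits at the
#' starting frequency p; the upper part simplifies to the numerically
#' stable form
#' `t(x) = 2 * expm1-form(G(1-x))/G * u(x) * 2N/(x(1-x))`
#' which removes the catastrophic cancellation of `(S(1)-S(x))/psi(x)` at
#' large G; both parts are integrated adaptively (relative tolerance
#' 1e-9). The neutral limit is 4N(1 - p/2) ~ 4N generations.
#'
#' @param G non-negative conversion coefficient.
#' @param N diploid population size.
#' @param x0 initial frequency (default 1/(2N), a new mutant).
#' @return Mean conditional fixation time in generations.
#' @examples
#' kimuraMeanFixationTime(0, 1000)     # ~ 4N
#' kimuraMeanFixationTime(20, 1000)
#' @export
kimuraMeanFixationTime <- function(G, N, x0 = 1 / (2 * N)) {
  stopifnot(N >= 2, x0 > 0, x0 < 1)
  if (G < 0) stop("G must be non-negative")
  p <- x0
  if (G < 1e-8) {
    up <- integrate(function(x) rep(4 * N, length(x)), p, 1,
                    rel.tol = 1e-10)$value
    dn <- integrate(function(x) 4 * N * x * (1 - p) / p, 0, p,
                    rel.tol = 1e-10)$value
    return(up + dn)
  }
  S1 <- -expm1(-G) / G
  Sp <- -expm1(-G * p) / G
  fUp <- function(x)
    2 * (-expm1(-G * (1 - x)) / G) * (-expm1(-G * x) / (-expm1(-G))) *
      2 * N / (x * (1 - x))
  fDn <- function(x) {
    Sx <- -expm1(-G * x) / G
    2 * Sx^2 * exp(G * x) * (S1 - Sp) / (S1 * Sp) * 2 * N / (x * (1 - x))
  }
  up <- integrate(fUp, p, 1, rel.tol = 1e-9, subdivisions = 1000L)$value
  dn <- integrate(fDn, 0, p, rel.tol = 1e-9, subdivisions = 1000L)$value
  up + dn
}
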