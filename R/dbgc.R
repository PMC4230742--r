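# Poisson random-field estimation of the population-scaled conversion
# coefficient G from paired DAF spectra.

#' Sojourn density of a converted allele
#'
#' Expected time a new semidominant allele with population-scaled
#' conversion coefficient G = 4Ne*g spends at population frequency x before
#' absorption (diffusion approximation, per unit 2*Ne*u influx):
#' `H(x, 0) = 2/x` and, for G > 0,
#' `H(x, G) = 2 (1 - exp(-G(1-x))) / (x (1-x) (1 - exp(-G)))`.
#' Evaluation uses `expm1` so it is stable from the neutral limit up to
#' G of order 1e5.
#'
#' @param x frequencies strictly inside (0, 1) (vectorised).
#' @param G non-negative conversion coefficient.
#' @return `H(x, G)`, same length as `x`.
#' @examples
#' sojournDensity(0.5, 0)   # = 4
#' sojournDensity(0.3, 10)
#' @export
sojournDensity <- function(x, G) {
  stopifnot(length(G) == 1L, is.finite(G))
  if (G < 0) stop("G must be non-negative")
  if (any(x <= 0 | x >= 1)) stop("x must lie strictly inside (0, 1)")
  if (G == 0) return(2 / x)
  2 * (-expm1(-G * (1 - x))) / (x * (1 - x) * (-expm1(-G)))
}

#' Default DAF bin edges
#'
#' First bin `[1/nChrom, 0.01)` (rare variants), then `m` equal-width bins
#' partitioning `[0.01, 1)`.
#'
#' @param nChrom sample size n (must exceed 100 so that 1/n < 0.01).
#' @param m number of bins above 0.01.
#' @return Numeric vector of m + 2 edges.
#' @examples
#' dafBinEdges(2184, 10)
#' @export
dafBinEdges <- function(nChrom, m = 10L) {
  stopifnot(nChrom > 100L, m >= 1L)
  c(1 / nChrom, seq(0.01, 1, length.out = m + 1L))
}

#' Bin derived-allele frequencies into spectrum counts
#'
#' Values with `daf >= 1` are treated as fixed and excluded from the bins
#' (returned in the `fixed` attribute); values below the first edge are
#' dropped.
#'
#' @param daf numeric DAF values in (0, 1].
#' @param edges bin edges, bin j being `[edges[j], edges[j+1])`.
#' @return Integer counts per bin with attribute `fixed`.
#' @export
binDafCounts <- function(daf, edges) {
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  daf <- daf[!is.na(daf)]
  fixed <- sum(daf >= 1)
  daf <- daf[daf < 1 & daf >= edges[1]]
  counts <- as.integer(table(cut(daf, edges, right = FALSE,
                                 include.lowest = FALSE)))
  attr(counts, "fixed") <- fixed
  counts
}

# Integral of H(x, G) over one interval, adaptive quadrature.
.binIntegral <- function(lo, hi, G) {
  integrate(sojournDensity, lo, hi, G = G,
            rel.tol = 1e-10, subdivisions = 500L)$value
}

# Vector of per-bin sojourn integrals for a set of edges (adaptive; the
# reference-grade path used by expectedBinCounts).
.binIntegrals <- function(edges, G) {
  vapply(seq_len(length(edges) - 1L),
         function(j) .binIntegral(edges[j], edges[j + 1L], G), numeric(1))
}

# ---- fast fixed-node quadrature used inside the likelihood loops -------
# 24-point Gauss-Legendre on (0,1), cached.
.glEnv <- new.env(parent = emptyenv())
.gl24 <- function() {
  if (is.null(.glEnv$g)) .glEnv$g <- gaussLegendre(24L, 0, 1)
  .glEnv$g
}

# GL in log-x (exact for the neutral 2/x integrand; compresses the wide
# first bin).
.quadLog <- function(a, b, G) {
  g <- .gl24()
  la <- log(a); lb <- log(b)
  x <- exp(la + g$x * (lb - la))
  sum(g$w * (lb - la) * x * sojournDensity(x, G))
}

.quadLin <- function(a, b, G) {
  g <- .gl24()
  x <- a + g$x * (b - a)
  sum(g$w * (b - a) * sojournDensity(x, G))
}

# GL in log(1-x), for panels hugging x = 1 where 1/(1-x) dominates.
.quadLog1m <- function(a, b, G) {
  g <- .gl24()
  la <- log1p(-b); lb <- log1p(-a)      # t = 1-x decreasing in x
  t <- exp(la + g$x * (lb - la))
  sum(g$w * (lb - la) * t * sojournDensity(1 - t, G))
}

# Fast per-bin integrals: log-x GL per bin; for large G the bin touching
# x = 1 is split at the 1 - 20/G boundary layer so the e^(-G(1-x))
# transition is resolved. Agrees with the adaptive path to ~1e-10
# relative (asserted in the test suite).
.binIntegralsFast <- function(edges, G) {
  nb <- length(edges) - 1L
  out <- numeric(nb)
  for (j in seq_len(nb)) {
    a <- edges[j]; b <- edges[j + 1L]
    if (G > 50 && b > 1 - 20 / G) {
      cpt <- max(a, 1 - 20 / G)
      out[j] <- (if (cpt > a) .quadLog1m(a, cpt, G) else 0) +
        (if (b > cpt) .quadLin(cpt, b, G) else 0)
    } else {
      out[j] <- .quadLog(a, b, G)
    }
  }
  out
}

#' Expected spectrum counts under the Poisson-field model
#'
#' Per-bin expectation `r_j * scale * integral of H(x, G) over bin j`. The
#' continuous approximation collapses the binomial sampling of i alleles
#' out of n onto the true frequency, valid when n is large;
#' `method = "discrete"` instead sums the exact binomial-sampled class
#' expectations (the small-n oracle) over the classes whose i/n falls in
#' each bin.
#'
#' @param G conversion coefficient (0 for the neutral class).
#' @param edges bin edges; the first edge must be positive (H is integrable
#'   only away from 0 -- it starts at 1/n).
#' @param scale mutation-scale multiplier (theta*L analog).
#' @param r per-bin distortion multipliers, recycled; `r[1]` conventionally 1.
#' @param nChrom sample size, required for `method = "discrete"`.
#' @param method `"continuous"` (default) or `"discrete"`.
#' @return Numeric vector of per-bin expected counts.
#' @examples
#' expectedBinCounts(0, dafBinEdges(2184, 5), scale = 32.5)
#' @export
expectedBinCounts <- function(G, edges, scale = 1, r = 1, nChrom = NULL,
                              method = c("continuous", "discrete")) {
  method <- match.arg(method)
  if (any(diff(edges) <= 0)) stop("bin edges must be strictly increasing")
  if (edges[1] <= 0)
    stop("first bin edge must be positive (use 1/nChrom)")
  nb <- length(edges) - 1L
  r <- rep_len(r, nb)
  if (method == "continuous") {
    ints <- .binIntegrals(edges, G)
  } else {
    if (is.null(nChrom)) stop("nChrom is required for the discrete method")
    cls <- expectedClassCounts(G, nChrom, scale = 1)
    f <- (seq_len(nChrom - 1L)) / nChrom
    idx <- findInterval(f, edges, rightmost.closed = FALSE)
    ints <- vapply(seq_len(nb), function(j) sum(cls[idx == j]), numeric(1))
  }
  r * scale * ints
}

#' Exact discrete class expectations (binomial sampling)
#'
#' Expected number of SNPs observed with i derived copies out of n,
#' `scale * choose(n,i) * integral x^i (1-x)^(n-i) H(x, G) dx`, for
#' i = 1..n-1. This is the exact finite-sample counterpart of the
#' continuous approximation; at G = 0 it reduces to `2 * scale / i`.
#'
#' @param G conversion coefficient.
#' @param nChrom sample size n.
#' @param scale mutation-scale multiplier.
#' @return Numeric vector of length n - 1 (classes i = 1..n-1).
#' @export
expectedClassCounts <- function(G, nChrom, scale = 1) {
  n <- as.integer(nChrom)
  if (G == 0) return(2 * scale / seq_len(n - 1L))
  vapply(seq_len(n - 1L), function(i) {
    f <- function(x)
      exp(lchoose(n, i) + i * log(x) + (n - i) * log1p(-x)) *
        sojournDensity(x, G)
    scale * integrate(f, 0, 1, rel.tol = 1e-9, subdivisions = 500L)$value
  }, numeric(1))
}

# Poisson log-likelihood (factorial terms dropped) with the distortions
# r_j (j >= 2) profiled out: r_j = (kN_j + kT_j) / (a I0_j + b IG_j).
# Bin 1 has r_1 = 1. Returns lnL and the profiled r if wanted.
.profileLnL <- function(a, b, kN, kT, I0, IG, returnR = FALSE) {
  nb <- length(kN)
  r <- numeric(nb)
  r[1] <- 1
  denom <- a * I0 + b * IG
  tot <- kN + kT
  r[-1] <- ifelse(denom[-1] > 0, tot[-1] / denom[-1], 0)
  muN <- r * a * I0
  muT <- r * b * IG
  ll <- sum(ifelse(kN > 0, kN * log(pmax(muN, 1e-300)), 0) - muN) +
        sum(ifelse(kT > 0, kT * log(pmax(muT, 1e-300)), 0) - muT)
  if (returnR) list(lnL = ll, r = r, muN = muN, muT = muT) else ll
}

# Maximize over (a, b) for fixed bin integrals; returns list(lnL, a, b).
# `start` allows warm starts along a G search path.
.fitScales <- function(kN, kT, I0, IG, start = NULL) {
  if (is.null(start))
    start <- c(log(max(sum(kN) / sum(I0), 1e-8)),
               log(max(sum(kT) / sum(IG), 1e-8)))
  obj <- function(p) -.profileLnL(exp(p[1]), exp(p[2]), kN, kT, I0, IG)
  opt <- nlminb(start, obj,
                control = list(rel.tol = 1e-12, abs.tol = 1e-12))
  list(lnL = -opt$objective, a = exp(opt$par[1]), b = exp(opt$par[2]),
       par = opt$par, convergence = opt$convergence)
}

# Saturated log-likelihood: every cell mean free => mu = k.
.lnLSaturated <- function(kN, kT) {
  k <- c(kN, kT)
  sum(ifelse(k > 0, k * log(k) - k, 0))
}

#' Fit the conversion-intensity model to a paired DAF spectrum
#'
#' Maximizes the Poisson log-likelihood of the binned neutral and test
#' spectra over the per-class mutation scales, the shared per-bin
#' demographic distortions r_j (r_1 = 1, profiled in closed form), and --
#' for model M1 -- the conversion coefficient G >= 0. G is searched on a
#' log grid of starts (0.1, 1, 10, 100, 1000) followed by bounded
#' refinement; the G = 0 boundary (= M0) is always considered. The
#' likelihood-ratio statistic against M0 is reported with a
#' boundary-corrected p-value (1/2 chi-square(1) mixture, appropriate when
#' the null value G = 0 lies on the parameter boundary), the goodness of
#' fit as the deviance against the saturated model, and the confidence
#' interval by profiling G (all other parameters held at their optima)
#' until the log-likelihood falls two points below the maximum.
#'
#' @param spectrum a [DAFSpectrum-class].
#' @param model `"M1"` (constant conversion, default) or `"M0"`.
#' @param ci compute the confidence interval (M1 only).
#' @param ciMethod `"profile"` (default): genuine profile likelihood,
#'   re-optimizing the scales and distortions at each candidate G;
#'   `"fixed"`: hold the nuisance parameters at their optima while varying
#'   G (narrower, anti-conservative -- provided for comparability with
#'   analyses that used it).
#' @param gMax upper bound of the G search; likelihoods are nearly flat
#'   above G of a few tens, so the upper limit may be reported as `Inf`
#'   when the drop of two log-likelihood points is never reached.
#' @return A [DbgcFit-class].
#' @examples
#' cfg <- simConfig(seed = 3, gTrue = 10)
#' sp <- simulateDafSpectrum(cfg)
#' fitDbgc(sp)
#' @export
fitDbgc <- function(spectrum, model = c("M1", "M0"), ci = TRUE,
                    ciMethod = c("profile", "fixed"), gMax = 1e5) {
  model <- match.arg(model)
  ciMethod <- match.arg(ciMethod)
  kN <- spectrum@countsNeutral
  kT <- spectrum@countsTest
  edges <- spectrum@edges
  if (sum((kN + kT) > 0) < 2L)
    stop("need at least 2 bins with nonzero total count")
  I0 <- .binIntegralsFast(edges, 0)

  fit0 <- .fitScales(kN, kT, I0, I0)
  lnLM0 <- fit0$lnL
  lnLSat <- .lnLSaturated(kN, kT)

  if (model == "M0") {
    pr <- .profileLnL(fit0$a, fit0$b, kN, kT, I0, I0, returnR = TRUE)
    nPar <- (length(kN) - 1L) + 2L
    return(new("DbgcFit", model = "M0", gHat = 0, ciLo = 0, ciHi = 0,
               rHat = pr$r, scaleNeutral = fit0$a, scaleTest = fit0$b,
               lnL = lnLM0, lnLM0 = lnLM0, lnLSaturated = lnLSat,
               lrt = 0, pLrt = 1, gof = 2 * (lnLSat - lnLM0),
               gofDf = 2 * sum((kN + kT) > 0) - nPar,
               details = list(convergence = fit0$convergence)))
  }

  warm <- fit0$par
  profLnL <- function(G) {
    IG <- .binIntegralsFast(edges, G)
    ft <- .fitScales(kN, kT, I0, IG, start = warm)
    warm <<- ft$par
    ft
  }
  # coarse multi-start log grid, then bounded refinement around the best
  lgrid <- log(10) * seq(-2, log10(gMax), by = 0.5)
  gridLnL <- vapply(lgrid, function(lg) profLnL(exp(lg))$lnL, numeric(1))
  iBest <- which.max(gridLnL)
  lo <- lgrid[max(1L, iBest - 1L)]
  hi <- lgrid[min(length(lgrid), iBest + 1L)]
  opt <- optim(lgrid[iBest], function(lg) -profLnL(exp(lg))$lnL,
               method = "Brent", lower = lo, upper = hi,
               control = list(reltol = 1e-10))
  best <- list(G = exp(opt$par), lnL = -opt$value)
  # boundary: if no interior improvement over M0, the MLE is G = 0
  if (best$lnL <= lnLM0 + 1e-9) {
    gHat <- 0
    fitG <- fit0
    IGhat <- I0
  } else {
    gHat <- best$G
    IGhat <- .binIntegralsFast(edges, gHat)
    fitG <- .fitScales(kN, kT, I0, IGhat, start = warm)
  }
  lnL1 <- max(fitG$lnL, lnLM0)
  pr <- .profileLnL(fitG$a, fitG$b, kN, kT, I0, IGhat, returnR = TRUE)
  lrt <- max(0, 2 * (lnL1 - lnLM0))
  # G >= 0 boundary null: LRT ~ 1/2 chi2_0 + 1/2 chi2_1
  pLrt <- if (lrt == 0) 1 else 0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)

  ciLo <- ciHi <- NA_real_
  if (ci) {
    lnLat <- if (ciMethod == "profile") {
      function(G) profLnL(G)$lnL
    } else {
      function(G) {
        IG <- .binIntegralsFast(edges, G)
        muN <- pr$r * fitG$a * I0
        muT <- pr$r * fitG$b * IG
        sum(ifelse(kN > 0, kN * log(pmax(muN, 1e-300)), 0) - muN) +
          sum(ifelse(kT > 0, kT * log(pmax(muT, 1e-300)), 0) - muT)
      }
    }
    target <- lnL1 - 2
    f <- function(G) lnLat(G) - target
    gLoBound <- 1e-6
    lnL0ci <- if (ciMethod == "profile") lnLM0 else lnLat(gLoBound)
    ciLo <- if (gHat <= gLoBound || lnL0ci >= target) 0 else
      uniroot(f, c(gLoBound, gHat), tol = 1e-8)$root
    ciHi <- if (f(gMax) >= 0) Inf else
      exp(uniroot(function(lg) f(exp(lg)),
                  c(log(max(gHat, gLoBound)), log(gMax)), tol = 1e-8)$root)
  }

  nPar <- (length(kN) - 1L) + 3L
  new("DbgcFit", model = "M1", gHat = gHat, ciLo = ciLo, ciHi = ciHi,
      rHat = pr$r, scaleNeutral = fitG$a, scaleTest = fitG$b,
      lnL = lnL1, lnLM0 = lnLM0, lnLSaturated = lnLSat,
      lrt = lrt, pLrt = pLrt, gof = 2 * (lnLSat - lnL1),
      gofDf = 2 * sum((kN + kT) > 0) - nPar,
      details = list(convergence = fitG$convergence, ciMethod = ciMethod))
}

#' @describeIn fitDbgc profile-likelihood interval of a fitted model.
#' @param object a [DbgcFit-class].
#' @param parm,level ignored (the interval is the stored two-point profile).
#' @param ... ignored.
#' @export
setMethod("confint", "DbgcFit", function(object, parm, level = 0.95, ...) {
  c(lower = object@ciLo, upper = object@ciHi)
})

#' Fit a gamma law to per-motif crossover rates
#'
#' Maximum-likelihood gamma fit on the strictly positive rates; exact zeros
#' are excluded from the MLE and reported as a point-mass fraction (mapped
#' to G = 0 by the proportional model). The shape MLE solves
#' `log(shape) - digamma(shape) = log(mean(x)) - mean(log(x))` by monotone
#' root finding; the scale follows as `mean(x)/shape`. A near-constant
#' input (shape diverging) is flagged degenerate.
#'
#' @param rates non-negative per-motif rates (cM/Mb), at least 10 positive.
#' @return A list with `mean`, `shape`, `zeroFraction`, `n`, `degenerate`.
#' @examples
#' set.seed(1)
#' fitGammaToRates(rgamma(500, shape = 0.28, scale = 5.02 / 0.28))
#' @export
fitGammaToRates <- function(rates) {
  if (any(rates < 0) || any(!is.finite(rates))) stop("rates must be finite and >= 0")
  x <- rates[rates > 0]
  if (length(x) < 10L) stop("need at least 10 positive rates")
  zf <- 1 - length(x) / length(rates)
  s <- log(mean(x)) - mean(log(x))   # >= 0 by Jensen, 0 iff constant
  if (s < 1e-12) {
    return(list(mean = mean(x), shape = Inf, zeroFraction = zf,
                n = length(x), degenerate = TRUE))
  }
  g <- function(a) log(a) - digamma(a) - s
  # g is decreasing in a; bracket then root-find
  lo <- 1e-8; hi <- 1
  while (g(hi) > 0) hi <- hi * 10
  shape <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  list(mean = mean(x), shape = shape, zeroFraction = zf, n = length(x),
       degenerate = FALSE)
}

# Gauss-Legendre nodes/weights on (0,1) for averaging over the gamma law
# of G via the probability-integral transform.
.gaussNodes01 <- function(n = 48L) {
  gl <- gaussLegendre(n, 0, 1)
  list(x = gl$x, w = gl$w)
}

# Per-bin expectations averaged over G ~ gamma(shape, mean MG) with a
# zero-mass atom at G = 0.
.avgBinIntegrals <- function(edges, MG, shape, zeroFraction = 0, nodes) {
  if (MG <= 0) return(.binIntegrals(edges, 0))
  Gs <- qgamma(nodes$x, shape = shape, scale = MG / shape)
  Gs <- pmin(pmax(Gs, 1e-10), 1e7)
  acc <- 0
  for (q in seq_along(Gs))
    acc <- acc + nodes$w[q] * .binIntegralsFast(edges, Gs[q])
  zeroFraction * .binIntegralsFast(edges, 0) + (1 - zeroFraction) * acc
}

#' Fit the recombination-proportional conversion model
#'
#' Models G = c * X where X is the local crossover rate, gamma-distributed
#' with the mean and shape of `rateFit` (see [fitGammaToRates()]); G then
#' follows a gamma law with the same shape and mean `c * rateMean`. The
#' spectrum expectations are the sojourn integrals averaged over that law
#' by Gauss-Legendre quadrature on the probability scale, and c is
#' maximized by profile likelihood exactly as in [fitDbgc()]. `c = 0`
#' reduces to M0.
#'
#' @param spectrum a [DAFSpectrum-class].
#' @param rateFit list with `mean`, `shape` and optionally `zeroFraction`,
#'   as returned by [fitGammaToRates()].
#' @param ci compute a profile-likelihood interval on c (two
#'   log-likelihood points below the maximum; the likelihood in c is very
#'   flat, so expect wide intervals).
#' @param cMax upper bound of the c search.
#' @param nNodes Gauss-Legendre node count for the gamma averaging.
#' @param hotspotQuantile motifs above this quantile of G are summarized as
#'   the "within-hotspot" subset (implied median reported).
#' @param tailQuantile upper quantile defining the highly recombining tail
#'   (implied conditional mean reported).
#' @return A list with `gDist` (a [GDistribution-class]), `fit` (a
#'   [DbgcFit-class] whose `gHat` is the implied mean G = c * rateMean),
#'   `cHat`, `cCiLo`/`cCiHi` (when `ci`), `medianWithinHotspots` and
#'   `meanTail`.
#' @export
fitProportional <- function(spectrum, rateFit, ci = FALSE, cMax = 1000,
                            nNodes = 48L,
                            hotspotQuantile = 0.8, tailQuantile = 0.92) {
  kN <- spectrum@countsNeutral
  kT <- spectrum@countsTest
  edges <- spectrum@edges
  shape <- rateFit$shape
  MX <- rateFit$mean
  zf <- if (is.null(rateFit$zeroFraction)) 0 else rateFit$zeroFraction
  nodes <- .gaussNodes01(nNodes)
  I0 <- .binIntegrals(edges, 0)

  fitC <- function(cc) {
    IG <- .avgBinIntegrals(edges, cc * MX, shape, zf, nodes)
    .fitScales(kN, kT, I0, IG)
  }
  obj <- function(lc) -fitC(exp(lc))$lnL
  opt <- optim(log(1), obj, method = "Brent",
               lower = log(1e-4), upper = log(cMax),
               control = list(reltol = 1e-10))
  fit0 <- .fitScales(kN, kT, I0, I0)      # c = 0 boundary
  if (-opt$value <= fit0$lnL + 1e-9) {
    cHat <- 0
    best <- fit0
    IGhat <- I0
  } else {
    cHat <- exp(opt$par)
    IGhat <- .avgBinIntegrals(edges, cHat * MX, shape, zf, nodes)
    best <- .fitScales(kN, kT, I0, IGhat)
  }
  lnL1 <- max(best$lnL, fit0$lnL)
  pr <- .profileLnL(best$a, best$b, kN, kT, I0, IGhat, returnR = TRUE)
  lnLSat <- .lnLSaturated(kN, kT)
  lrt <- max(0, 2 * (lnL1 - fit0$lnL))
  nPar <- (length(kN) - 1L) + 3L
  MG <- cHat * MX
  gd <- gDistribution(shape = shape, mean = MG, c = cHat, rateMean = MX,
                      rateShape = shape, zeroFraction = zf)
  fit <- new("DbgcFit", model = "gamma", gHat = MG, ciLo = NA_real_,
             ciHi = NA_real_, rHat = pr$r, scaleNeutral = best$a,
             scaleTest = best$b, lnL = lnL1, lnLM0 = fit0$lnL,
             lnLSaturated = lnLSat, lrt = lrt,
             pLrt = if (lrt == 0) 1 else 0.5 * pchisq(lrt, 1, lower.tail = FALSE),
             gof = 2 * (lnLSat - lnL1),
             gofDf = 2 * sum((kN + kT) > 0) - nPar,
             details = list(cHat = cHat))
  medWithin <- if (MG > 0)
    qgamma(1 - (1 - hotspotQuantile) / 2, shape, scale = MG / shape) else 0
  meanTail <- if (MG > 0) {
    y0 <- qgamma(tailQuantile, shape)
    (MG / shape) * shape * (1 - pgamma(y0, shape + 1)) / (1 - tailQuantile)
  } else 0
  cCiLo <- cCiHi <- NA_real_
  if (ci) {
    target <- lnL1 - 2
    f <- function(cc) fitC(cc)$lnL - target
    cMin <- 1e-4
    cCiLo <- if (cHat <= cMin || fit0$lnL >= target) 0 else
      uniroot(f, c(cMin, cHat), tol = 1e-6)$root
    cCiHi <- if (f(cMax) >= 0) Inf else
      exp(uniroot(function(lc) f(exp(lc)),
                  c(log(max(cHat, cMin)), log(cMax)), tol = 1e-8)$root)
  }
  list(gDist = gd, fit = fit, cHat = cHat, cCiLo = cCiLo, cCiHi = cCiHi,
       medianWithinHotspots = medWithin, meanTail = meanTail)
}
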