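---
title: "Quantifying biased gene conversion against PRDM9 target motifs"
author: "hotspotErosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying biased gene conversion against PRDM9 target motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hotspotErosion)
```

## The problem

Meiotic recombination in humans clusters in hotspots whose position is
set by the zinc-finger protein PRDM9. The common A-type allele binds a
degenerate 13-bp motif (HM, `CCTCCCTNNCCAC`). Because double-strand
breaks initiated at the motif are repaired using the homologue as
template, a heterozygous carrier of a motif-disrupting mutation tends to
transmit the *disrupted* allele: the repair machinery converts the hot
allele away. This DSB-driven biased gene conversion (dBGC) behaves like
selection of population-scaled strength `G = 4*Ne*g` against the active
motif, and it predicts the self-destruction of hotspots — the engine of
the Red Queen dynamics of hotspot turnover. A second, weaker bias (gBGC)
favors G/C over A/T alleles in heteroduplex repair and drags base
composition toward an equilibrium GC content (GC*), leaving a sequence
signature wherever recombination has been active.

This package implements the quantitative machinery for measuring both
signatures in a human / Denisovan / chimpanzee quartet anchored on the
reconstructed human–chimpanzee ancestor, and for predicting how long the
targeted motifs can survive:

1. degenerate motif scanning (`scanMotifs()`),
2. branch assignment of motif-disrupting mutations under tiered quality
   filters, loss-rate tables and DAF extraction (`assignBranch()`,
   `applyFilter()`, `computeLossRates()`, `extractDaf()`),
3. Poisson random-field estimation of `G` from paired DAF spectra
   (`fitDbgc()`, `fitProportional()`),
4. equilibrium GC content per branch (`gcStar()`, `gcstarProfile()`),
5. diffusion-based lifespan predictions (`lossProbability()`,
   `expectedLossFraction()`, `kimuraFixationProbability()`,
   `kimuraMeanFixationTime()`),
6. a synthetic-data generator that produces every input with known truth
   (`simulateQuartetAlignment()`, `simulateDafSpectrum()`,
   `simulateWrightFisher()`).

## Conversion as selection: the sojourn density

A motif-disrupting allele at frequency `x` in a heterozygote is
transmitted with probability `(1+g)/2`, so its expected per-generation
frequency change is `g x (1-x)` — formally identical to genic selection
with coefficient `g`. All diffusion quantities in the package therefore
use one convention, `G = 4*Ne*g`, with scale density `exp(-G x)`:

* fixation probability `u(x0) = (1 - e^(-G x0)) / (1 - e^(-G))`,
* sojourn density of a new mutant,
  `H(x, G) = 2 (1 - e^(-G(1-x))) / (x (1-x) (1 - e^(-G)))`,
  reducing to the neutral `2/x` as `G -> 0`.

`H` is evaluated through `expm1` and is stable from the neutral limit up
to `G ~ 1e5` (the regime matters: profile upper limits routinely explore
very large `G`).

## The spectrum likelihood

Let the neutral reference class be mutations disrupting the control
motif (CM, `CTTCCCTNNCCAC` — one base away from HM, with no effect on
recombination), and the test class be HM-disrupting mutations. Both
classes are reduced to counts `k_j` in derived-allele-frequency bins;
fixed changes (DAF = 1) are informative descriptively but are not SNPs
and stay out of the likelihood. Each count is Poisson with mean

```
mu_j(class) = r_j * scale_class * ∫_bin H(x, G_class) dx
```

where `G = 0` for the neutral class, the `r_j` are per-bin distortion
multipliers shared by both classes that absorb demography, population
structure and ascertainment (`r_1 = 1` anchors the scale), and
`scale_class` is the `2 Ne u L` mutation-influx analog of each class.
Binning uses a first bin `[1/n, 0.01)` and `m` equal-width bins on
`[0.01, 1)` (`dafBinEdges()`; `m = 10` by default, and estimates are
stable across `m` — asserted in the test suite by overlapping intervals
at `m = 5, 10, 20`).

Given `(scaleN, scaleT, G)` the `r_j (j >= 2)` have a closed-form
profile (`(kN_j + kT_j) / (scaleN I0_j + scaleT IG_j)`), leaving a 2–3
dimensional optimization. `G` is searched on a log grid spanning
`1e-2 .. 1e5` followed by Brent refinement, with the `G = 0` boundary
always compared (`fitDbgc()`).

**Continuous approximation.** The exact finite-sample expectation folds
`H` against binomial sampling of `i` copies out of `n`
(`expectedClassCounts()`). With `n = 2184` chromosomes the sampling
kernel is collapsed onto the point frequency. The local error of that
collapse is `~ H''(x) x(1-x)/(2n)`, negligible in the interior but
growing at both frequency extremes (`H ~ 1/x` near 0; curvature
`~ 1/(1-x)^2` near 1). The test suite verifies sub-0.5% agreement for
all bins with class index `i >= 10` and `n (1-x)^2 >= 10`, down to
`n = 200`. The residual at the rare end is common to both classes and is
absorbed by the free per-class scales through the `r_1 = 1` anchor, so
the neutral-vs-test contrast that carries the signal about `G` is
insensitive to it.

**Hypothesis test.** `G` is constrained non-negative (conversion acts
against the motif by construction), so under the no-conversion null the
likelihood-ratio statistic follows the boundary mixture
`1/2 chi2_0 + 1/2 chi2_1`, not a plain 1-df chi-square; `fitDbgc()`
reports the mixture p-value, which makes the test's size equal its
nominal level (the suite calibrates the type-I error at ~5% over 1000
null spectra). The raw statistic is stored alongside for anyone wanting
the unadjusted convention.

**Confidence interval.** The interval collects all `G` whose
log-likelihood lies within two points of the maximum. By default the
nuisance parameters are re-optimized at each candidate `G` (a genuine
profile; coverage ~95% in the suite's simulations at `G = 1` and
`G = 10`). Holding the nuisances at their optima instead (a slice,
`ciMethod = "fixed"`) is offered for comparability, but a slice is
anti-conservative whenever `G` is correlated with the scales and
distortions — which it is here — and should not be used for inference.

**Flat likelihood at large G.** Away from the near-fixation bin, the
expected spectrum shape changes very little once `G` exceeds a few tens
(the suite bounds the shape difference between `G = 100` and `G = 1000`
below 2%), so upper confidence limits at strong conversion are very
large or infinite. This is a property of the data, not of the optimizer,
and `ciHi = Inf` is a legitimate outcome.

## The recombination-proportional model

dBGC strength at a locus scales with the local crossover rate `X`
(cM/Mb, measured on a 2-kb window centered on the motif,
`motifLocalRates()`). `fitGammaToRates()` fits a gamma law to the
observed rates by maximum likelihood — the shape solves
`log(a) - digamma(a) = log(mean(x)) - mean(log x)` by monotone root
finding; exact zeros are excluded and carried as a point-mass fraction.
Under `G = c X`, `G` inherits the gamma shape with mean `c M_X`;
`fitProportional()` averages the per-bin sojourn integrals over that law
by 48-node Gauss–Legendre quadrature on the probability scale (the
zero-rate atom contributes the neutral integrals) and maximizes over
`c`. The likelihood in `c` is very flat — single spectra of a few
hundred mutations barely distinguish `c` values a factor of three apart
— so the honest summary is the profile interval on `c`, not the point
estimate; the suite verifies interval coverage of the true `c` rather
than point recovery.

## Branch assignment, filters and loss rates

A quartet column holds the ancestral base (human–chimpanzee ancestor),
the human base, the Denisovan diploid genotype and the chimpanzee base.
Assignment (`assignBranch()`): hominini if human and Denisovan agree and
differ from the ancestor; human (denisovan) if only that terminal
lineage differs; chimpanzee if only the chimpanzee differs; a column
where human and Denisovan both differ from the ancestor *and* from each
other is excluded — three independent differences at one site more
likely indicate a misreconstructed ancestor than three mutations.
Denisovan heterozygotes are resolved by a fair coin per site; every
count that depends on the resolution is repeated (default 100 times) and
averaged, with the across-repeat spread reported.

A motif is lost on a branch as soon as one comparison-informative site
(the 10 sites shared by HM and CM: the two `N`s are never compared, and
the discriminating second position is also set aside so both motif
classes see identical mutational context) carries a mutation on that
branch. A motif hit both on the hominini branch and on a terminal branch
counts once, as hominini, and stops being part of the terminal branches'
denominator (the intact count at the human–Denisovan ancestor). Loss
disruption opportunity, by contrast, spans all `k = 11` non-N sites —
that `k` feeds the lifespan model below.

Filter tiers mirror the practical quality ladder of an
ancient-DNA-bearing quartet: F1 (Denisovan genotype called, no indel),
F2 (F1 plus membership in a high-quality filtered primate alignment and
3-of-4 primate concordance), F3 (F2 plus no low-quality/systematic-error
flags, Denisovan coverage within 16–46, perfect 20-mer mappability, no
paralogous alignment copies). A motif enters a tier's analysis set only
if all its informative sites pass, so the sets nest (F3 ⊆ F2 ⊆ F1 —
fuzz-tested). Loss-rate comparisons use a pooled two-proportion Z-test
with Yates continuity correction (`proportionTest()`; its squared
statistic is `prop.test()`'s chi-square, which the suite uses as an
independent oracle).

## Equilibrium GC content

For one branch, count (after masking) the W→S (A/T to G/C) and S→W
substitutions assigned to that branch and the W and S base counts at the
branch's ancestral node; then

```
GC* = fWS / (fWS + fSW),   fWS = nWS/nAT,   fSW = nSW/nGC.
```

This flux-ratio form — the stationary composition at which the per-base
flows balance — is the package's central estimator reconstruction; it is
validated in the suite against two-state simulations with a known
substitution-direction balance. Because CpG hypermutability would swamp
the signal in real data, any site carrying a G preceded by a C, or a C
followed by a G, *in at least one of the aligned sequences* is discarded
first (`maskCpg()`). Note one interaction worth understanding: in a
generator without CpG hypermutation, masking still preferentially
removes W→S events (a created CpG masks its own site), biasing GC*
downward; recovery tests therefore disable the mask, while mask
correctness (brute-force rescan equality, count monotonicity) is tested
separately. On real data the mask is the intended behavior.

Profiles around hotspot centers pool substitutions and opportunities
across anchors per offset window *before* forming the ratio
(ratio-of-sums): 10-bp windows rarely contain any substitution at one
anchor, so a mean of per-anchor ratios would be undefined almost
everywhere. Pooling is associative (grouping 10-bp dots into 500-bp
bins equals computing 500-bp bins directly — asserted in the suite), and
empty pooled windows yield missing values, never zeros. The 1-Mb-window
GC*-versus-rate regression (`windowedGcstarVsRecomb()`) is ordinary
least squares on per-window pooled estimates; window width scales down
for short simulated chromosomes.

## Lifespan predictions

Relative to neutral, a conversion coefficient `G` multiplies a site's
substitution rate by the fixation-bias factor `G / (1 - e^(-G))` (the
ratio of `u(1/2N)` to its neutral limit). With `k = 11` disruptible
sites, per-site mutation rate `mu = 1.2e-8` per generation and horizon
`T` generations, the probability that a motif acquires at least one
disrupting substitution is

```
P(G) = 1 - exp(-mu k T G / (1 - e^(-G)))
```

(`lossProbability()`). The form reproduces the published interval
endpoints for this system (`P(29) ≈ 32%`, `P(291) ≈ 96%–98%` at
`T = 1e5`), which is why it was adopted over alternatives.

Averaging `P` over the fitted gamma law of `G` gives population-level
predictions (`expectedLossFraction()`), optionally conditioned on a
quantile range such as the top 8% of motifs by local crossover rate. The
proportionality constant `c` is pinned by `calibrateTailMean()`: the
gamma scale is solved (monotone root finding, unique because the
conditional tail mean is linear in the scale) so that the top-8%
conditional mean equals a target — 174 by default for this motif family.
Under that calibration the package computes a top-8% loss fraction of
~86% and an overall fraction of ~21.5% at `T = 1e5` generations (both
recomputed from scratch by `scripts/acceptance.R`). A caveat worth
stating plainly: a top-8% conditional mean of 174 and an overall loss
fraction of 18% — two figures often quoted together for this system —
cannot both hold under a single gamma law of shape 0.28; calibrating on
the 18% instead would imply a tail mean near 130. The tail mean is the
anchor used here because the tail prediction (87%) is the quantity the
lifespan argument rests on; the discrepancy most plausibly traces to the
tail mean having been computed from the heavier empirical rate tail
(where the top 8% of motifs concentrate ~60% of crossovers, against
~49% under the fitted gamma) while the overall average used the gamma.

`kimuraMeanFixationTime()` computes the mean time to fixation of a new
converted mutant, conditional on fixing, from the diffusion sojourn
integrals. The upper integrand is algebraically rearranged so that the
catastrophic cancellation of `(S(1) - S(x))/psi(x)` at large `G`
disappears (`-expm1(-G(1-x))/G`), and both parts are integrated
adaptively to 1e-9 relative accuracy; the neutral limit `4N(1 - x0/2)`
is exact. The forward Wright–Fisher simulator
(`simulateWrightFisher()`, conversion as `(1+g)/2` heterozygote
transmission, all replicates vectorized) is the independent oracle: at
`G ∈ {0, 2, 20}` fixation probabilities and conditional times agree
within Monte-Carlo error (several thousand fixations per setting). At
`G = 90`, `Ne = 10,000` the conditional diffusion time is ~4,500
generations. The figure of ~9,000 generations sometimes quoted for this
regime is reproduced instead by the deterministic logistic sweep
duration `(2/g) ln(2N)` (~8,800 here) — an approximation that ignores
the conditioning, which roughly halves the stochastic boundary phases;
both numbers are computed in the acceptance suite so the distinction is
on the record.

## The synthetic-data generator

`simulateQuartetAlignment()` emulates the study inputs end-to-end on one
chromosome: an i.i.d. ancestor at GC fraction 0.4 with HM and CM motifs
planted one per genome slot; hotspot (2 kb) and THE1-like (350 bp)
intervals anchored on a motif subset (15% and 3% by default); a
HapMap-convention map with gamma background rates (mean 5.02 cM/Mb,
shape 0.28 — the empirical scale of human crossover-rate variation) and
elevated hotspot rates; branch substitutions at human–chimpanzee
divergence scale (0.6% chimpanzee, 0.55% hominini, 0.04% per terminal
branch); an optional extra disrupting-substitution probability on HM
informative sites per branch (the planted dBGC excess); an optional W→S
substitution-direction bias inside hotspots for designated branches
(planted gBGC as a biased choice at fixation, not a frequency
trajectory — sufficient to test GC* recovery); Denisovan-branch
mutations heterozygous with probability `hetRate`; per-site annotation
tracks with configurable defect rates; and an allele-frequency table in
which a configurable fraction of human-branch mutations still segregate.
One root seed drives named, hash-derived RNG streams per component, so
changing one component's consumption never perturbs another. Truth
tables are emitted alongside so tests never reach into generator
internals.

Deliberate simplifications, and what they mean for the tests: mutations
follow an infinite-sites rule (at most one hit per site across
branches), there is no linkage, no coalescent noise, no demography, no
CpG hypermutability, and substitution direction is a single-parameter
choice. Passing tests therefore certify the *estimators* — that branch
attribution, loss counting, spectrum likelihood, GC* and the diffusion
formulas recover planted truth — not that real alignments satisfy these
assumptions. `simulateDafSpectrum()` draws spectra from exactly the
Poisson-field model the fit assumes; the type-I and coverage
calibrations are therefore model-matched by design.

## Numerical choices

* Likelihood bin integrals: 24-node Gauss–Legendre in `log x` per bin
  (exact for the neutral `2/x`), with the bin touching `x = 1` split at
  the `1 - 20/G` boundary layer for `G > 50`; agrees with adaptive
  quadrature to ~1e-10 over `G` up to 1e5 (asserted). Reference-grade
  paths (`expectedBinCounts()`) use adaptive quadrature at 1e-10
  relative tolerance.
* Optimization in log-parameters with `nlminb` (relative tolerance
  1e-12), warm-started along the `G` search path; `G` grid
  `10^(-2..5)` in half-decade steps plus Brent refinement.
* Tercile stratification breaks rate ties by position order, making the
  split deterministic.
* Degenerate inputs fail loudly and early: empty anchor sets,
  non-monotone bin edges, all-zero rates, maps with unsorted positions
  (HapMap segment semantics are easy to corrupt silently — positions are
  0-based and each rate runs to the next position; the reader enforces
  sortedness and the writer round-trips exactly).
* Coordinates are 1-based closed inside the package (the GRanges
  convention); BED's 0-based half-open convention is converted exactly
  once, at the I/O boundary, and round-trip tested.

## Problem sizes

The suite runs at desk scale, chosen so the full test run takes minutes:
spectra of ~500 mutations per class at `n = 2184` chromosomes (1000
replicates for the type-I calibration, 120 per `G` for interval
coverage), Wright–Fisher oracles of 0.25–2.5 million replicates sized so
each setting yields well over 2000 fixations, and synthetic chromosomes
of 0.16–0.45 Mb carrying 100–300 motifs. The acceptance script's three
headline quantities are deterministic quadratures that complete in
seconds; its seed feeds only the Monte-Carlo cross-check.

## Known limitations

* The spectrum model assumes free recombination between motif sites and
  independence between motifs; linked selection or shared genealogies
  would make the Poisson variance an underestimate.
* `G` and the demographic distortions are only jointly identified
  through the neutral class; a neutral reference that itself experiences
  conversion would bias `G` downward.
* The proportional model fixes the gamma shape at the rate-fit value;
  uncertainty in the shape is not propagated into `c`.
* GC* is a ratio estimator; at very low substitution counts it is
  biased away from 0.5, which is why profiles pool counts and report
  missing values rather than per-anchor ratios.
* Real ancestral-state reconstruction error (the generator emits the
  true ancestor) adds misassignment the filters can only partly remove;
  the excluded-column rule is the lone guard implemented here.
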