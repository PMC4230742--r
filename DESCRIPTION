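Package: hotspotErosion
Title: Biased Gene Conversion Against PRDM9 Target Motifs and the
    Lifespan of Recombination Hotspots
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies the self-destructive drive (biased gene conversion,
    BGC) acting on PRDM9 recombination-hotspot target motifs from quartet
    genome alignments and derived-allele-frequency (DAF) spectra. Scans
    degenerate 13-bp hotspot motifs, assigns motif-disrupting mutations to
    phylogeny branches under tiered quality filters, estimates the
    population-scaled conversion coefficient G = 4Ne*g by Poisson
    random-field maximum likelihood on paired DAF spectra (with nuisance
    demography distortions, profile-likelihood confidence intervals and a
    recombination-proportional gamma extension), estimates equilibrium GC
    content (GC*) per branch from CpG-masked substitution counts, and
    predicts motif-loss probabilities and fixation times from Wright-Fisher
    diffusion theory. A synthetic-data module generates every input with
    known ground truth, including a forward Wright-Fisher simulator used as
    an independent oracle for the diffusion formulas.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    MASS
Config/testthat/edition: 3
biocViews: Genetics, PopulationGenetics, Software, Alignment
RoxygenNote: 7.3.3
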