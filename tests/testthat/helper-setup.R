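# test_dir() with an installed package does not source tests/testthat.R,
# so attach the Bioconductor generics the tests use (start/end/strand on
# GRanges) here.
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})
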