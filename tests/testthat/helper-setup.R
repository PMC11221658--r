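# Bioconductor infrastructure used throughout the tests.
suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
  library(withr)
})
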