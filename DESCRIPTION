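Package: recvalley
Title: Detection of Recombination Rate Valleys in Regulatory Domains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the genomic spans between regulatory elements and
    their target genes (eQTL/meQTL, Hi-C, DNase-TSS and enhancer-TSS links)
    carry a lower recombination rate than matched random controls. Provides
    genetic-map interpolation and interval-rate computation, three matched
    control generators (length-matched rejection sampling on feature tracks,
    k-d tree nearest-neighbour matching over an enumerated candidate index,
    and domain-constrained sampling), a bootstrap null of median rates over
    the SNP-TSS pair universe, paired signed-rank and permutation tests per
    link distance class, DNA-methylation correlation analyses, a random
    forest recombination-rate predictor, and a synthetic genome generator
    with planted rate valleys for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    randomForest,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
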