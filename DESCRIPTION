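Package: zfsurvey
Title: Genome-Scale Survey of C2H2 Zinc-Finger Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for genome-scale surveys of C2H2-type zinc-finger
    transcription factors in plants, developed around the hexaploid bread
    wheat (Triticum aestivum) family. Detects C2H2 zinc-finger domains in
    protein sequences, types each finger by the integrity of its
    plant-specific QALGGH hexapeptide (Q, M1-M4, Z1/Z2, D), classifies
    proteins into tandem and isolated architecture subsets, matches
    accessory repressor and activator boxes (EAR-like motifs and
    relatives), estimates Ka/Ks by the Nei-Gojobori (1986) method with a
    molecular-clock conversion of Ks to divergence time, and reproduces
    the expression-side analyses (log2 TPM transformation, expressed-gene
    filtering, five-group hierarchical clustering, 2^-ddCt qPCR
    quantification). A synthetic-data module generates proteomes, gene
    models, codon pairs and TPM matrices with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    dplyr,
    ggplot2,
    generics,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
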