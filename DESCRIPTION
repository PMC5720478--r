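Package: hlaloh
Title: HLA Allele-Specific Copy Number and Loss of Heterozygosity from
    Paired Tumor/Germline Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls allele-specific copy number, allelic imbalance and loss
    of heterozygosity (LOH) at the class I HLA genes (HLA-A/B/C) from paired
    tumor and germline short-read alignments. Reads overlapping the MHC
    region are extracted and re-aligned to the patient's own HLA allele
    sequences; coverage at the mismatch positions between the two homologous
    alleles yields b-allele frequencies and binned logR, which a
    purity/ploidy mixture model inverts into per-allele copy numbers. LOH is
    called when the minor allele copy number falls below 0.5 and a paired
    t-test on per-site logR differences supports allelic imbalance.
    Downstream, LOH events are placed on clone phylogenies by quadratic
    programming over regional cancer cell fractions, copy-number segments
    are classified as focal or arm-level, and a permutation test assesses
    enrichment of focal loss. A seeded synthetic-data generator produces
    homologous allele pairs, tumor/germline read sets under the mixture
    model, clone trees and segmentations with machine-readable truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    jsonlite,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
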