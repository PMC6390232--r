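Package: askit
Title: Allele-Specific CRISPR Knockout Design and Backcross Linkage Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for forward-genetics validation of candidate genes by
    allele-specific CRISPR/Cas9 knockout in F1 hybrids between two inbred
    strains. Builds the two parental haplotypes of a gene locus from a
    reference sequence and a strain variant table with an exact bidirectional
    coordinate map; scans both alleles for Cas9 protospacer sites and selects
    guide pairs whose PAM exists on only one allele (SNP-derived PAM
    specificity); genotypes edited founder animals from fluorescent-PCR
    fragment peak tables and Sanger clone reads, assigning each indel to its
    allele of origin and classifying reading-frame consequences; and maps a
    dominant binary trait in an N2 backcross by EM interval mapping with
    permutation-based genome-wide LOD thresholds, recombinant screening and
    minimal-interval fine mapping. A simulation module generates strain
    sequence pairs with planted PAM-gain SNPs, backcross panels with a single
    dominant locus, and allele-restricted editing outcomes with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    graphics,
    IRanges,
    Rcpp,
    rtracklayer,
    stats,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
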