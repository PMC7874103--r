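Package: bsaseq
Title: Bulked-Segregant QTL-Seq Mapping with Delta SNP-Index Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping dominant loci from pooled whole-genome
    re-sequencing of segregant bulks (QTL-seq / BSA-seq). Computes per-site
    SNP- and InDel-indices and their difference between phenotypic pools,
    smooths them in sliding windows, derives significance thresholds by
    Monte-Carlo simulation of the null pooling process, and calls associated
    regions. Includes a forward genetic simulator for F2:3 families founded
    by a single heterozygous plant (meiosis under the Haldane map function,
    phenotype models with two-locus dominance epistasis, pool selection and
    pooled read-depth simulation), an ANNOVAR-style variant-effect
    classifier driven by GFF3 gene models and a FASTA genome, and
    recombinant-marker fine mapping by phenotype-consistency constraint
    propagation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    GenomicRanges,
    methods,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
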