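Package: prxfam
Title: Peroxiredoxin Gene Family Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide characterization of the peroxiredoxin (PRX)
    gene family: rule-based subfamily classification from conserved active-site
    profiles (the PxxxTxxC...S...W/F core and cysteine spacings), theoretical
    isoelectric point and molecular weight, exon/intron architecture and
    5'UTR-intron detection, Nei-Gojobori Ka/Ks estimation with Jukes-Cantor
    correction and Ks-based divergence dating of duplicate gene pairs,
    strand-aware promoter extraction and IUPAC cis-element scanning against a
    packaged catalogue, qPCR fold-change analysis by the three-step 2^-dCt
    procedure, alternative-splicing event classification with ORF arithmetic,
    and seeded synthetic-data generators with planted ground truth for
    round-trip validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    rtracklayer,
    GenomicRanges,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
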