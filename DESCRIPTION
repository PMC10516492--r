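Package: ghostibd
Title: Ancestry-Specific IBD Decomposition and Ghost-Ancestry Detection in
    Admixed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and characterise deeply divergent unsampled
    ("ghost") ancestry in admixed human populations. Implements
    ancestry-specific decomposition of identity-by-descent (IBD) segments
    using local ancestry calls (with gap merging, inconsistency filtering,
    length-class binning, population pooling and UPGMA summaries), quartet
    genealogical-concordance topology tests with block-jackknife standard
    errors, coalescent internode-time estimation from concordance fractions,
    admixture-pulse ordering from covariances of ancestry ratios, ancestry
    masking with missingness filters, ancestry-specific pairwise-difference
    clustering, and total-variation distances between chromosome-painting
    copy profiles. A seeded synthetic-data generator produces admixed
    cohorts with known ancestry tracts, planted IBD segments and quartet
    site patterns so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
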