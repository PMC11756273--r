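Package: hetcheck
Title: Model Adequacy Tests for Site-Heterogeneous Amino Acid Substitution Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether an amino-acid substitution model
    adequately describes the across-site compositional heterogeneity of a
    protein alignment, in a maximum-likelihood setting.  Implements forward
    simulation of alignments on a fixed tree under site-homogeneous,
    finite-mixture, and site-specific-profile (PMSF) models; the across-sites
    amino-acid diversity statistic (div); a parametric-bootstrap Z-score
    adequacy test; computation and file exchange of posterior mean site
    frequency (PMSF) profiles; and gene-family curation operators (gap
    filtering, iterated long-branch removal, paralogue resolution) for
    phylogenomic matrix assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
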