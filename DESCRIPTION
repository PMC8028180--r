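Package: arraybridge
Title: Cross-Platform SNP Array Curation and Integration
Version: 0.1.0
Authors@R: person("arraybridge", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to curate and integrate biallelic SNP genotype calls from
    two array platforms. Implements duplicate-sample concordance screening,
    pedigree-based Mendelian inconsistent and consistent error detection,
    null-allele inference from cluster intensities, cluster-plot analytics
    (cluster space, mode detection, between-cluster calls, heterozygous
    sub-cluster rescue), physical-coordinate-constrained genetic map
    revision, probe off-target and secondary-polymorphism quality control,
    and a rule-based compatibility classifier that fuses all evidence into
    per-SNP verdicts. A synthetic two-platform dataset generator with
    planted artifacts (null alleles, paralogous binding, 3'-proximal
    secondary polymorphisms, platform-specific probe chemistry) provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
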