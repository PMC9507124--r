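Package: embryoploidy
Title: Ploidy and Chromosome-Arm Dosage Inference from Single-Embryo
    Sequencing Depth
Version: 0.1.0
Authors@R:
    person("Embryo", "Ploidy Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers embryo ploidy (haploid versus diploid versus segmental
    aneuploid), sex, and paternal-marker (transgene) presence from per-position
    whole-genome read-depth tracks of single Drosophila embryos, using the
    percent-depth statistic (mean gene depth over mean genome depth). Includes
    a synthetic-data generator that emulates a miniature multi-chromosome
    reference, per-embryo coverage profiles under arbitrary karyotypes with
    Poisson counting noise, and embryo-fate cohorts under a first-division
    outcome model of Wolbachia-induced cytoplasmic incompatibility, plus the
    cohort-level statistical battery (chi-squared, Fisher exact, Mann-Whitney,
    Kruskal-Wallis, paired t) used to quantify lethal phases and mitotic
    defect rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
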