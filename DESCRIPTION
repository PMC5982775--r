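Package: kinpen
Title: Kin-Cohort Penetrance Estimation for BRCA1/2 Mutation Carriers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates age-specific breast and ovarian cancer penetrance in
    BRCA1/2 mutation carriers from family-registry data under the kin-cohort
    design. First-degree relatives of genotyped probands form a retrospective
    cohort; untested relatives' genotypes are imputed from the proband's
    under Mendelian transmission and Hardy-Weinberg equilibrium, while
    observed relative genotypes replace the imputation to improve efficiency.
    Nonparametric discrete-time hazards for carriers and non-carriers are
    fitted by an EM algorithm over the genotype-mixture marginal likelihood;
    confidence intervals come from a bootstrap that resamples whole families.
    Also provides DerSimonian-Laird random-effects pooling of published
    penetrance estimates and a synthetic family-registry generator with known
    truth for validating the estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
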