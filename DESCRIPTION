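Package: bruiseAge
Title: Histological Age Estimation and Agreement Analysis for Bruises in Slaughter Pigs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for forensic age determination of human-inflicted bruises in
    slaughter pigs from semi-quantitative histological scores. Maps neutrophil
    and macrophage infiltration scores to age intervals in hours, combines the
    two lines of evidence into a single interval and a four-way age category,
    and quantifies between-lesion agreement with unweighted Cohen's kappa
    (asymptotic confidence intervals, one-sided test, Landis-Koch labels)
    computed from first principles. Includes a seeded synthetic-cohort
    generator with a latent infliction-time emission model for studying how
    many lesions must be sampled to reach a reliable consensus age, and a
    command-line interface for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
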