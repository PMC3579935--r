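Package: DiffGrowthScreen
Title: Differential Growth-Inhibition Screening Analytics for SDH-Mutant Yeast
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A three-stage analysis pipeline for high-throughput screens that
    seek compounds differentially toxic to succinate dehydrogenase (SDH)
    deficient yeast. Provides plate-level percent-inhibition scoring with
    z-factor quality control and hit calling; mono- and biphasic (diauxic)
    logistic growth-curve fitting that extracts lag time, maximal growth rate
    and maximal saturation per phase; differential-toxicity scores comparing
    mutant and reference strains with marker-strain concordance checks;
    four-parameter log-logistic dose-response (IC50) estimation for whole-cell
    growth and NADH-linked enzyme assays; and a synthetic-data generator with
    known ground truth that emulates wild-type, respiration-deficient and
    marker-control strains on mixed fermentable/non-fermentable media.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'DiffGrowthScreen-package.R'
    'differential.R'
    'dose-response.R'
    'enzyme.R'
    'growth-fit.R'
    'io.R'
    'pipeline.R'
    'plate.R'
    'synthetic.R'
    'utils.R'
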