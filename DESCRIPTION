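Package: fragRegime
Title: Landscape-Dependent Patch-Area Models and Diversity Statistics for
    Fragmented Landscapes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multimodel inference for species-patch-area relationships across
    fragmented landscapes that differ in total native vegetation cover. Provides
    a SummarizedExperiment-based container for site-by-species-by-year capture
    tables, an explicit catalogue of eight candidate count models (constant
    and/or linear in log10 patch area, per landscape, under Poisson or
    Negative Binomial error), maximum-likelihood fitting by multi-start
    derivative-free optimization, AICc model selection with Akaike weights,
    landscape-scale diversity statistics (sample-based rarefaction with exact
    conditional variance, Chao2 and first-order jackknife richness estimators,
    Bray-Curtis presence/absence similarity, representation percentages), and
    a synthetic-data generator that emulates the regime-shift sampling design
    so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, jsonlite
Suggests: testthat (>= 3.0.0), vegan, MASS, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
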