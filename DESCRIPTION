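Package: alpsim
Title: DTI-ALPS Glymphatic Index Simulation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for the diffusion tensor image analysis
    along the perivascular space (DTI-ALPS) method of glymphatic-activity
    quantification. Simulates diffusion-weighted MRI phantoms and
    multi-subject cohorts with known perivascular diffusivity structure,
    fits diffusion tensors by log-linear least squares, derives FA and
    directionally encoded colour maps, places and quality-checks the four
    projection/association-fibre ROIs, computes left and right ALPS
    indices, and runs the full group-statistics stage (summary-statistics
    one-way ANOVA with Bonferroni post hoc, t and Mann-Whitney tests,
    Pearson chi-square, age- and sex-adjusted partial correlations, and
    noncentral-F power analysis) so that published group summaries can be
    re-analysed without subject-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
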