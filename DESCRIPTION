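Package: lipidqi
Title: Fatty-Acid Nutritional Quality Indices and Lipid Bioactivity Assays
Version: 1.0.0
Authors@R: person("AARL", "Analytics", email = "aarl.analytics@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing the nutritional quality of fatty-acid (FA)
    profiles obtained from GC-MS FAME analysis. Parses Cx:y shorthand
    nomenclature into structured descriptors, aggregates per-sample
    compositions into the class sums (SFA, MUFA, PUFA, omega-3, omega-6,
    trans) that nutritional index formulas consume, and computes the eight
    standard indices: the PUFA/SFA ratio (PS), index of atherogenicity (IA),
    index of thrombogenicity (IT), the hypocholesterolemic to
    hypercholesterolemic ratio (h/H), the health-promoting index (HPI), the
    unsaturation index (UI), the sum of EPA and DHA (SED), and total trans
    fatty acids (TFA). Also evaluates colorimetric bioassay readouts: DPPH
    and ABTS radical-scavenging percentages, angiotensin-converting enzyme
    (ACE) inhibition percentages, and IC50 estimation from dose-response
    series by four-parameter logistic fitting with log-linear interpolation
    fallback. Includes seeded simulators for compositional FA profiles and
    sigmoidal dose-response plates, a packaged reference dataset of two
    freshwater diatom isolates, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
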