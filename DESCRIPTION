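Package: herbnet
Title: Inter- and Intra-Forest Variability in Insect Herbivory from Leaf Censuses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of insect herbivory recorded as damage types
    (DTs) and functional feeding groups (FFGs) on censused leaves, following the
    paleobotanical census design (forest > depositional environment > quarry).
    Provides validated leaf-census data structures and I/O, damage frequencies
    and analytically rarefied damage-type diversities, leaf-level probabilistic
    (hypergeometric) DT co-occurrence, bootstrap weighted bipartite plant-DT
    networks with connectance, NODF nestedness, partner diversity, robustness
    and the H2' specialization index, NMDS ordination and ANOSIM on FFG and
    plant composition, Rosner outlier screening and Tukey comparisons, a
    hierarchical synthetic leaf-census generator with an insect-outbreak
    scenario, and a pipeline orchestrator with reproducibility manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
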