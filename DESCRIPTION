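Package: whalesight
Title: Attendance, Association and Relatedness Analysis for Photo-Identified Whales
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing long-term photo-identification and biopsy
    records of individually identified baleen whales on a feeding ground.
    Builds validated encounter stores from sighting tables; computes
    occurrence, occupancy and operational sex ratios over April-March
    seasonal cycles; calculates encounter-level half-weight association
    indices and exports weighted social networks; estimates maximum
    likelihood pairwise relatedness from microsatellite genotypes with
    parent-offspring inference and a simulation-based test against the
    full-sibling alternative; and simulates pedigreed genotype panels and
    seasonally structured encounter histories with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
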