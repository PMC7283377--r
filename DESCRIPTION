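Package: sslmap
Title: QTL Substitution Mapping with Single-Segment Substitution Lines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Substitution-mapping pipeline for quantitative trait loci (QTLs)
    detected in libraries of single-segment substitution lines (SSSLs). Infers
    donor introgression segments from codominant marker genotypes and computes
    their minimum, maximum and estimated lengths; screens lines for elevated
    stigma exsertion rate (SER) against the recurrent parent with one-way ANOVA,
    LSD contrasts and Duncan's multiple range test; delimits QTL intervals by
    primary and secondary substitution mapping; and estimates genetic effects
    (season-wise additive effects, 1:2:1 F2 segregation chi-square tests,
    dominance degree). A synthetic-data module generates marker maps, SSSL
    libraries, secondary recombinant lines, season-structured phenotypes and F2
    populations with known ground truth so the whole pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
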