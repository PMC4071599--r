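Package: spongebiomass
Title: Biomass Composition Analysis and Biomass Equation Assembly for
    Marine Sponges
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to turn raw compositional assay tables from marine sponge
    biopsies into macromolecular summaries and a biomass equation suitable for
    genome-scale metabolic modelling. Covers dry-weight bookkeeping (salt
    correction, displacement-volume conversion, skeleton fraction), standard
    curve back-calculation of protein, carbohydrate, DNA and RNA content,
    GC-MS FAME peak-table quantification of fatty acids and sterols,
    amino-acid hydrolysate profiling with amide splitting and skeleton
    subtraction, nucleotide composition from genome and transcriptome GC
    content, random-intercept variance partitioning of between- versus
    within-individual variation, and a deterministic synthetic-data generator
    that emulates the hierarchical sampling design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite
Config/testthat/edition: 3
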