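Package: metalsiteqc
Title: Regional Quality Control of Metal Binding Sites in Crystal Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Evaluates the regional structural quality of metal ion binding
    sites in macromolecular crystal structures against four criteria:
    diffraction resolution, metal atom occupancy, exclusion of
    crystallographic symmetry contacts, and the sum of significant Fo-Fc
    difference-density discrepancies (in electrons) within a sphere around
    the metal, compared against a data-driven cohort cutoff. Includes a
    fixed-column legacy PDB parser (CRYST1, REMARK 2, REMARK 290 SMTRY,
    ATOM/HETATM), a CCP4/MRC mode-2 density map reader and writer,
    crystallographic symmetry expansion over neighboring unit cells, cohort
    statistics (trimmed-SD cutoff derivation, metal cluster detection,
    per-element tabulation), a deterministic synthetic fixture generator
    producing paired toy structures and density maps with ground truth, and
    a two-phase command-line workflow.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
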