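Package: tractometry
Title: Tidy Tables, Tract-Profile Statistics and Publishable Bundles for
    Diffusion MRI Tractometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts tractometry outputs (AFQ MATLAB structures, TRACULA
    group-stats folders) into a documented tidy table bundle (CSV + JSON),
    computes group Tract-Profile summaries (per-node mean, SD, SE), normative
    per-node z-score profiles for individual-versus-group comparison and focal
    lesion localization, encodes and decodes a reproducible viewer state as a
    canonical URL query string, and assembles, serves and dry-run-publishes a
    shareable data bundle. Includes a seeded synthetic tract-profile generator
    (between-subject offsets, AR(1) node noise, group effects, focal lesions in
    control-SD units) so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    callr,
    digest,
    jsonlite,
    rhdf5,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: python with scipy (classic MAT v7 file support only)
Config/testthat/edition: 3
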