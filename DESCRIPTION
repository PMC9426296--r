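Package: gonadose
Title: Reconstruction of Preconception Gonadal Radiation Doses with
    Two-Dimensional Monte Carlo Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Time-and-motion reconstruction of gonadal (testes/ovaries)
    absorbed doses for parents exposed after the 1986 Chornobyl accident,
    over individually defined preconception windows (51 and 38 weeks before
    a child's date of birth).  Implements four exposure-pathway models:
    external irradiation during the cleanup mission and during residence in
    Pripyat (air kerma rate x duration x location factor), external
    irradiation from the multi-radionuclide ground deposition during
    residence in other settlements (including Bateman decay-product
    ingrowth and a two-exponential soil-migration attenuation function),
    and ingestion of radiocesium with locally produced foodstuffs.
    Uncertainty is propagated by Monte Carlo simulation, with a
    two-dimensional scheme separating shared (settlement/area/global) from
    unshared (subject-level) parameter errors.  A synthetic cohort
    generator emulates questionnaire-derived itineraries, occupancy
    timelines, residence histories and diet records so the whole pipeline
    is testable without confidential study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
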