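Package: spo0Areg
Title: Biophysical Models of Dual-Promoter Autoregulation at the spo0A Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-thermodynamic and kinetic models of transcriptional
    autoregulation for a dual-promoter locus controlled by multiple
    transcription-factor binding sites, built around the spo0A system of
    Bacillus subtilis. Implements cooperative (Hill/mass-action) binding
    models for EMSA titrations with bootstrap confidence intervals and
    stoichiometry selection, four scenarios of promoter control (kinetic or
    thermodynamic for each promoter) with configuration-resolved partition
    functions, constrained multi-strain fitting of reporter time courses by
    multi-start bounded optimization with a compiled objective, model
    ranking and BIC-based nesting tests for box-box interaction energies,
    and downstream regulatory analyses: additivity and normalization data
    collapses, repression/activation strength, box-occupancy saturation
    timing, RNA-polymerase dynamics decomposition, and shared-sigma joint
    fits. Includes a synthetic-data generator emulating a 24-strain reporter
    panel and sigmoidal binding titrations so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
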