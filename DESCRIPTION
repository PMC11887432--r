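Package: patchtitrate
Title: Charge Regulation and Donnan Partitioning of Patchy Nanoparticles in Dialysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Coarse-grained simulation and closed-form theory of dialyzed
    dispersions of rigid nanoparticles bearing weakly acidic surface sites
    arranged in patches. The retentate is sampled with reaction-ensemble and
    grand-canonical Monte Carlo moves against a virtual ion reservoir at fixed
    pH and salt concentration (the Grand-Reaction scheme), with WCA excluded
    volume and Ewald electrostatics. Includes the ideal Donnan and coupled
    Henderson-Hasselbalch/Donnan reference theory, Widom-insertion estimates of
    steric ion partitioning, blocking-based error analysis, and a
    reproducibility shell (TOML-style run configs, sweeps, extended-XYZ
    snapshots).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: C++17
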