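Package: nsphere
Title: Analytical EEG Lead Fields in Concentric N-Sphere Head Models
Version: 0.1.0
Authors@R: person("Nsphere", "Developers", email = "nsphere-dev@example.org",
    role = c("aut", "cre"))
Description: Computes the electric potential of a radial current dipole inside
    a volume conductor made of an arbitrary number of concentric, homogeneous,
    isotropic spherical shells, via a per-degree iterative formulation of the
    Legendre-series expansion coefficients. Includes the historical explicit
    four-sphere constants and the spherical spatial-filter formulation as
    built-in cross-validation oracles, a first-principles boundary-condition
    linear-system solver, and tooling to assemble radial-dipole lead-field
    matrices for scalp electrode arrays, with a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
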