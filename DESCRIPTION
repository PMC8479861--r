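Package: cosolv
Title: Noniterative COSMO Solvation Free Energies from Semiempirical Atomic Charges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes standard-state solvation free energies for neutral and
    ionic solutes in water, polar protic, polar aprotic and nonpolar solvents
    from fixed gas-phase atomic point charges (e.g. PM7 charges read from
    MOPAC or Gaussian output). The electrostatic component is obtained by a
    single linear solve of the conductor-like screening model (COSMO) on a
    tessellated van der Waals cavity, scaled by the Born dielectric factor
    1 - 1/eps; an element- and solvent-class-specific linear correction adds
    cavitation, dispersion and implicit polarization terms. Includes the
    weighted linear least-squares machinery used to parameterize the
    correction, error statistics, seed-deterministic synthetic fixtures, and
    parsers for MOPAC, Gaussian and a plain-text XYZQ interchange format.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse, knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
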