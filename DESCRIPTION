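Package: groupadd
Title: Atom-Group Additivity Models for Liquid Viscosity and
    Infinite-Dilution Activity Coefficients in Water
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements an atom-centered group-contribution (group-additivity)
    method for predicting the decimal logarithm of the liquid viscosity
    coefficient at 293.15 K and of the activity coefficient at infinite
    dilution in water at 298.15 K of organic compounds and ionic liquids.
    Molecules are broken down into atom groups -- one per heavy-atom center,
    classified by element, hybridisation and formal charge together with a
    canonical encoding of the immediate bonded neighbourhood -- and the
    property is the sum of tabulated group contributions, optional special
    hydrocarbon and hydrogen-bond terms, and a constant.  Ships the two
    published parameter tables, reads V2000 SDF files and SMILES strings,
    and provides the full training machinery: sparse design matrices,
    Gauss-Seidel least-squares fitting, group-validity gating, outlier
    exclusion against the cross-validated standard error, and ten-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    tools
Suggests:
    ChemmineOB,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
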