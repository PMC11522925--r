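Package: petentry
Title: Contact, Energetics, Entry-Pathway and Kinetics Analysis for PET Hydrolases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-simulation studies of
    polyethylene-terephthalate (PET) hydrolases. Detects residue-polymer
    contacts and filters them by persistence, splits binding sites into
    proximal and distal classes around the catalytic serine, decomposes
    nonbonded interaction energies (Coulomb plus Lennard-Jones) per residue
    and per physicochemical class, identifies productive binding poses and
    substrate-entry events with si/re face labels, builds replica-weighted
    two-dimensional free-energy surfaces and compares their features between
    enzyme variants, decomposes entry pathways by principal component
    analysis, and fits conventional and inverse Michaelis-Menten kinetics
    with molar secondary parameters. Ships a synthetic-fixture generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
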