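Package: helimem
Title: Orientation, Contact, Diffusion and Free-Energy Analysis of Helical
    Peptides at Lipid Bilayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for coarse-grained simulations of helical
    antimicrobial peptides interacting with planar lipid bilayers. Computes
    per-frame orientation descriptors (tilt angle, spin angle, hydrophobic
    dipole moment and its longitudinal/transversal decomposition), residue
    class composition fingerprints, distance-cutoff peptide-lipid contact
    fingerprints, z-density profiles, and lateral diffusion coefficients via
    Rayleigh fits of in-plane displacement distributions. Reconstructs
    well-tempered metadynamics free-energy surfaces from Gaussian deposition
    records, projects them to one-dimensional potentials of mean force, and
    converts them into partition coefficients, standard-state adsorption free
    energies and membrane-to-membrane transfer free energies. Ships
    deterministic synthetic-data generators (ideal helices, model bilayers,
    scheduled trajectories, Brownian walks, analytic free-energy surfaces
    with known partition coefficients) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    jsonlite
Suggests:
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
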