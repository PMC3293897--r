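Package: helixscreen
Title: Interface Hot-Spot Mapping and Pharmacophore-Constrained Virtual
    Screening for Helix-Mediated Protein Dimerization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for targeting protein-protein interfaces formed by
    antiparallel alpha helices. Computes ensemble-averaged per-residue
    van der Waals and electrostatic interaction energies across a dimer
    interface, detects hydrogen bonds and ranks hot-spot residues,
    derives a complementary ligand-side pharmacophore from the hot
    spots, screens multi-conformer ligand libraries by RMSD-gated rigid
    pharmacophore matching with reduced-radius steric filtering, and
    rescores poses with an empirical contact score and an MM-GBSA-style
    binding energy including per-group electrostatic decomposition.
    Deterministic synthetic-system generators (toy helix dimers,
    jittered coordinate ensembles, active/decoy ligand libraries)
    support end-to-end testing of the protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
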