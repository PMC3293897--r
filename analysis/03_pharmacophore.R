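#!/usr/bin/env Rscript
# Stage 3: derive the complementary pharmacophore and build the library.
#
# Hot spots on chain A (the flagged polar residues plus the hydrophobic
# leucine) are projected into the emptied interface: each protein donor
# contributes a ligand-acceptor (HA) point 2.9 A along its most exposed
# N-H; each carboxylate oxygen contributes a ligand-donor (HD) point; the
# leucine tip contributes a hydrophobic (HY) point 4.0 A outward. The
# 5-point model then drives construction of the screening library: 10
# actives, 2 neutral-carbonyl analogs and 40 matcher-audited decoys.

library(helixscreen)

seed <- 1L
ens <- assign_parameters(read_pdb("results/data/dimer_ensemble.pdb"),
                         read_parameter_table("results/data/parameters.tsv"))
mat <- interface_matrix(ens, "A", "B")
hb <- detect_hbonds(ens)
rk <- rank_hotspots(mat, hb)$ranked
hydro <- rownames(mat$e_vdw)[rowSums(mat$e_vdw) <= -0.25 &
                               mat$res_a$resname %in%
                                 c("LEU", "ILE", "VAL", "ALA", "PHE", "MET",
                                   "TRP")]
hot <- sort(unique(c(rk$residue[rk$flagged & rk$chain == "A"], hydro)))
cat("Hot-spot residues used for the model:", hot, "\n\n")

model <- derive_interface_pharmacophore(ens, hot)
print(model)
print(model$features[, c("kind", "x", "y", "z", "source")])
write_pharmacophore(model, "results/tables/pharmacophore.yaml")

mono <- select_chain(ens, "A")
lib <- make_ligand_library(
  library_spec(n_actives = 10L, n_decoys = 40L, displacement = 2.5,
               n_analogs = 2L, noise = 0.25, seed = seed + 2L),
  model, away_from = colMeans(mono$frames[[1]]),
  avoid = mono$frames[[1]][!mono$atoms$is_h, , drop = FALSE])
write_sdf(lib, "results/data/library.sdf")
cat("\nWrote the 5-point model and a", length(lib), "ligand library",
    "(multi-conformer SDF).\n")
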