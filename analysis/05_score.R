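#!/usr/bin/env Rscript
# Stage 5: rigid-body refinement, MM-GBSA-style energies, group terms.
#
# Surviving poses are relaxed by greedy rigid-body descent on the
# intermolecular MM energy, then scored: intermolecular vdW and Coulomb
# terms (dielectric 1), generalized-Born polar solvation (HCT effective
# radii), nonpolar solvation from the buried surface area, and the
# electrostatics of the nitro-like charged acceptor group reported
# separately -- the quantity that distinguishes the actives from their
# neutral-carbonyl analogs.

library(helixscreen)

run <- run_pipeline(list(
  seed = 1L,
  library_spec = list(n_actives = 10L, n_decoys = 40L, displacement = 2.5,
                      n_analogs = 2L, noise = 0.25),
  out_dir = "results/tables"))

en <- run$energies
cat("MM-GBSA-style energies of the scored poses (kcal/mol):\n")
print(en[order(en$total),
         c("ligand", "e_vdw", "e_elec", "g_polar", "g_nonpolar", "total",
           "elec_nitro")], digits = 4)

cat("\nCharged-group electrostatics, actives vs neutral analogs:\n")
cat(sprintf("  actives : mean %.2f kcal/mol\n",
            mean(en$elec_nitro[grepl('^active', en$ligand)])))
cat(sprintf("  analogs : mean %.2f kcal/mol\n",
            mean(en$elec_nitro[grepl('^analog', en$ligand)])))
cat("\nThe analogs lose the favorable charged-group contribution while",
    "remaining\npharmacophore-compatible, mirroring how removing the",
    "nitro group abolishes\nthe strongest electrostatic contact without",
    "changing the binding mode.\n")
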