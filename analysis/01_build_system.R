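#!/usr/bin/env Rscript
# Stage 1: build the synthetic benchmark system.
#
# Constructs the antiparallel two-helix dimer with its planted interface
# contacts (two donor -> carboxylate hydrogen-bond pairs per chain plus a
# leucine-like hydrophobic contact), a 20-frame jittered ensemble standing
# in for MD production frames, and writes everything to results/data/ as
# plain-text PDB and TSV. The ligand library is built in stage 3, after the
# pharmacophore it must satisfy exists.

library(helixscreen)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dimer <- make_toy_dimer(dimer_spec(seed = seed))
cat("Built dimer:\n")
print(dimer$structure)

ens <- jitter_ensemble(dimer$structure, sigma = 0.1, n_frames = 20L,
                       seed = seed + 1L)
write_pdb(ens, file.path(out, "dimer_ensemble.pdb"))
write_parameter_table(dimer$parameters, file.path(out, "parameters.tsv"))

hb <- detect_hbonds(dimer$structure)
cat("\nPlanted inter-chain hydrogen bonds in the reference frame:\n")
print(hb$occupancy[, c("donor_res", "acceptor_res", "occupancy")])
cat("\nWrote", file.path(out, "dimer_ensemble.pdb"), "(20 frames) and the",
    "parameter table.\n")
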