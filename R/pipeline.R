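# End-to-end screening pipeline -------------------------------------------------
#
# hotspots -> pharmacophore -> screen -> minimize -> score, driven by one
# validated configuration. All randomness derives from the single config
# seed via fixed per-stage offsets (dimer seed, ensemble seed + 1, library
# seed + 2), so a config determines every output byte.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    receptor = NULL,            # PDB path; NULL -> synthetic dimer
    library = NULL,             # SDF path; NULL -> synthetic library
    parameter_table = NULL,     # TSV path; NULL -> built-in table
    chain_a = "A", chain_b = "B",
    n_frames = 20L, sigma = 0.1,
    dielectric = list(type = "distance", factor = 4, value = 1),
    hbond = list(dist_max = 3.5, angle_min = 120),
    hotspot_criteria = list(energy_max = -2, occupancy_min = 0.5,
                            conservation_min = 0.5),
    hotspots = NULL,            # explicit residue refs; NULL -> automatic
    hydrophobic_vdw_max = -0.25,
    gate = 1.0, radius_scale = 0.6, max_clashes = 0L,
    weights = list(vdw = 0.004, hbond = 0.5, hydrophobic = 0.1, rotor = 0.5),
    solvation = list(eps_solvent = 80, gamma = 0.00542, beta = 0.92,
                     probe = 1.4, n_points = 960L),
    minimize = list(steps = 200L, step_size = 0.05, step_deg = 0.5),
    library_spec = list(n_actives = 10L, n_decoys = 40L, displacement = 2.5,
                        n_analogs = 0L, noise = 0.25),
    out_dir = NULL)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown and duplicated keys, and
#' range-checks every threshold. Errors are aggregated into one message.
#'
#' @param config named list of overrides (may be empty)
#' @return normalized config list
#' @export
validate_config <- function(config = list()) {
  defs <- pipeline_defaults()
  errors <- character(0)
  if (length(config) && is.null(names(config)))
    stop("config must be a named list")
  dup <- names(config)[duplicated(names(config))]
  if (length(dup))
    errors <- c(errors, paste0("duplicate config key: ",
                               paste(unique(dup), collapse = ", ")))
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    errors <- c(errors, paste0("unknown config key: ",
                               paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defs, config[setdiff(names(config), unknown)])
  chk <- function(ok, msg) if (!isTRUE(ok)) errors <<- c(errors, msg)
  chk(cfg$radius_scale > 0 && cfg$radius_scale <= 1,
      "radius_scale must be in (0, 1]")
  chk(cfg$gate >= 0, "gate must be non-negative")
  chk(cfg$sigma >= 0, "sigma must be non-negative")
  chk(cfg$n_frames >= 1, "n_frames must be at least 1")
  chk(cfg$max_clashes >= 0, "max_clashes must be non-negative")
  chk(cfg$hbond$dist_max > 0, "hbond dist_max must be positive")
  chk(cfg$hbond$angle_min >= 0 && cfg$hbond$angle_min <= 180,
      "hbond angle_min must be in [0, 180]")
  chk(cfg$dielectric$type %in% c("distance", "constant"),
      "dielectric type must be 'distance' or 'constant'")
  chk(cfg$solvation$eps_solvent > 1, "solvent dielectric must exceed 1")
  chk(cfg$minimize$steps >= 0, "minimize steps must be non-negative")
  if (length(errors)) stop(paste(errors, collapse = "; "))
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full interface-screening pipeline
#'
#' Stages, in order: build or load the receptor ensemble; compute the
#' ensemble-averaged interface matrix and hydrogen bonds and rank hot
#' spots; derive the complementary pharmacophore on `chain_a`; build or
#' load the ligand library; screen it against the `chain_a` monomer
#' (RMSD gate, reduced-radius clash filter, empirical score); rigid-body
#' minimize surviving poses and compute MM-GBSA-style energies with
#' per-group electrostatics. When `out_dir` is set, every intermediate is
#' written as TSV/YAML/PDB with fixed numeric formatting, so identical
#' configs reproduce identical bytes.
#'
#' @param config named list of overrides for [validate_config()]
#' @return an `hx_run_report`: list(config, hotspot_report, pharmacophore,
#'   screen, energies, counts, version)
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  diel <- dielectric_model(cfg$dielectric$type, cfg$dielectric$factor,
                           cfg$dielectric$value)
  ptable <- if (is.null(cfg$parameter_table)) default_parameter_table()
            else read_parameter_table(cfg$parameter_table)

  ## stage 1: receptor ensemble
  if (is.null(cfg$receptor)) {
    dim <- make_toy_dimer(dimer_spec(seed = cfg$seed))
    receptor <- jitter_ensemble(dim$structure, sigma = cfg$sigma,
                                n_frames = cfg$n_frames, seed = cfg$seed + 1L)
  } else {
    receptor <- assign_parameters(read_pdb(cfg$receptor), ptable)
  }

  ## stage 2: interface energetics and hot spots
  mat <- interface_matrix(receptor, cfg$chain_a, cfg$chain_b, dielectric = diel)
  hb <- detect_hbonds(receptor, dist_max = cfg$hbond$dist_max,
                      angle_min = cfg$hbond$angle_min)
  report <- rank_hotspots(mat, hb,
                          energy_max = cfg$hotspot_criteria$energy_max,
                          occupancy_min = cfg$hotspot_criteria$occupancy_min,
                          conservation_min = cfg$hotspot_criteria$conservation_min)

  ## stage 3: pharmacophore on chain A (flagged polar hot spots plus
  ## hydrophobic residues with a real vdW contribution)
  if (is.null(cfg$hotspots)) {
    rk <- report$ranked
    polar <- rk$residue[rk$flagged & rk$chain == cfg$chain_a]
    vdw_tot <- rowSums(mat$e_vdw)
    hydro <- rownames(mat$e_vdw)[vdw_tot <= cfg$hydrophobic_vdw_max &
                                   mat$res_a$resname %in% HYDROPHOBIC_RES]
    hotspots <- sort(unique(c(polar, hydro)))
  } else hotspots <- cfg$hotspots
  pharm <- derive_interface_pharmacophore(receptor, hotspots)

  ## stage 4: library
  monomer <- select_chain(receptor, cfg$chain_a)
  if (is.null(cfg$library)) {
    ls <- cfg$library_spec
    lspec <- library_spec(ls$n_actives, ls$n_decoys, ls$displacement,
                          ls$n_analogs, ls$noise, seed = cfg$seed + 2L)
    heavy <- monomer$frames[[1]][!monomer$atoms$is_h, , drop = FALSE]
    library <- make_ligand_library(lspec, pharm,
                                   away_from = colMeans(monomer$frames[[1]]),
                                   avoid = heavy)
  } else {
    library <- lapply(read_sdf(cfg$library), assign_parameters, table = ptable)
  }
  n_conformers <- sum(vapply(library, function(l) length(l$conformers), 0L))

  ## stage 5: screen
  w <- do.call(empirical_weights, cfg$weights)
  screen <- screen_library(library, pharm, monomer, gate = cfg$gate,
                           radius_scale = cfg$radius_scale,
                           max_clashes = cfg$max_clashes, weights = w)

  ## stage 6: minimize + score survivors
  solv <- do.call(solvation_settings, cfg$solvation)
  energies <- list()
  for (nm in names(screen$poses)) {
    pose <- local_minimize(screen$poses[[nm]], monomer,
                           steps = cfg$minimize$steps,
                           step_size = cfg$minimize$step_size,
                           step_deg = cfg$minimize$step_deg)
    mm <- mmpbsa_energy(pose, monomer, solv)
    ge <- group_electrostatics(pose, monomer)
    row <- data.frame(ligand = nm, conformer = pose$conformer,
                      e_vdw = mm$e_vdw, e_elec = mm$e_elec,
                      g_polar = mm$g_polar, g_nonpolar = mm$g_nonpolar,
                      total = mm$total)
    for (g in seq_len(nrow(ge)))
      row[[paste0("elec_", ge$group[g])]] <- ge$e_elec_group[g]
    energies[[nm]] <- row
  }
  energies <- if (length(energies)) {
    cols <- unique(unlist(lapply(energies, names)))
    do.call(rbind, lapply(energies, function(r) {
      for (cl in setdiff(cols, names(r))) r[[cl]] <- NA_real_
      r[, cols]
    }))
  } else data.frame()
  rownames(energies) <- NULL

  counts <- list(
    residue_pairs = nrow(mat$res_a) * nrow(mat$res_b),
    features_in_model = nrow(pharm$features),
    ligands = length(library),
    conformers = n_conformers,
    conformers_rejected = nrow(screen$rejections),
    ligands_accepted = nrow(screen$entries),
    poses_scored = nrow(energies))
  stopifnot(counts$ligands_accepted <= counts$ligands,
            counts$poses_scored == counts$ligands_accepted)

  out <- structure(list(config = cfg, interface_matrix = mat,
                        hbonds = hb, hotspot_report = report,
                        hotspots = hotspots, pharmacophore = pharm,
                        screen = screen, energies = energies,
                        counts = counts,
                        version = as.character(utils::packageVersion("helixscreen"))),
                   class = "hx_run_report")
  if (!is.null(cfg$out_dir)) write_run_outputs(out, cfg$out_dir)
  out
}

#' @export
print.hx_run_report <- function(x, ...) {
  cat("hx_run_report (helixscreen", x$version, ")\n")
  cat("  residue pairs evaluated:", x$counts$residue_pairs, "\n")
  cat("  pharmacophore features :", x$counts$features_in_model, "\n")
  cat("  ligands screened       :", x$counts$ligands, "(",
      x$counts$conformers, "conformers )\n")
  cat("  ligands accepted       :", x$counts$ligands_accepted, "\n")
  cat("  poses scored           :", x$counts$poses_scored, "\n")
  invisible(x)
}

write_run_outputs <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(out_dir, f)
  write_interface_matrix(report$interface_matrix, fp("interface_matrix.tsv"))
  rk <- report$hotspot_report$ranked
  rk$energy <- formatC(rk$energy, format = "f", digits = 6)
  rk$occupancy <- formatC(rk$occupancy, format = "f", digits = 4)
  utils::write.table(rk[, c("residue", "resname", "energy", "occupancy",
                            "flagged")],
                     fp("hotspots.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_pharmacophore(report$pharmacophore, fp("pharmacophore.yaml"))
  write_ranking(report$screen, fp("ranking.tsv"))
  rej <- report$screen$rejections
  utils::write.table(rej, fp("rejections.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  en <- report$energies
  if (nrow(en)) {
    num <- vapply(en, is.numeric, TRUE) & names(en) != "conformer"
    for (cl in names(en)[num]) en[[cl]] <- formatC(en[[cl]], format = "f",
                                                   digits = 6)
  }
  utils::write.table(en, fp("energies.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out_dir)
}
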