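# Empirical rescoring, GB/SASA solvation anchors, MM-GBSA, group terms.

scene_pose <- function(seed = 1L, n_actives = 1L, n_analogs = 0L) {
  sc <- default_scene(seed = seed, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = n_actives, n_decoys = 0,
                                          n_analogs = n_analogs,
                                          seed = seed + 10L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  poses <- lapply(lib, function(lg)
    place_pose(lg, 1, match_pharmacophore(type_ligand_features(lg, 1),
                                          sc$model)))
  c(sc, list(lib = lib, poses = poses))
}

test_that("a far-away pose scores only its rotor penalty", {
  s <- scene_pose()
  pose <- s$poses[[1]]
  pose$coords <- pose$coords + 500
  sc <- empirical_score(pose, s$monomer)
  expect_equal(sc$vdw_term, 0)
  expect_equal(sc$hbond_term, 0)
  expect_equal(sc$hydrophobic_term, 0)
  expect_equal(sc$rotor_term, -0.5 * count_rotatable(pose$ligand))
  w <- empirical_weights()
  expect_equal(sc$total, w[["rotor"]] * sc$rotor_term)
})

test_that("one ideal hydrogen bond raises the bond term by exactly one", {
  ## receptor: carbonyl-like acceptor; ligand: amine donor at ideal geometry
  rec <- tiny_structure(list(
    atom_spec("C", "A", 1, "C", c(-1.23, 0, 0), charge = 0.45,
              epsilon = 0.086, rmin_half = 1.908, radius = 1.7),
    atom_spec("O", "A", 1, "O", c(0, 0, 0), charge = -0.45,
              epsilon = 0.21, rmin_half = 1.6612, radius = 1.52)))
  lig_far <- make_ligand("probe", c("N", "H"),
                         rbind(c(50, 0, 0), c(49, 0, 0)),
                         data.frame(i = 1L, j = 2L, order = 1L))
  lig_far$atoms$radius <- c(1.55, 1.1)
  lig_far$atoms$epsilon <- c(0.17, 0.0157)
  lig_far$atoms$rmin_half <- c(1.824, 0.6)
  mkpose <- function(lg) structure(
    list(ligand = lg, conformer = 1L, rotation = diag(3),
         translation = c(0, 0, 0), coords = lg$conformers[[1]],
         pharm_rmsd = 0, clash_count = 0L), class = "hx_pose")
  base <- empirical_score(mkpose(lig_far), rec)
  expect_equal(base$hbond_term, 0)

  lig_hb <- lig_far
  lig_hb$conformers[[1]] <- rbind(c(2.9, 0, 0), c(1.9, 0, 0))  # N-H...O=C, 180 deg
  hb <- empirical_score(mkpose(lig_hb), rec)
  expect_equal(hb$hbond_term, 1.0, tolerance = 1e-12)
  w <- empirical_weights()
  delta_other <- (hb$total - w[["hbond"]] * hb$hbond_term) -
    (base$total - w[["hbond"]] * base$hbond_term)
  expect_equal(hb$total - base$total - delta_other, w[["hbond"]],
               tolerance = 1e-9)
})

test_that("scores are invariant under rigid motion of the whole complex", {
  s <- scene_pose(seed = 4L)
  pose <- s$poses[[1]]
  e0 <- empirical_score(pose, s$monomer)
  m0 <- mmpbsa_energy(pose, s$monomer)

  set.seed(31)
  R <- random_rotation(); t <- c(7, -4, 2)
  pose2 <- pose
  pose2$coords <- sweep(pose$coords %*% t(R), 2, t, "+")
  rec2 <- s$monomer
  rec2$frames[[1]] <- sweep(rec2$frames[[1]] %*% t(R), 2, t, "+")
  e1 <- empirical_score(pose2, rec2)
  m1 <- mmpbsa_energy(pose2, rec2)
  expect_equal(e0$total, e1$total, tolerance = 1e-6)
  ## distance-only terms are exactly invariant
  for (term in c("e_vdw", "e_elec", "g_polar"))
    expect_equal(m0[[term]], m1[[term]], tolerance = 1e-6)
  ## SASA terms use a fixed-orientation quadrature grid, so invariance holds
  ## only to the quadrature resolution (960 points per atom)
  expect_equal(m0$g_nonpolar, m1$g_nonpolar, tolerance = 0.02)
  expect_equal(m0$total, m1$total, tolerance = 0.02)
})

test_that("single-ion GB energy matches the Born closed form within 0.1%", {
  for (radius in c(1, 2, 3.5, 5)) for (q in c(-2, -1, 1, 2)) {
    got <- gb_polar_energy(matrix(0, 1, 3), q, radius, eps_solvent = 80)
    born <- -0.5 * 332.0637 * (1 - 1 / 80) * q^2 / radius
    expect_equal(got, born, tolerance = 1e-3)
  }
  ## effective radius of an isolated atom is its intrinsic radius
  expect_equal(effective_born_radii(matrix(0, 1, 3), 2.09), 2.0,
               tolerance = 1e-12)
})

test_that("isolated-sphere SASA matches the closed form within 2%", {
  for (r in c(1.2, 1.7, 2.5)) {
    got <- shrake_rupley(matrix(0, 1, 3), r, probe = 1.4, n_points = 960L)
    expect_equal(got, 4 * pi * (r + 1.4)^2, tolerance = 0.02)
  }
  ## a deeply buried atom has zero accessible area
  cluster <- rbind(c(0, 0, 0), 2.2 * rbind(
    c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1),
    c(.7, .7, 0), c(-.7, .7, 0), c(.7, -.7, 0), c(-.7, -.7, 0),
    c(.7, 0, .7), c(-.7, 0, .7), c(.7, 0, -.7), c(-.7, 0, -.7),
    c(0, .7, .7), c(0, -.7, .7), c(0, .7, -.7), c(0, -.7, -.7)))
  sas <- shrake_rupley(cluster, rep(1.7, nrow(cluster)))
  expect_equal(sas[1], 0)
})

test_that("MM-GBSA bookkeeping holds and vanishes at infinite separation", {
  s <- scene_pose(seed = 5L)
  pose <- s$poses[[1]]
  mm <- mmpbsa_energy(pose, s$monomer)
  expect_false(mm$entropy_included)
  expect_equal(mm$total,
               mm$e_vdw + mm$e_elec + mm$g_polar + mm$g_nonpolar,
               tolerance = 1e-6)

  far <- pose; far$coords <- far$coords + 1000
  mmf <- mmpbsa_energy(far, s$monomer)
  expect_lt(abs(mmf$e_vdw), 1e-6)
  expect_lt(abs(mmf$e_elec), 1e-3)
  expect_lt(abs(mmf$g_polar), 1e-3)
  expect_lt(abs(mmf$dsasa), 1e-9)
  ## only the constant nonpolar offset survives
  expect_equal(mmf$total, solvation_settings()$beta, tolerance = 1e-3)
})

test_that("group electrostatics partition the MM term exactly", {
  s <- scene_pose(seed = 6L)
  pose <- s$poses[[1]]
  mm <- mmpbsa_energy(pose, s$monomer)

  ## trivial partition: everything in one group
  all_in_one <- group_electrostatics(pose, s$monomer,
                                     groups = list(all = seq_len(nrow(pose$ligand$atoms))))
  expect_equal(all_in_one$e_elec_group, mm$e_elec, tolerance = 1e-6)

  ## default partition: named groups + remainder sum to the MM term
  ge <- group_electrostatics(pose, s$monomer)
  expect_equal(sum(ge$e_elec_group), mm$e_elec, tolerance = 1e-6)

  ## a zero-charge group contributes nothing
  zero_idx <- which(pose$ligand$atoms$charge == 0)[1:3]
  gz <- group_electrostatics(pose, s$monomer, groups = list(z = zero_idx))
  expect_equal(gz$e_elec_group, 0, tolerance = 1e-12)

  ## overlapping groups are rejected
  expect_error(group_electrostatics(pose, s$monomer,
                                    groups = list(a = 1:2, b = 2:3)),
               "more than one group")
})

test_that("a nitro group beside a lysine ammonium dominates the electrostatics", {
  ## minimal fixture: isolated lysine-like ammonium; ligand = nitro group
  ## 2.8 A from the ammonium nitrogen plus a neutral hydrophobic tail
  rec <- assign_parameters(tiny_structure(list(
    atom_spec("CE", "A", 1, "C", c(-1.5, 0, 0), resname = "LYS"),
    atom_spec("NZ", "A", 1, "N", c(0, 0, 0), resname = "LYS"),
    atom_spec("HZ1", "A", 1, "H", c(1.0, 0, 0), resname = "LYS"),
    atom_spec("HZ2", "A", 1, "H", c(-0.33, 0.94, 0), resname = "LYS"),
    atom_spec("HZ3", "A", 1, "H", c(-0.33, -0.47, 0.82), resname = "LYS"))))
  lg <- make_ligand("nitroprobe", c("N", "O", "O", "C", "C"),
                    rbind(c(4.0, 0, 0), c(2.8, 0, 0), c(4.6, 1.05, 0),
                          c(5.5, -0.6, 0), c(7.0, -0.6, 0)),
                    data.frame(i = c(1, 1, 1, 4), j = c(2, 3, 4, 5),
                               order = c(2L, 1L, 1L, 1L)),
                    charges = c(0.65, -0.55, -0.55, 0, 0))
  lg <- local({q <- lg$atoms$charge; l <- assign_parameters(lg)
               l$atoms$charge <- q; l})
  pose <- structure(list(ligand = lg, conformer = 1L, rotation = diag(3),
                         translation = c(0, 0, 0),
                         coords = lg$conformers[[1]], pharm_rmsd = 0,
                         clash_count = 0L), class = "hx_pose")
  ge <- group_electrostatics(pose, rec,
                             groups = list(nitro = 1:3, tail = 4:5))
  ## per-atom Coulomb audit reproduces the group sums
  per_atom <- vapply(1:5, function(i)
    sum(332.0637 * lg$atoms$charge[i] * rec$atoms$charge /
          sqrt(colSums((t(rec$frames[[1]]) - pose$coords[i, ])^2))), 0)
  expect_equal(ge$e_elec_group, c(sum(per_atom[1:3]), sum(per_atom[4:5])),
               tolerance = 1e-9)
  expect_lt(ge$e_elec_group[1], -20)
  expect_lt(ge$e_elec_group[1], ge$e_elec_group[2])
})

test_that("charged-group removal weakens the minimized group electrostatics", {
  ## group energies are read off minimized docked poses, as in the protocol
  s <- scene_pose(seed = 8L, n_actives = 2L, n_analogs = 2L)
  vals <- vapply(seq_along(s$lib), function(k) {
    mini <- local_minimize(s$poses[[k]], s$monomer)
    group_electrostatics(mini, s$monomer,
                         groups = list(nitro = s$lib[[k]]$groups$nitro)
                         )$e_elec_group
  }, 0)
  names(vals) <- vapply(s$lib, `[[`, "", "name")
  expect_true(max(vals[grep("^active", names(vals))]) <
                min(vals[grep("^analog", names(vals))]))
})
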