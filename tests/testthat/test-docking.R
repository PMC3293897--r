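# Pose placement, reduced-radius clash filtering, screening, minimization.

test_that("placement is rigid and idempotent", {
  sc <- default_scene(seed = 5L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 1, n_decoys = 0,
                                          seed = 2L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  lg <- lib[[1]]
  fts <- type_ligand_features(lg, 1)
  m <- match_pharmacophore(fts, sc$model)
  pose <- place_pose(lg, 1, m)

  ## rigidity: all intra-ligand distances preserved
  d0 <- dist(lg$conformers[[1]])
  d1 <- dist(pose$coords)
  expect_lt(max(abs(d0 - d1)), 1e-9)

  ## idempotence: re-typing and re-matching the placed conformer
  lg2 <- lg
  lg2$conformers[[1]] <- pose$coords
  m2 <- match_pharmacophore(type_ligand_features(lg2, 1), sc$model)
  expect_equal(m2$rmsd, m$rmsd, tolerance = 1e-9)

  ## an unaccepted match cannot be placed
  bad <- m; bad$accepted <- FALSE
  expect_error(place_pose(lg, 1, bad), "unaccepted")
})

test_that("clash rule arithmetic matches the 40% radius reduction", {
  rec <- tiny_structure(list(
    atom_spec("C1", "A", 1, "C", c(0, 0, 0), radius = 1.7)))
  lg <- make_ligand("probe", "C", matrix(c(2.72, 0, 0), 1),
                    data.frame(i = integer(0), j = integer(0),
                               order = integer(0)))
  lg$atoms$radius <- 1.7
  pose <- structure(list(ligand = lg, conformer = 1L, rotation = diag(3),
                         translation = c(0, 0, 0),
                         coords = lg$conformers[[1]], pharm_rmsd = 0,
                         clash_count = NA), class = "hx_pose")
  ## full radii: 2.72 < 3.4 clashes; reduced radii: 2.72 >= 2.04 does not
  expect_equal(clash_check(pose, rec, radius_scale = 1.0)$clash_count, 1L)
  expect_equal(clash_check(pose, rec, radius_scale = 0.6)$clash_count, 0L)
  expect_error(clash_check(pose, rec, radius_scale = 1.5), "radius_scale")
  expect_error(clash_check(pose, rec, radius_scale = 0), "radius_scale")

  ## far pose never clashes
  pose$coords <- pose$coords + 50
  expect_equal(clash_check(pose, rec, 1.0)$clash_count, 0L)
})

test_that("clash counts are monotone in the radius scale", {
  sc <- default_scene(seed = 7L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 3, n_decoys = 0,
                                          seed = 4L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  for (lg in lib) {
    m <- match_pharmacophore(type_ligand_features(lg, 1), sc$model)
    pose <- place_pose(lg, 1, m)
    c06 <- clash_check(pose, sc$monomer, 0.6)$clash_count
    c08 <- clash_check(pose, sc$monomer, 0.8)$clash_count
    c10 <- clash_check(pose, sc$monomer, 1.0)$clash_count
    expect_lte(c06, c08)
    expect_lte(c08, c10)
  }
})

test_that("screening separates constructed actives from decoys", {
  sc <- default_scene(seed = 1L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 6, n_decoys = 9,
                                          seed = 3L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  out <- screen_library(lib, sc$model, sc$monomer)
  expect_equal(sort(out$entries$ligand),
               sort(grep("^active", vapply(lib, `[[`, "", "name"),
                         value = TRUE)))
  ## post-hoc audit: every survivor satisfies the published criteria
  expect_true(all(out$entries$pharm_rmsd <= out$criteria$gate))
  expect_true(all(out$entries$clash_count <= out$criteria$max_clashes))
  ## rejection log covers every decoy conformer
  expect_setequal(unique(out$rejections$ligand),
                  grep("^decoy", vapply(lib, `[[`, "", "name"), value = TRUE))
})

test_that("screening output is invariant under library input order", {
  sc <- default_scene(seed = 1L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 4, n_decoys = 4,
                                          seed = 5L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  a <- screen_library(lib, sc$model, sc$monomer)
  b <- screen_library(rev(lib), sc$model, sc$monomer)
  expect_equal(a$entries, b$entries)
})

test_that("a zero gate only admits exact-geometry matches", {
  sc <- default_scene(seed = 1L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 4, n_decoys = 0,
                                          seed = 6L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  strict <- screen_library(lib, sc$model, sc$monomer, gate = 0.0)
  loose <- screen_library(lib, sc$model, sc$monomer, gate = 1.0)
  expect_lt(nrow(strict$entries), nrow(loose$entries))
  expect_equal(nrow(loose$entries), 4L)
})

test_that("rigid minimization descends and respects internal geometry", {
  sc <- default_scene(seed = 2L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 2, n_decoys = 0,
                                          seed = 7L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  for (lg in lib) {
    m <- match_pharmacophore(type_ligand_features(lg, 1), sc$model)
    pose <- place_pose(lg, 1, m)
    e0 <- helixscreen:::intermolecular_energy(pose$coords, lg$atoms,
                                              sc$monomer)
    mini <- local_minimize(pose, sc$monomer)
    expect_lte(attr(mini, "energy"), e0)
    expect_lt(max(abs(dist(mini$coords) - dist(pose$coords))), 1e-9)
  }
})

test_that("a converged pose is a fixed point of the minimizer", {
  sc <- default_scene(seed = 2L, n_frames = 1L)
  lib <- make_ligand_library(library_spec(n_actives = 1, n_decoys = 0,
                                          seed = 7L),
                             sc$model, away_from = sc$center,
                             avoid = sc$heavy)
  lg <- lib[[1]]
  pose <- place_pose(lg, 1,
                     match_pharmacophore(type_ligand_features(lg, 1),
                                         sc$model))
  mini <- local_minimize(pose, sc$monomer, steps = 5000L)
  again <- local_minimize(mini, sc$monomer, steps = 5000L)
  expect_equal(attr(again, "energy"), attr(mini, "energy"), tolerance = 1e-9)
  expect_lt(max(abs(again$coords - mini$coords)), 1e-9)
})

test_that("a two-atom system converges to the Lennard-Jones minimum", {
  ## receptor: one carbon at origin; ligand: one carbon 0.5 A beyond r_min
  rmin <- 2 * 1.908
  rec <- tiny_structure(list(
    atom_spec("C1", "A", 1, "C", c(0, 0, 0), epsilon = 0.086,
              rmin_half = 1.908, radius = 1.7)))
  lg <- make_ligand("probe", "C", matrix(c(rmin + 0.5, 0, 0), 1),
                    data.frame(i = integer(0), j = integer(0),
                               order = integer(0)))
  lg$atoms$epsilon <- 0.086; lg$atoms$rmin_half <- 1.908; lg$atoms$radius <- 1.7
  pose <- structure(list(ligand = lg, conformer = 1L, rotation = diag(3),
                         translation = c(0, 0, 0),
                         coords = lg$conformers[[1]], pharm_rmsd = 0,
                         clash_count = 0L), class = "hx_pose")
  mini <- local_minimize(pose, rec, steps = 400L)
  sep <- sqrt(sum(mini$coords^2))
  ## 1-D scan oracle: the minimum of the pair potential sits at r_min
  scan_r <- seq(3, 5, by = 1e-4)
  scan_e <- 0.086 * ((rmin / scan_r)^12 - 2 * (rmin / scan_r)^6)
  expect_equal(scan_r[which.min(scan_e)], rmin, tolerance = 1e-3)
  expect_equal(sep, rmin, tolerance = 0.05)
})
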