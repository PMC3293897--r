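# Pairwise energetics, interface matrix, hydrogen bonds, hot-spot ranking.

two_atom_structure <- function(r, q1 = 0, q2 = 0, eps = 0, rmin_half = 0) {
  tiny_structure(list(
    atom_spec("X1", "A", 1, "C", c(0, 0, 0), charge = q1, epsilon = eps,
              rmin_half = rmin_half, radius = 1.7),
    atom_spec("X2", "B", 1, "C", c(r, 0, 0), charge = q2, epsilon = eps,
              rmin_half = rmin_half, radius = 1.7)))
}

test_that("Coulomb and Lennard-Jones closed forms are reproduced exactly", {
  ## unit charges at r = k/100 with constant dielectric 1 give -100 kcal/mol
  s <- two_atom_structure(3.320637, q1 = 1, q2 = -1)
  e <- pair_energy(s, "A:1", "B:1",
                   dielectric = dielectric_model("constant", value = 1))
  expect_equal(e[["e_elec"]], -100.0, tolerance = 1e-12)
  expect_equal(e[["e_vdw"]], 0)

  ## apolar pair at the pair minimum: e_vdw = -eps_ij exactly
  s2 <- two_atom_structure(3.816, eps = 0.086, rmin_half = 1.908)
  e2 <- pair_energy(s2, "A:1", "B:1")
  expect_equal(e2[["e_vdw"]], -0.086, tolerance = 1e-12)

  ## asymptotic decay: both terms vanish at 1e4 Angstrom
  s3 <- two_atom_structure(1e4, q1 = 1, q2 = -1, eps = 0.086,
                           rmin_half = 1.908)
  e3 <- pair_energy(s3, "A:1", "B:1")
  expect_lt(max(abs(e3)), 1e-6)
})

test_that("overlapping atoms trigger the numeric guard", {
  s <- two_atom_structure(1e-8, q1 = 1, q2 = -1)
  expect_error(pair_energy(s, "A:1", "B:1"), "overlapping")
})

test_that("matrix total equals a single-pass atom-pairwise brute force", {
  sc <- default_scene(seed = 4L, n_frames = 1L)
  st <- sc$dimer$structure
  ia <- which(st$atoms$chain == "A"); ib <- which(st$atoms$chain == "B")
  oracle <- brute_interaction(st, ia, ib)
  m <- interface_matrix(st, "A", "B")
  expect_equal(sum(m$e_total), sum(oracle), tolerance = 1e-6)
  expect_equal(sum(m$e_vdw), oracle[["e_vdw"]], tolerance = 1e-6)
  ## per-residue totals are consistent row/column sums
  expect_equal(unname(m$per_residue_totals[rownames(m$e_total)]),
               unname(rowSums(m$e_total)), tolerance = 1e-9)
})

test_that("energies are invariant under global rigid motion", {
  set.seed(11)
  st <- make_toy_dimer()$structure
  m0 <- interface_matrix(st, "A", "B")
  R <- random_rotation()
  st2 <- st
  st2$frames[[1]] <- sweep(st$frames[[1]] %*% t(R), 2, c(5, -3, 12), "+")
  m1 <- interface_matrix(st2, "A", "B")
  expect_equal(m0$e_total, m1$e_total, tolerance = 1e-9)
})

test_that("frame averaging is linear and degenerate ensembles have zero spread", {
  st <- make_toy_dimer()$structure
  ens5 <- helixscreen:::new_structure(st$atoms, rep(st$frames[1], 5))
  m1 <- interface_matrix(st, "A", "B")
  m5 <- interface_matrix(ens5, "A", "B")
  expect_equal(m5$e_total, m1$e_total, tolerance = 1e-12)
  expect_true(all(m5$sd_total == 0))

  ens <- jitter_ensemble(st, sigma = 0.15, n_frames = 4L, seed = 9L)
  mavg <- interface_matrix(ens, "A", "B")
  per_frame <- lapply(1:4, function(f)
    interface_matrix(ens, "A", "B", frames = f)$e_total)
  expect_equal(mavg$e_total, Reduce(`+`, per_frame) / 4, tolerance = 1e-9)
})

test_that("chain swap transposes the matrix with identical energies", {
  st <- make_toy_dimer()$structure
  ab <- interface_matrix(st, "A", "B")
  ba <- interface_matrix(st, "B", "A")
  expect_equal(ab$e_total, t(ba$e_total), tolerance = 1e-12)
})

test_that("the planted salt bridge is the most negative electrostatic entry", {
  st <- make_toy_dimer()$structure
  m <- interface_matrix(st, "A", "B")
  w <- which(m$e_elec == min(m$e_elec), arr.ind = TRUE)
  pair <- c(rownames(m$e_elec)[w[1]], colnames(m$e_elec)[w[2]])
  ## lysine-ammonium against glutamate-carboxylate across the interface
  expect_true(pair[1] %in% c("A:204", "A:207"))
  expect_true(pair[2] %in% c("B:204", "B:207"))
  expect_true(any(grepl(":204", pair)) && any(grepl(":207", pair)))
})

test_that("empty frame selections and identical chains are rejected", {
  st <- make_toy_dimer()$structure
  expect_error(interface_matrix(st, "A", "B", frames = integer(0)), "empty")
  expect_error(interface_matrix(st, "A", "A"), "distinct")
})

test_that("hydrogen-bond detection applies the geometric criteria", {
  ## ideal amide-to-carbonyl geometry: N...O = 2.9 A, angle 180 deg
  ideal <- tiny_structure(list(
    atom_spec("N", "A", 1, "N", c(0, 0, 0), resname = "GLN"),
    atom_spec("H", "A", 1, "H", c(1.0, 0, 0), resname = "GLN"),
    atom_spec("O", "B", 1, "O", c(2.9, 0, 0), resname = "GLU")))
  out <- detect_hbonds(ideal)
  expect_equal(nrow(out$events), 1L)
  expect_equal(out$occupancy$occupancy, 1.0)
  expect_equal(out$events$angle, 180, tolerance = 1e-6)

  ## beyond the default 3.5 A ceiling: no event
  far <- tiny_structure(list(
    atom_spec("N", "A", 1, "N", c(0, 0, 0)),
    atom_spec("H", "A", 1, "H", c(1.0, 0, 0)),
    atom_spec("O", "B", 1, "O", c(4.5, 0, 0))))
  expect_equal(nrow(detect_hbonds(far)$events), 0L)

  ## no hydrogens at all: usage error
  bare <- tiny_structure(list(
    atom_spec("N", "A", 1, "N", c(0, 0, 0)),
    atom_spec("O", "B", 1, "O", c(2.9, 0, 0))))
  expect_error(detect_hbonds(bare), "explicit-H")
})

test_that("planted donor/acceptor pairs keep high occupancy under jitter", {
  st <- make_toy_dimer()$structure
  ens <- jitter_ensemble(st, sigma = 0.1, n_frames = 20L, seed = 5L)
  out <- detect_hbonds(ens)
  occ <- out$occupancy
  planted <- occ[occ$donor_res == "A:203" & occ$acceptor_res == "B:207", ]
  expect_gte(nrow(planted), 1L)
  expect_gte(max(planted$occupancy), 0.9)

  ## independent geometric audit of the same pair, frame by frame
  a <- ens$atoms
  dh <- which(a$chain == "A" & a$resno == 203 & a$name == "NE2")
  hh <- which(a$chain == "A" & a$resno == 203 & a$name == "HE21")
  ac <- which(a$chain == "B" & a$resno == 207 & a$name == "OE1")
  hits <- vapply(ens$frames, function(fr) {
    d <- sqrt(sum((fr[dh, ] - fr[ac, ])^2))
    v1 <- fr[dh, ] - fr[hh, ]; v2 <- fr[ac, ] - fr[hh, ]
    ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
    d <= 3.5 && ang >= 120
  }, TRUE)
  audit_occ <- mean(hits)
  got <- occ$occupancy[occ$donor_heavy == dh & occ$acceptor == ac]
  expect_equal(got, audit_occ, tolerance = 1e-12)
})

test_that("hot-spot ranking puts the planted residues on top", {
  sc <- default_scene(seed = 2L, n_frames = 5L)
  rk <- sc$report$ranked
  top_a <- rk$residue[rk$chain == "A"][1:3]
  expect_setequal(top_a, c("A:203", "A:204", "A:207"))
  ## without a conservation map, the criterion is reported unevaluated
  expect_false(sc$report$criteria$conservation_evaluated)
  expect_true(all(is.na(rk$conservation)))

  with_cons <- rank_hotspots(sc$matrix, sc$hbonds,
                             conservation = setNames(rep(1, nrow(rk)),
                                                     rk$residue))
  expect_true(with_cons$criteria$conservation_evaluated)
})

test_that("an inert well-separated dimer produces no hot spots", {
  d <- make_toy_dimer(dimer_spec(separation = 14, planted_contacts = FALSE,
                                 hydrophobic_patch = FALSE))
  m <- interface_matrix(d$structure, "A", "B")
  expect_true(all(m$per_residue_totals >= -0.1))
  rep <- rank_hotspots(m, NULL)
  expect_false(any(rep$ranked$flagged))
})
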