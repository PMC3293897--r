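# Shared fixtures and independent oracles for the test suite.

## bare structure from an atom spec list: list(name, resname, chain, resno,
## element, xyz, charge, epsilon, rmin_half, radius)
tiny_structure <- function(specs, n_frames = 1L) {
  atoms <- do.call(rbind, lapply(seq_along(specs), function(k) {
    s <- specs[[k]]
    data.frame(serial = k, name = s$name, resname = s$resname,
               chain = s$chain, resno = s$resno, element = s$element,
               charge = s$charge %||% 0, epsilon = s$epsilon %||% 0,
               rmin_half = s$rmin_half %||% 0, radius = s$radius %||% 0,
               is_h = s$element == "H", stringsAsFactors = FALSE)
  }))
  xyz <- do.call(rbind, lapply(specs, function(s) s$xyz))
  helixscreen:::new_structure(atoms, rep(list(xyz), n_frames))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

atom_spec <- function(name, chain, resno, element, xyz, resname = "UNK",
                      charge = 0, epsilon = 0, rmin_half = 0, radius = 0) {
  list(name = name, resname = resname, chain = chain, resno = resno,
       element = element, xyz = xyz, charge = charge, epsilon = epsilon,
       rmin_half = rmin_half, radius = radius)
}

## hand-assembled ligands -----------------------------------------------------

make_ligand <- function(name, elements, coords, bonds, charges = NULL) {
  atoms <- data.frame(name = paste0(elements, seq_along(elements)),
                      element = elements,
                      charge = charges %||% rep(0, length(elements)),
                      epsilon = 0, rmin_half = 0, radius = 0,
                      is_h = elements == "H", stringsAsFactors = FALSE)
  helixscreen:::new_ligand(name, atoms, bonds, list(coords))
}

## linear alkane with explicit hydrogens (geometry schematic but bonded)
alkane_ligand <- function(n_carbon, name = paste0("C", n_carbon)) {
  elements <- rep("C", n_carbon)
  coords <- cbind(1.54 * (seq_len(n_carbon) - 1), 0, 0)
  bonds <- if (n_carbon > 1)
    data.frame(i = seq_len(n_carbon - 1), j = seq_len(n_carbon - 1) + 1L,
               order = 1L)
  else data.frame(i = integer(0), j = integer(0), order = integer(0))
  nH <- if (n_carbon == 1) 4 else c(3, rep(2, max(0, n_carbon - 2)), 3)
  for (k in seq_len(n_carbon)) {
    for (h in seq_len(nH[k])) {
      elements <- c(elements, "H")
      coords <- rbind(coords, c(1.54 * (k - 1), 0.6 * h, 1.0))
      bonds <- rbind(bonds, data.frame(i = k, j = length(elements), order = 1L))
    }
  }
  make_ligand(name, elements, coords, bonds)
}

benzene_ligand <- function(shift = c(0, 0, 0)) {
  elements <- c(rep("C", 6), rep("H", 6))
  th <- (0:5) * pi / 3
  coords <- rbind(cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                  cbind(2.47 * cos(th), 2.47 * sin(th), 0))
  coords <- sweep(coords, 2, shift, "+")
  bonds <- data.frame(i = c(1:6, 1:6), j = c(2:6, 1, 7:12),
                      order = c(rep(c(2L, 1L), 3), rep(1L, 6)))
  make_ligand("benzene", elements, coords, bonds)
}

nitrobenzene_ligand <- function() {
  b <- benzene_ligand()
  elements <- c(b$atoms$element[1:6], b$atoms$element[8:12], "N", "O", "O")
  coords <- rbind(b$conformers[[1]][1:6, ], b$conformers[[1]][8:12, ],
                  c(2.86, 0, 0), c(3.5, 1.05, 0), c(3.5, -1.05, 0))
  bonds <- data.frame(
    i = c(1:6, 2:6, 1, 12, 12),
    j = c(2:6, 1, 7:11, 12, 13, 14),
    order = c(rep(c(2L, 1L), 3), rep(1L, 5), 1L, 2L, 1L))
  make_ligand("nitrobenzene", elements, coords, bonds)
}

## two phenyls + urea core + explicit hydrogens on N
diphenyl_urea_ligand <- function() {
  ringA <- benzene_ligand(shift = c(-5, 0, 0))$conformers[[1]]
  ringB <- benzene_ligand(shift = c(5, 0, 0))$conformers[[1]]
  elements <- c(rep("C", 6), rep("H", 5),      # ring A (one H replaced by N)
                rep("C", 6), rep("H", 5),      # ring B
                "N", "H", "C", "O", "N", "H")  # urea
  coords <- rbind(ringA[1:6, ], ringA[8:12, ],
                  ringB[1:6, ], ringB[8:12, ],
                  c(-2.5, 0, 0), c(-2.5, 1.0, 0),
                  c(-1.2, -0.6, 0), c(-1.2, -1.83, 0),
                  c(0.1, 0, 0), c(0.1, 1.0, 0))
  ring_bonds <- function(off)
    data.frame(i = off + c(1:6, 2:6), j = off + c(2:6, 1, 7:11),
               order = c(rep(c(2L, 1L), 3), rep(1L, 5)))
  bonds <- rbind(ring_bonds(0), ring_bonds(11),
                 data.frame(i = c(1, 23, 23, 25, 25, 27, 12),
                            j = c(23, 24, 25, 26, 27, 28, 27),
                            order = c(1L, 1L, 1L, 2L, 1L, 1L, 1L)))
  make_ligand("diphenylurea", elements, coords, bonds)
}

## independent oracles ----------------------------------------------------------

## plain-loop Coulomb + LJ over all atom pairs of two index sets (one frame)
brute_interaction <- function(x, idx_a, idx_b, frame = 1L,
                              diel_type = "distance", diel_par = 4) {
  fr <- x$frames[[frame]]; a <- x$atoms
  ev <- 0; ee <- 0
  for (i in idx_a) for (j in idx_b) {
    r <- sqrt(sum((fr[i, ] - fr[j, ])^2))
    rmin <- a$rmin_half[i] + a$rmin_half[j]
    eps <- sqrt(a$epsilon[i] * a$epsilon[j])
    ev <- ev + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
    epsr <- if (diel_type == "distance") diel_par * r else diel_par
    ee <- ee + 332.0637 * a$charge[i] * a$charge[j] / (epsr * r)
  }
  c(e_vdw = ev, e_elec = ee)
}

## all permutations of v (for the brute-force matcher scan)
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v))
    for (p in perms(v[-k])) out[[length(out) + 1L]] <- c(v[k], p)
  out
}

## brute-force minimal pharmacophore RMSD: scan every injective
## kind-compatible assignment via permutations of ligand feature indices
brute_best_rmsd <- function(ligand_features, model) {
  mk <- model$features$kind
  mx <- as.matrix(model$features[, c("x", "y", "z")])
  lk <- ligand_features$kind
  lx <- as.matrix(ligand_features[, c("x", "y", "z")])
  n <- length(mk)
  if (nrow(ligand_features) < n) return(Inf)
  best <- Inf
  idx <- seq_len(nrow(ligand_features))
  combs <- utils::combn(idx, n, simplify = FALSE)
  for (cb in combs) for (p in perms(cb)) {
    if (!all(lk[p] == mk)) next
    s <- superpose(lx[p, , drop = FALSE], mx)
    if (s$rmsd < best) best <- s$rmsd
  }
  best
}

random_rotation <- function() {
  ## QR of a random Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## standard synthetic scene shared by several files
default_scene <- function(seed = 1L, n_frames = 5L) {
  d <- make_toy_dimer(dimer_spec(seed = seed))
  rec <- jitter_ensemble(d$structure, sigma = 0.1, n_frames = n_frames,
                         seed = seed + 1L)
  mat <- interface_matrix(rec, "A", "B")
  hb <- detect_hbonds(rec)
  rep <- rank_hotspots(mat, hb)
  rk <- rep$ranked
  hydro <- rownames(mat$e_vdw)[rowSums(mat$e_vdw) <= -0.25 &
                                 mat$res_a$resname %in%
                                   helixscreen:::HYDROPHOBIC_RES]
  hot <- sort(unique(c(rk$residue[rk$flagged & rk$chain == "A"], hydro)))
  ph <- derive_interface_pharmacophore(rec, hot)
  mono <- select_chain(rec, "A")
  list(dimer = d, receptor = rec, matrix = mat, hbonds = hb, report = rep,
       hotspots = hot, model = ph, monomer = mono,
       heavy = mono$frames[[1]][!mono$atoms$is_h, , drop = FALSE],
       center = colMeans(mono$frames[[1]]))
}
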