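# Empirical rescoring and MM-GBSA-style binding energies -----------------------
#
# Two scoring layers over placed poses:
#   * an additive empirical contact score (vdW 8-4 contacts, hydrogen-bond
#     ramps, hydrophobic carbon contacts, rotor penalty) in the spirit of
#     published empirical functions; its absolute values are not comparable
#     to any published scale and the weights are configuration;
#   * an end-point binding energy: intermolecular MM terms (dielectric 1)
#     plus polar solvation from a pairwise generalized-Born model with
#     HCT-style effective radii and nonpolar solvation from a linear
#     SASA model (Shrake-Rupley sampling). Entropy is never included.

#' Empirical score weights
#' @param vdw,hbond,hydrophobic,rotor term weights
#' @return named numeric vector
#' @export
empirical_weights <- function(vdw = 0.004, hbond = 0.5, hydrophobic = 0.1,
                              rotor = 0.5) {
  c(vdw = vdw, hbond = hbond, hydrophobic = hydrophobic, rotor = rotor)
}

hbond_ramp_dist <- function(d) pmax(0, pmin(1, (3.5 - d) / 0.5))
hbond_ramp_angle <- function(a) pmax(0, pmin(1, (a - 120) / 30))

ligand_attached_h <- function(lig) {
  nb <- heavy_neighbors(lig)
  hs <- which(lig$atoms$is_h)
  heavy <- vapply(hs, function(h) {
    nn <- nb[[h]]
    nn <- nn[!lig$atoms$is_h[nn]]
    if (length(nn)) nn[1] else NA_integer_
  }, 0L)
  data.frame(h = hs, heavy = heavy)[!is.na(heavy), , drop = FALSE]
}

intermolecular_hbonds <- function(pose, receptor) {
  ## both directions: ligand donor -> receptor acceptor and vice versa
  lc <- pose$coords
  rc <- receptor$frames[[1]]
  la <- pose$ligand$atoms
  ra <- receptor$atoms
  att_l <- ligand_attached_h(pose$ligand)
  att_r <- structure_bond_guess(receptor)
  don_l <- att_l[la$element[att_l$heavy] %in% c("N", "O"), , drop = FALSE]
  don_r <- att_r[ra$element[att_r$heavy] %in% c("N", "O"), , drop = FALSE]
  acc_l <- which(la$element == "O" |
                 (la$element == "N" & !(seq_len(nrow(la)) %in% att_l$heavy)))
  acc_r <- which(ra$element == "O" |
                 (ra$element == "N" & !(seq_len(nrow(ra)) %in% att_r$heavy)))
  strength <- 0
  events <- list()
  score_one <- function(dh, hh, ac, cd, ch, ca) {
    d <- sqrt(sum((cd - ca)^2))
    if (d > 3.5) return(0)
    v1 <- cd - ch; v2 <- ca - ch
    ang <- acos(pmin(pmax(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)), -1), 1)) * 180 / pi
    hbond_ramp_dist(d) * hbond_ramp_angle(ang)
  }
  for (r in seq_len(nrow(don_l))) for (ac in acc_r) {
    s <- score_one(don_l$heavy[r], don_l$h[r], ac,
                   lc[don_l$heavy[r], ], lc[don_l$h[r], ], rc[ac, ])
    if (s > 0) {
      strength <- strength + s
      events[[length(events) + 1L]] <- data.frame(
        direction = "ligand_donor", donor = don_l$heavy[r], acceptor = ac,
        strength = s)
    }
  }
  for (r in seq_len(nrow(don_r))) for (ac in acc_l) {
    s <- score_one(don_r$heavy[r], don_r$h[r], ac,
                   rc[don_r$heavy[r], ], rc[don_r$h[r], ], lc[ac, ])
    if (s > 0) {
      strength <- strength + s
      events[[length(events) + 1L]] <- data.frame(
        direction = "receptor_donor", donor = don_r$heavy[r], acceptor = ac,
        strength = s)
    }
  }
  list(strength = strength,
       events = if (length(events)) do.call(rbind, events)
                else data.frame(direction = character(0), donor = integer(0),
                                acceptor = integer(0), strength = numeric(0)))
}

#' Empirical additive rescoring of a pose
#'
#' Terms (all favorable-positive, higher total is better):
#' * `vdw_term`: soft 8-4 contact sum over heavy ligand/receptor pairs,
#'   `-[(d0/d)^8 - 2 (d0/d)^4]` with `d0 = r_i + r_j` (1 per ideal contact,
#'   strongly negative on overlap);
#' * `hbond_term`: sum of distance x angle ramps over intermolecular
#'   hydrogen bonds (1 at ideal geometry: donor-acceptor <= 3.0 A, angle at
#'   H >= 150 deg; 0 beyond 3.5 A or below 120 deg);
#' * `hydrophobic_term`: count of carbon-carbon heavy pairs within 4.5 A;
#' * `rotor_term`: -0.5 per rotatable bond.
#' The total is the weight-weighted sum; it depends on interatomic
#' distances only and is invariant under rigid motion of the complex.
#'
#' @param pose an `hx_pose` (parameterized)
#' @param receptor parameterized `hx_structure`
#' @param weights from [empirical_weights()]
#' @return an `hx_empirical_score`: list(vdw_term, hbond_term,
#'   hydrophobic_term, rotor_term, total, weights)
#' @export
empirical_score <- function(pose, receptor, weights = empirical_weights()) {
  la <- pose$ligand$atoms
  if (all(la$radius == 0) || all(receptor$atoms$radius == 0))
    stop("unparameterized atoms; run assign_parameters() first")
  lh <- which(!la$is_h); rh <- which(!receptor$atoms$is_h)
  lc <- pose$coords[lh, , drop = FALSE]
  rc <- receptor$frames[[1]][rh, , drop = FALSE]
  d <- sqrt(pmax(outer(rowSums(lc^2), rowSums(rc^2), "+") - 2 * lc %*% t(rc), 0))
  d0 <- outer(la$radius[lh], receptor$atoms$radius[rh], "+")
  near <- d < 8
  vdw_term <- 0
  if (any(near)) {
    q <- (d0[near] / d[near])^4
    vdw_term <- -sum(q^2 - 2 * q)
  }
  hb <- intermolecular_hbonds(pose, receptor)
  cc <- outer(la$element[lh] == "C", receptor$atoms$element[rh] == "C") & d <= 4.5
  hydrophobic_term <- sum(cc)
  rotor_term <- -0.5 * count_rotatable(pose$ligand)
  terms <- c(vdw = vdw_term, hbond = hb$strength,
             hydrophobic = hydrophobic_term, rotor = rotor_term)
  structure(list(vdw_term = vdw_term, hbond_term = hb$strength,
                 hydrophobic_term = hydrophobic_term, rotor_term = rotor_term,
                 total = sum(weights[names(terms)] * terms), weights = weights,
                 hbond_events = hb$events),
            class = "hx_empirical_score")
}

# Generalized-Born polar solvation ------------------------------------------------

GB_OFFSET <- 0.09
GB_SCALE <- 0.8

#' HCT-style effective Born radii
#'
#' Intrinsic radii are the collision radii minus a 0.09 A offset; pairwise
#' descreening uses the Hawkins-Cramer-Truhlar integral with a uniform
#' scaling factor of 0.8. An isolated atom's effective radius equals its
#' intrinsic radius.
#'
#' @param coords n x 3 coordinates, Angstrom
#' @param radii collision radii, Angstrom
#' @return effective Born radii, Angstrom
#' @export
effective_born_radii <- function(coords, radii) {
  n <- nrow(coords)
  rho <- pmax(radii - GB_OFFSET, 0.4)
  inv <- 1 / rho
  if (n > 1L) {
    d <- as.matrix(stats::dist(coords))
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        r <- d[i, j]
        sr <- GB_SCALE * rho[j]
        if (r + sr <= rho[i]) next
        L <- max(abs(r - sr), rho[i])
        U <- r + sr
        H <- 0.5 * (1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
                    (1 / (2 * r)) * log(L / U) +
                    (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2))
        inv[i] <- inv[i] - H
      }
    }
  }
  1 / pmax(inv, 1e-3)
}

#' Pairwise generalized-Born polar solvation energy
#'
#' `-k/2 (1 - 1/eps_w) sum_ij q_i q_j / f_ij` with
#' `f_ij = sqrt(r^2 + a_i a_j exp(-r^2 / (4 a_i a_j)))`; the i = j terms are
#' the Born self-energies `-k/2 (1 - 1/eps_w) q_i^2 / a_i`.
#'
#' @param coords n x 3 coordinates
#' @param charges partial charges, e
#' @param born_radii effective Born radii, Angstrom
#' @param eps_solvent solvent dielectric
#' @return polar solvation energy, kcal/mol
#' @export
gb_polar_energy <- function(coords, charges, born_radii, eps_solvent = 80) {
  n <- length(charges)
  d2 <- as.matrix(stats::dist(coords))^2
  ab <- outer(born_radii, born_radii)
  f <- sqrt(d2 + ab * exp(-d2 / (4 * ab)))
  -0.5 * COULOMB_K * (1 - 1 / eps_solvent) * sum(outer(charges, charges) / f)
}

# Shrake-Rupley SASA ---------------------------------------------------------------

sphere_points <- function(n) {
  ## deterministic golden-spiral sampling of the unit sphere
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' @param coords n x 3 coordinates, Angstrom
#' @param radii atomic radii, Angstrom
#' @param probe probe radius, Angstrom
#' @param n_points sample points per atom
#' @return per-atom SASA vector, Angstrom^2
#' @export
shrake_rupley <- function(coords, radii, probe = 1.4, n_points = 960L) {
  n <- nrow(coords)
  pts <- sphere_points(n_points)
  rext <- radii + probe
  out <- numeric(n)
  d2 <- as.matrix(stats::dist(coords))^2
  for (i in seq_len(n)) {
    surf <- sweep(pts * rext[i], 2, coords[i, ], "+")
    nbrs <- which(d2[i, ] < (rext[i] + rext)^2 & seq_len(n) != i)
    acc <- rep(TRUE, n_points)
    for (j in nbrs) {
      dj2 <- colSums((t(surf) - coords[j, ])^2)
      acc <- acc & dj2 >= rext[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * rext[i]^2 * mean(acc)
  }
  out
}

# MM-GBSA-style binding energy ------------------------------------------------------

#' Solvation settings
#' @param eps_solvent solvent dielectric
#' @param gamma surface-tension coefficient, kcal/mol/A^2
#' @param beta nonpolar offset, kcal/mol
#' @param probe probe radius, Angstrom
#' @param n_points Shrake-Rupley points per atom
#' @return settings list
#' @export
solvation_settings <- function(eps_solvent = 80, gamma = 0.00542, beta = 0.92,
                               probe = 1.4, n_points = 960L) {
  list(model = "gb_hct", eps_solvent = eps_solvent, gamma = gamma,
       beta = beta, probe = probe, n_points = n_points)
}

#' MM-GBSA-style binding energy of a pose
#'
#' `total = e_vdw + e_elec + g_polar + g_nonpolar` where the MM terms are
#' intermolecular with dielectric 1, `g_polar` is the generalized-Born
#' solvation change on binding (complex minus receptor minus ligand, with
#' effective radii recomputed per species) and
#' `g_nonpolar = gamma * dSASA + beta`. The entropic contribution is never
#' computed (`entropy_included` is always FALSE), so totals are comparable
#' only within a congeneric series.
#'
#' @param pose an `hx_pose` (ideally minimized; a warning is issued when the
#'   intermolecular energy looks unrelaxed)
#' @param receptor parameterized `hx_structure`
#' @param solvent from [solvation_settings()]
#' @return an `hx_mmgbsa`: list(e_vdw, e_elec, g_polar, g_nonpolar, total,
#'   entropy_included = FALSE)
#' @export
mmpbsa_energy <- function(pose, receptor, solvent = solvation_settings()) {
  lc <- pose$coords; rc <- receptor$frames[[1]]
  la <- pose$ligand$atoms; ra <- receptor$atoms
  const_eps <- dielectric_model("constant", value = 1)
  e <- energy_terms(lc, rc, la$charge, ra$charge, la$epsilon, ra$epsilon,
                    la$rmin_half, ra$rmin_half, const_eps)
  if (!all(is.finite(e))) stop("overlapping atoms; minimize the pose first")
  if (e[["e_vdw"]] > 100)
    warning("large positive vdW energy; pose looks unminimized")
  all_c <- rbind(lc, rc)
  all_q <- c(la$charge, ra$charge)
  all_r <- c(la$radius, ra$radius)
  gb <- function(coords, q, radii)
    gb_polar_energy(coords, q, effective_born_radii(coords, radii),
                    solvent$eps_solvent)
  g_polar <- gb(all_c, all_q, all_r) - gb(rc, ra$charge, ra$radius) -
    gb(lc, la$charge, la$radius)
  sasa <- function(coords, radii)
    sum(shrake_rupley(coords, radii, solvent$probe, solvent$n_points))
  dsasa <- sasa(all_c, all_r) - sasa(rc, ra$radius) - sasa(lc, la$radius)
  g_nonpolar <- solvent$gamma * dsasa + solvent$beta
  structure(list(e_vdw = e[["e_vdw"]], e_elec = e[["e_elec"]],
                 g_polar = g_polar, g_nonpolar = g_nonpolar,
                 total = e[["e_vdw"]] + e[["e_elec"]] + g_polar + g_nonpolar,
                 dsasa = dsasa, entropy_included = FALSE),
            class = "hx_mmgbsa")
}

#' @export
print.hx_mmgbsa <- function(x, ...) {
  cat(sprintf(paste0("hx_mmgbsa (kcal/mol): e_vdw %.2f, e_elec %.2f, ",
                     "g_polar %.2f, g_nonpolar %.2f, total %.2f ",
                     "(entropy omitted)\n"),
              x$e_vdw, x$e_elec, x$g_polar, x$g_nonpolar, x$total))
  invisible(x)
}

#' Per-group intermolecular electrostatics of a pose
#'
#' Coulomb sum (dielectric 1, as in the MM term) of each named ligand atom
#' group against all receptor atoms. When the groups partition all ligand
#' atoms the group energies sum exactly to the MM electrostatic term.
#'
#' @param pose an `hx_pose`
#' @param receptor parameterized `hx_structure`
#' @param groups named list of ligand atom index vectors; defaults to the
#'   ligand's own `groups` plus a `remainder` group for uncovered atoms
#' @return data.frame(group, e_elec_group) in kcal/mol
#' @export
group_electrostatics <- function(pose, receptor, groups = NULL) {
  la <- pose$ligand$atoms
  if (is.null(groups)) {
    groups <- pose$ligand$groups
    covered <- unlist(groups)
    rest <- setdiff(seq_len(nrow(la)), covered)
    if (length(rest)) groups$remainder <- rest
  }
  allidx <- unlist(groups)
  if (anyDuplicated(allidx))
    stop("atom assigned to more than one group")
  rc <- receptor$frames[[1]]
  out <- data.frame(group = names(groups), e_elec_group = NA_real_)
  for (k in seq_along(groups)) {
    idx <- groups[[k]]
    lc <- pose$coords[idx, , drop = FALSE]
    d <- sqrt(pmax(outer(rowSums(lc^2), rowSums(rc^2), "+") - 2 * lc %*% t(rc), 0))
    out$e_elec_group[k] <- sum(COULOMB_K * outer(la$charge[idx],
                                                 receptor$atoms$charge) / d)
  }
  out
}
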