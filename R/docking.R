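# Pharmacophore-constrained placement, steric filtering, screening -------------
#
# Conformers are placed rigidly by the transform of an accepted pharmacophore
# match. Steric filtering scales all collision radii by `radius_scale`
# (default 0.6, i.e. a 40% reduction that tolerates minor clashes as a crude
# proxy for flexibility); a heavy-atom pair clashes when its distance falls
# below radius_scale * (r_i + r_j). Ranking is RMSD-first.

#' Place a conformer with the transform of an accepted match
#' @param lig an `hx_ligand`
#' @param conformer conformer index
#' @param match an accepted `hx_match`
#' @return an `hx_pose`: list(ligand, conformer, rotation, translation,
#'   coords, pharm_rmsd, clash_count)
#' @export
place_pose <- function(lig, conformer, match) {
  if (!isTRUE(match$accepted)) stop("cannot place an unaccepted match")
  coords <- apply_transform(lig$conformers[[conformer]],
                            match$rotation, match$translation)
  structure(list(ligand = lig, conformer = conformer,
                 rotation = match$rotation, translation = match$translation,
                 coords = coords, pharm_rmsd = match$rmsd,
                 clash_count = NA_integer_),
            class = "hx_pose")
}

#' @export
print.hx_pose <- function(x, ...) {
  cat("hx_pose: ", x$ligand$name, " conformer ", x$conformer,
      ", pharm RMSD ", format(x$pharm_rmsd, digits = 4), " A\n", sep = "")
  invisible(x)
}

#' Reduced-radius steric clash check
#'
#' Hydrogens are ignored on both sides. A ligand/receptor heavy-atom pair
#' clashes when d < radius_scale * (r_i + r_j).
#'
#' @param pose an `hx_pose` (parameterized ligand)
#' @param receptor parameterized `hx_structure` (frame 1)
#' @param radius_scale radius scale factor in (0, 1]; 0.6 reproduces a 40%
#'   radius reduction
#' @return list(clash_count, pairs = data.frame(ligand_atom, receptor_atom,
#'   distance, limit))
#' @export
clash_check <- function(pose, receptor, radius_scale = 0.6) {
  if (radius_scale <= 0 || radius_scale > 1)
    stop("radius_scale must be in (0, 1]")
  lh <- which(!pose$ligand$atoms$is_h)
  rh <- which(!receptor$atoms$is_h)
  lc <- pose$coords[lh, , drop = FALSE]
  rc <- receptor$frames[[1]][rh, , drop = FALSE]
  d <- sqrt(pmax(outer(rowSums(lc^2), rowSums(rc^2), "+") - 2 * lc %*% t(rc), 0))
  lim <- radius_scale * outer(pose$ligand$atoms$radius[lh],
                              receptor$atoms$radius[rh], "+")
  hit <- which(d < lim, arr.ind = TRUE)
  pairs <- data.frame(ligand_atom = lh[hit[, 1]], receptor_atom = rh[hit[, 2]],
                      distance = d[hit], limit = lim[hit])
  list(clash_count = nrow(pairs), pairs = pairs)
}

#' Screen a multi-conformer library against a pharmacophore and receptor
#'
#' For every conformer of every ligand: type features, match against the
#' model, place accepted matches, apply the reduced-radius clash filter and
#' score the survivors with [empirical_score()]. The best surviving
#' conformer (lowest pharmacophore RMSD) is kept per ligand. The ranking is
#' sorted by RMSD ascending (ties: empirical score descending, then ligand
#' name), which makes the output independent of library input order.
#'
#' @param library list of parameterized `hx_ligand`
#' @param model an `hx_pharmacophore`
#' @param receptor parameterized `hx_structure`
#' @param gate RMSD acceptance gate, Angstrom
#' @param radius_scale clash radius scale
#' @param max_clashes maximum residual clashes a pose may keep
#' @param weights empirical score weights (see [empirical_score()])
#' @return an `hx_screen`: list(entries = data.frame, poses = named list of
#'   `hx_pose`, rejections = data.frame(ligand, conformer, reason), criteria)
#' @export
screen_library <- function(library, model, receptor, gate = 1.0,
                           radius_scale = 0.6, max_clashes = 0L,
                           weights = empirical_weights()) {
  if (!length(library)) stop("ligand library is empty")
  entries <- list(); poses <- list(); rej <- list()
  note <- function(lig, cf, reason)
    rej[[length(rej) + 1L]] <<- data.frame(ligand = lig, conformer = cf,
                                           reason = reason)
  for (lig in library) {
    best <- NULL
    for (cf in seq_along(lig$conformers)) {
      fts <- type_ligand_features(lig, cf)
      if (!nrow(fts)) { note(lig$name, cf, "no_features"); next }
      m <- match_pharmacophore(fts, model, gate = gate)
      if (!is.finite(m$rmsd)) { note(lig$name, cf, "no_kind_compatible_assignment"); next }
      if (!m$accepted) { note(lig$name, cf, "rmsd_gate"); next }
      pose <- place_pose(lig, cf, m)
      cl <- clash_check(pose, receptor, radius_scale)
      pose$clash_count <- cl$clash_count
      if (cl$clash_count > max_clashes) { note(lig$name, cf, "steric_clash"); next }
      if (is.null(best) || pose$pharm_rmsd < best$pharm_rmsd) best <- pose
    }
    if (!is.null(best)) {
      sc <- empirical_score(best, receptor, weights)
      entries[[length(entries) + 1L]] <- data.frame(
        ligand = lig$name, conformer = best$conformer,
        pharm_rmsd = best$pharm_rmsd, clash_count = best$clash_count,
        empirical_score = sc$total)
      poses[[lig$name]] <- best
    }
  }
  entries <- if (length(entries)) do.call(rbind, entries)
             else data.frame(ligand = character(0), conformer = integer(0),
                             pharm_rmsd = numeric(0), clash_count = integer(0),
                             empirical_score = numeric(0))
  ord <- order(entries$pharm_rmsd, -entries$empirical_score, entries$ligand)
  entries <- entries[ord, ]
  rownames(entries) <- NULL
  rejections <- if (length(rej)) do.call(rbind, rej)
                else data.frame(ligand = character(0), conformer = integer(0),
                                reason = character(0))
  structure(list(entries = entries, poses = poses[entries$ligand],
                 rejections = rejections,
                 criteria = list(gate = gate, radius_scale = radius_scale,
                                 max_clashes = max_clashes)),
            class = "hx_screen")
}

#' @export
print.hx_screen <- function(x, ...) {
  cat("hx_screen:", nrow(x$entries), "ligands accepted,",
      nrow(x$rejections), "conformer rejections\n")
  print(utils::head(x$entries, 8))
  invisible(x)
}

#' Write a screen ranking as TSV (fixed formatting, byte-reproducible)
#' @param screen an `hx_screen`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ranking <- function(screen, path) {
  e <- screen$entries
  df <- data.frame(ligand = e$ligand, conformer = e$conformer,
                   pharm_rmsd = formatC(e$pharm_rmsd, format = "f", digits = 6),
                   clash_count = e$clash_count,
                   empirical_score = formatC(e$empirical_score, format = "f",
                                             digits = 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Rigid-body minimization --------------------------------------------------------

rotation_about <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

intermolecular_energy <- function(coords, lig_atoms, receptor,
                                  dielectric = dielectric_model("constant", value = 1)) {
  fr <- receptor$frames[[1]]
  e <- energy_terms(coords, fr, lig_atoms$charge, receptor$atoms$charge,
                    lig_atoms$epsilon, receptor$atoms$epsilon,
                    lig_atoms$rmin_half, receptor$atoms$rmin_half, dielectric)
  sum(e)
}

#' Rigid-body greedy minimization of a pose
#'
#' Greedy descent over the six rigid degrees of freedom (translations of
#' `step_size` Angstrom, rotations of `step_deg` degrees about the ligand
#' centroid) on the intermolecular vdW + electrostatic energy (constant
#' dielectric 1). The ligand's internal geometry is untouched; the returned
#' energy never exceeds the starting energy.
#'
#' @param pose an `hx_pose`
#' @param receptor parameterized `hx_structure`
#' @param steps maximum accepted moves
#' @param step_size translation step, Angstrom
#' @param step_deg rotation step, degrees
#' @return the minimized `hx_pose`, with attribute `"energy"`
#' @export
local_minimize <- function(pose, receptor, steps = 200L, step_size = 0.05,
                           step_deg = 0.5) {
  coords <- pose$coords
  la <- pose$ligand$atoms
  e0 <- intermolecular_energy(coords, la, receptor)
  if (!is.finite(e0))
    stop("non-finite starting energy (atomic overlap); run clash filtering first")
  axes <- diag(3)
  for (s in seq_len(steps)) {
    cen <- colMeans(coords)
    cands <- list()
    for (k in 1:3) for (sgn in c(-1, 1)) {
      cands[[length(cands) + 1L]] <- sweep(coords, 2, sgn * step_size * axes[k, ], "+")
      R <- rotation_about(axes[k, ], sgn * step_deg)
      cands[[length(cands) + 1L]] <- sweep(sweep(coords, 2, cen) %*% t(R), 2, cen, "+")
    }
    es <- vapply(cands, intermolecular_energy, 0, lig_atoms = la,
                 receptor = receptor)
    if (min(es) >= e0 - 1e-12) break
    k <- which.min(es)
    coords <- cands[[k]]
    e0 <- es[k]
  }
  pose$coords <- coords
  attr(pose, "energy") <- e0
  pose
}
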