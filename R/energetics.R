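# Per-residue inter-chain interaction energetics ------------------------------
#
# Pairwise molecular-mechanics energies between residues on opposite chains,
# averaged over a coordinate ensemble, with no distance cutoff. Electrostatics
# use the Coulomb constant 332.0637 kcal*A/(mol*e^2); the screening model is
# either a distance-dependent dielectric eps(r) = factor*r (default factor 4)
# or a constant dielectric.

COULOMB_K <- 332.0637

#' Dielectric model configuration
#'
#' @param type `"distance"` for eps(r) = factor * r, or `"constant"`
#' @param factor slope of the distance-dependent dielectric (dimensionless)
#' @param value constant dielectric value (used when `type = "constant"`)
#' @return a dielectric model list
#' @export
dielectric_model <- function(type = c("distance", "constant"), factor = 4,
                             value = 1) {
  type <- match.arg(type)
  if (type == "distance" && factor <= 0) stop("dielectric factor must be > 0")
  if (type == "constant" && value <= 0) stop("dielectric value must be > 0")
  list(type = type, factor = factor, value = value)
}

dielectric_eps <- function(model, r) {
  if (model$type == "distance") model$factor * r else model$value
}

## core pairwise terms between two atom sets for one coordinate frame
energy_terms <- function(ca, cb, qa, qb, epsa, epsb, rha, rhb, dielectric) {
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 1e-6)) {
    w <- which(d < 1e-6, arr.ind = TRUE)[1, ]
    stop("overlapping atoms (r < 1e-6 A) between atom ", w[1],
         " of set A and atom ", w[2], " of set B")
  }
  rmin <- outer(rha, rhb, "+")
  epsij <- sqrt(outer(epsa, epsb))
  sr6 <- (rmin / d)^6
  e_vdw <- sum(epsij * (sr6^2 - 2 * sr6))
  e_elec <- sum(COULOMB_K * outer(qa, qb) / (dielectric_eps(dielectric, d) * d))
  c(e_vdw = e_vdw, e_elec = e_elec)
}

#' Residue-residue interaction energy in one frame
#'
#' Lennard-Jones (Amber convention, epsilon_ij = sqrt(epsilon_i epsilon_j),
#' rmin_ij = rmin_i/2 + rmin_j/2) plus Coulomb energy over all atom pairs of
#' the two residues; no distance cutoff is applied.
#'
#' @param x parameterized `hx_structure`
#' @param res_a,res_b residue references (`"A:203"` or `list(chain, resno)`)
#'   on different chains
#' @param frame frame index (1-based; frame 1 is the reference)
#' @param dielectric a [dielectric_model()]
#' @return named vector `c(e_vdw, e_elec)` in kcal/mol
#' @export
pair_energy <- function(x, res_a, res_b, frame = 1L,
                        dielectric = dielectric_model()) {
  ia <- resolve_residue(x, res_a)
  ib <- resolve_residue(x, res_b)
  if (x$atoms$chain[ia[1]] == x$atoms$chain[ib[1]])
    stop("pair_energy requires residues on different chains")
  fr <- x$frames[[frame]]
  energy_terms(fr[ia, , drop = FALSE], fr[ib, , drop = FALSE],
               x$atoms$charge[ia], x$atoms$charge[ib],
               x$atoms$epsilon[ia], x$atoms$epsilon[ib],
               x$atoms$rmin_half[ia], x$atoms$rmin_half[ib], dielectric)
}

#' Ensemble-averaged residue-pair interaction matrix across an interface
#'
#' Every residue of `chain_a` against every residue of `chain_b`, averaged
#' over the selected frames. Entries carry the vdW and electrostatic means,
#' their sum, and the standard deviation of the per-frame totals. Row/column
#' order is deterministic: ascending residue number within each chain.
#'
#' @param x parameterized `hx_structure`
#' @param chain_a,chain_b distinct chain identifiers
#' @param frames frame indices to average over (default: all)
#' @param dielectric a [dielectric_model()]
#' @return an `hx_interface_matrix`: list(res_a, res_b, e_vdw, e_elec,
#'   e_total, sd_total (matrices), per_residue_totals)
#' @export
interface_matrix <- function(x, chain_a, chain_b, frames = seq_along(x$frames),
                             dielectric = dielectric_model()) {
  if (identical(chain_a, chain_b)) stop("chains must be distinct")
  if (!length(frames)) stop("empty frame selection")
  res <- residue_table(x)
  ra <- res[res$chain == chain_a, ]
  rb <- res[res$chain == chain_b, ]
  if (!nrow(ra) || !nrow(rb)) stop("chain not found or empty")
  na <- nrow(ra); nb <- nrow(rb)
  nf <- length(frames)
  per_v <- array(0, c(nf, na, nb)); per_e <- array(0, c(nf, na, nb))
  for (k in seq_len(nf)) {
    fr <- x$frames[[frames[k]]]
    for (i in seq_len(na)) for (j in seq_len(nb)) {
      ia <- ra$idx[[i]]; ib <- rb$idx[[j]]
      e <- energy_terms(fr[ia, , drop = FALSE], fr[ib, , drop = FALSE],
                        x$atoms$charge[ia], x$atoms$charge[ib],
                        x$atoms$epsilon[ia], x$atoms$epsilon[ib],
                        x$atoms$rmin_half[ia], x$atoms$rmin_half[ib],
                        dielectric)
      per_v[k, i, j] <- e[["e_vdw"]]
      per_e[k, i, j] <- e[["e_elec"]]
    }
  }
  per_t <- per_v + per_e
  e_vdw <- apply(per_v, c(2, 3), mean)
  e_elec <- apply(per_e, c(2, 3), mean)
  e_total <- e_vdw + e_elec
  ## population SD of the per-frame totals (0 for a degenerate ensemble)
  sd_total <- apply(per_t, c(2, 3), function(v) sqrt(mean((v - mean(v))^2)))
  dimnames(e_vdw) <- dimnames(e_elec) <- dimnames(e_total) <-
    dimnames(sd_total) <- list(rownames(ra), rownames(rb))
  per_res <- c(rowSums(e_total), colSums(e_total))
  names(per_res) <- c(rownames(ra), rownames(rb))
  structure(list(res_a = ra[, c("chain", "resno", "resname")],
                 res_b = rb[, c("chain", "resno", "resname")],
                 e_vdw = e_vdw, e_elec = e_elec, e_total = e_total,
                 sd_total = sd_total, per_residue_totals = per_res,
                 n_frames = nf),
            class = "hx_interface_matrix")
}

#' Write an interface matrix as TSV (rows chain-A residues, kcal/mol)
#' @param m an `hx_interface_matrix`
#' @param path output file
#' @param which matrix component to write
#' @return `path`, invisibly
#' @export
write_interface_matrix <- function(m, path, which = "e_total") {
  mat <- m[[which]]
  df <- data.frame(residue = rownames(mat),
                   formatC(mat, format = "f", digits = 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Hydrogen-bond detection ------------------------------------------------------

structure_bond_guess <- function(x, frame = 1L, hmax = 1.25) {
  ## hydrogens are attached to the nearest heavy N/O/C in the same residue
  fr <- x$frames[[frame]]
  hs <- which(x$atoms$is_h)
  heavy <- which(!x$atoms$is_h)
  out <- data.frame(h = integer(0), heavy = integer(0))
  for (h in hs) {
    same <- heavy[x$atoms$chain[heavy] == x$atoms$chain[h] &
                  x$atoms$resno[heavy] == x$atoms$resno[h]]
    if (!length(same)) next
    d <- sqrt(colSums((t(fr[same, , drop = FALSE]) - fr[h, ])^2))
    k <- which.min(d)
    if (d[k] <= hmax) out <- rbind(out, data.frame(h = h, heavy = same[k]))
  }
  out
}

#' Detect inter-chain hydrogen bonds over an ensemble
#'
#' Donors are N/O atoms with a covalently attached hydrogen (attachment is
#' inferred geometrically within each residue, cutoff 1.25 A); acceptors are
#' oxygens, plus nitrogens carrying no hydrogen. An event is recorded in a
#' frame when the donor-heavy to acceptor distance is at most `dist_max` and
#' the donor-H-acceptor angle at the hydrogen is at least `angle_min`.
#' Occupancy of a donor/acceptor pair is the fraction of selected frames
#' with an event.
#'
#' @param x `hx_structure` with explicit hydrogens
#' @param frames frame selection (default all)
#' @param dist_max donor-heavy to acceptor distance ceiling, Angstrom
#' @param angle_min donor-H-acceptor angle floor, degrees
#' @param inter_chain_only keep only donor/acceptor pairs on different chains
#' @return list(events = data.frame(frame, donor_heavy, hydrogen, acceptor,
#'   distance, angle), occupancy = data.frame(donor_heavy, acceptor,
#'   donor_res, acceptor_res, occupancy))
#' @export
detect_hbonds <- function(x, frames = seq_along(x$frames), dist_max = 3.5,
                          angle_min = 120, inter_chain_only = TRUE) {
  if (!any(x$atoms$is_h))
    stop("structure has no hydrogens; hydrogen-bond detection needs explicit-H input")
  att <- structure_bond_guess(x)
  don <- att[x$atoms$element[att$heavy] %in% c("N", "O"), ]
  has_h <- unique(att$heavy)
  acc <- which(x$atoms$element == "O" |
               (x$atoms$element == "N" & !(seq_len(nrow(x$atoms)) %in% has_h)))
  ev <- list()
  for (f in frames) {
    fr <- x$frames[[f]]
    for (r in seq_len(nrow(don))) {
      dh <- don$heavy[r]; hh <- don$h[r]
      for (a in acc) {
        if (a == dh) next
        if (x$atoms$chain[a] == x$atoms$chain[dh] &&
            x$atoms$resno[a] == x$atoms$resno[dh]) next
        if (inter_chain_only && x$atoms$chain[a] == x$atoms$chain[dh]) next
        dist <- sqrt(sum((fr[dh, ] - fr[a, ])^2))
        if (dist > dist_max) next
        v1 <- fr[dh, ] - fr[hh, ]; v2 <- fr[a, ] - fr[hh, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang < angle_min) next
        ev[[length(ev) + 1L]] <- data.frame(
          frame = f, donor_heavy = dh, hydrogen = hh, acceptor = a,
          distance = dist, angle = ang)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(frame = integer(0), donor_heavy = integer(0),
                            hydrogen = integer(0), acceptor = integer(0),
                            distance = numeric(0), angle = numeric(0))
  key <- paste(events$donor_heavy, events$acceptor)
  occ <- if (nrow(events)) {
    tab <- tapply(events$frame, key, function(v) length(unique(v)))
    dh <- as.integer(vapply(strsplit(names(tab), " "), `[`, "", 1))
    ac <- as.integer(vapply(strsplit(names(tab), " "), `[`, "", 2))
    data.frame(donor_heavy = dh, acceptor = ac,
               donor_res = paste0(x$atoms$chain[dh], ":", x$atoms$resno[dh]),
               acceptor_res = paste0(x$atoms$chain[ac], ":", x$atoms$resno[ac]),
               occupancy = as.numeric(tab) / length(frames))
  } else data.frame(donor_heavy = integer(0), acceptor = integer(0),
                    donor_res = character(0), acceptor_res = character(0),
                    occupancy = numeric(0))
  occ <- occ[order(-occ$occupancy, occ$donor_heavy, occ$acceptor), ]
  rownames(occ) <- NULL
  list(events = events, occupancy = occ)
}

# Hot-spot ranking --------------------------------------------------------------

#' Rank interface residues as hot-spot candidates
#'
#' Residues of both chains are sorted by their summed interaction energy
#' against the full opposite chain (most negative first; ties break by
#' hydrogen-bond occupancy descending, then residue number ascending). A
#' residue is flagged when it passes every criterion: energy at most
#' `energy_max`, best hydrogen-bond occupancy at least `occupancy_min`, and,
#' when a conservation map is given, conservation at least
#' `conservation_min`.
#'
#' @param matrix an `hx_interface_matrix`
#' @param hbonds result of [detect_hbonds()] (or NULL)
#' @param conservation optional named vector, `"A:203"` -> fraction in `[0,1]`
#' @param energy_max flag threshold on the per-residue total, kcal/mol
#' @param occupancy_min flag threshold on hydrogen-bond occupancy
#' @param conservation_min flag threshold on conservation
#' @return an `hx_hotspot_report`: list(ranked = data.frame, criteria)
#' @export
rank_hotspots <- function(matrix, hbonds = NULL, conservation = NULL,
                          energy_max = -2, occupancy_min = 0.5,
                          conservation_min = 0.5) {
  tot <- matrix$per_residue_totals
  res <- rbind(matrix$res_a, matrix$res_b)
  key <- paste0(res$chain, ":", res$resno)
  occ <- setNames(rep(0, length(tot)), names(tot))
  if (!is.null(hbonds) && nrow(hbonds$occupancy)) {
    for (r in seq_len(nrow(hbonds$occupancy))) {
      o <- hbonds$occupancy[r, ]
      for (side in c(o$donor_res, o$acceptor_res))
        if (side %in% names(occ)) occ[side] <- max(occ[side], o$occupancy)
    }
  }
  cons <- if (is.null(conservation)) rep(NA_real_, length(tot))
          else unname(conservation[names(tot)])
  df <- data.frame(residue = names(tot), chain = res$chain[match(names(tot), key)],
                   resno = res$resno[match(names(tot), key)],
                   resname = res$resname[match(names(tot), key)],
                   energy = unname(tot), occupancy = unname(occ),
                   conservation = cons, stringsAsFactors = FALSE)
  df <- df[order(df$energy, -df$occupancy, df$resno), ]
  df$flagged <- df$energy <= energy_max & df$occupancy >= occupancy_min &
    (if (is.null(conservation)) TRUE else !is.na(df$conservation) &
       df$conservation >= conservation_min)
  df$conservation_evaluated <- !is.null(conservation)
  rownames(df) <- NULL
  structure(list(ranked = df,
                 criteria = list(energy_max = energy_max,
                                 occupancy_min = occupancy_min,
                                 conservation_min = conservation_min,
                                 conservation_evaluated = !is.null(conservation))),
            class = "hx_hotspot_report")
}

#' @export
print.hx_hotspot_report <- function(x, ...) {
  cat("hx_hotspot_report:", sum(x$ranked$flagged), "flagged of",
      nrow(x$ranked), "residues\n")
  print(utils::head(x$ranked, 8))
  invisible(x)
}
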