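# Pharmacophore features, derivation and matching ------------------------------
#
# Features are typed 3-D points: HD (hydrogen-bond donor), HA (acceptor),
# HY (hydrophobic). A pharmacophore is an ordered feature set; matching a
# ligand against it enumerates every kind-compatible injective assignment of
# model features to ligand features, superposes the matched ligand features
# rigidly (proper rotations only) and keeps the assignment of minimal RMSD.

FEATURE_KINDS <- c("HD", "HA", "HY")

#' Construct a feature table
#' @param kind character vector from HD/HA/HY
#' @param xyz n x 3 matrix of positions, Angstrom
#' @param tolerance per-feature tolerance radii, Angstrom (reporting only;
#'   the screening gate is a global RMSD)
#' @param source provenance strings
#' @return data.frame(kind, x, y, z, tolerance, source)
#' @export
features <- function(kind, xyz, tolerance = 1.5, source = "") {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(all(kind %in% FEATURE_KINDS), all(tolerance > 0))
  data.frame(kind = kind, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             tolerance = tolerance, source = source, stringsAsFactors = FALSE)
}

#' Construct a pharmacophore model
#' @param feats a feature table from [features()] with at least 3 features
#' @param name model name
#' @return an `hx_pharmacophore`
#' @export
pharmacophore <- function(feats, name = "model") {
  if (nrow(feats) < 3L)
    stop("a pharmacophore needs at least 3 features (rigid superposition ",
         "requires 3 non-collinear points); got ", nrow(feats))
  structure(list(features = feats, name = name), class = "hx_pharmacophore")
}

#' @export
print.hx_pharmacophore <- function(x, ...) {
  cat("hx_pharmacophore '", x$name, "': ",
      paste(x$features$kind, collapse = " "), "\n", sep = "")
  invisible(x)
}

feature_xyz <- function(feats) as.matrix(feats[, c("x", "y", "z")])

#' Write / read a pharmacophore as structured YAML
#' @param model an `hx_pharmacophore`
#' @param path file path
#' @return `path` (write) or `hx_pharmacophore` (read)
#' @export
write_pharmacophore <- function(model, path) {
  obj <- list(name = model$name, features = lapply(seq_len(nrow(model$features)),
    function(i) {
      f <- model$features[i, ]
      list(kind = f$kind, xyz = c(f$x, f$y, f$z), tolerance = f$tolerance,
           source = f$source)
    }))
  yaml::write_yaml(obj, path, precision = 12L)
  invisible(path)
}

#' @rdname write_pharmacophore
#' @export
read_pharmacophore <- function(path) {
  obj <- yaml::read_yaml(path)
  kinds <- vapply(obj$features, `[[`, "", "kind")
  xyz <- t(vapply(obj$features, function(f) as.numeric(f$xyz), numeric(3)))
  tol <- vapply(obj$features, function(f) as.numeric(f$tolerance), 0)
  src <- vapply(obj$features, function(f) as.character(f$source), "")
  pharmacophore(features(kinds, xyz, tol, src), name = obj$name)
}

# Rigid superposition -----------------------------------------------------------

#' Least-squares rigid superposition (proper rotation only)
#'
#' Kabsch algorithm: returns the rotation and translation that minimize the
#' RMSD of `src` onto `dst`. Reflections are excluded so chirality is
#' preserved.
#'
#' @param src,dst n x 3 matrices of paired points
#' @return list(rotation 3x3, translation length-3, rmsd)
#' @export
superpose <- function(src, dst) {
  stopifnot(nrow(src) == nrow(dst), ncol(src) == 3, ncol(dst) == 3)
  cs <- colMeans(src); cd <- colMeans(dst)
  P <- sweep(src, 2, cs); Q <- sweep(dst, 2, cd)
  H <- t(P) %*% Q
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Q)^2)))
  list(rotation = R, translation = as.numeric(cd - R %*% cs), rmsd = rmsd)
}

apply_transform <- function(coords, rotation, translation) {
  sweep(coords %*% t(rotation), 2, translation, "+")
}

# Ligand feature typing ----------------------------------------------------------

find_rings <- function(lig, max_size = 7L) {
  ## smallest ring through each bond, deduplicated by atom set
  nb <- heavy_neighbors(lig)
  rings <- list()
  seen <- character(0)
  for (r in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[r]; j <- lig$bonds$j[r]
    if (lig$atoms$is_h[i] || lig$atoms$is_h[j]) next
    ## BFS from j to i avoiding the direct bond, tracking parents
    parent <- rep(NA_integer_, nrow(lig$atoms))
    depth <- rep(NA_integer_, nrow(lig$atoms))
    depth[j] <- 0L
    queue <- j
    found <- FALSE
    while (length(queue) && !found) {
      cur <- queue[1]; queue <- queue[-1]
      if (depth[cur] >= max_size - 1L) next
      for (nx in nb[[cur]]) {
        if (lig$atoms$is_h[nx]) next
        if (cur == j && nx == i) next
        if (!is.na(depth[nx])) next
        depth[nx] <- depth[cur] + 1L
        parent[nx] <- cur
        if (nx == i) { found <- TRUE; break }
        queue <- c(queue, nx)
      }
    }
    if (found) {
      path <- i
      while (path[length(path)] != j) path <- c(path, parent[path[length(path)]])
      ring <- sort(path)
      key <- paste(ring, collapse = ",")
      if (!(key %in% seen) && length(ring) <= max_size) {
        seen <- c(seen, key)
        rings[[length(rings) + 1L]] <- path
      }
    }
  }
  rings
}

#' Type the pharmacophoric features of a ligand conformer
#'
#' Rule table: HD at every N/O bearing at least one hydrogen (feature at the
#' heavy atom); HA at carbonyl/nitro-type oxygens (no hydrogen, one heavy
#' neighbor), hydroxyl oxygens, and pyridine-type ring nitrogens without
#' hydrogens; HY at the centroid of each carbocycle and at halogen-bearing
#' ring carbons. Feature kinds and counts are conformer-independent; only
#' positions move with the conformer.
#'
#' @param lig an `hx_ligand` with explicit hydrogens and bonds
#' @param conformer conformer index (1-based)
#' @param tolerance default per-feature tolerance, Angstrom
#' @return feature table (possibly empty)
#' @export
type_ligand_features <- function(lig, conformer = 1L, tolerance = 1.5) {
  if (!nrow(lig$bonds)) stop("ligand has no bonds; cannot type features")
  cf <- lig$conformers[[conformer]]
  nb <- heavy_neighbors(lig)
  el <- lig$atoms$element
  has_h <- vapply(nb, function(v) any(el[v] == "H"), TRUE)
  n_heavy <- vapply(nb, function(v) sum(el[v] != "H"), 0L)
  rings <- find_rings(lig)
  in_ring <- rep(FALSE, nrow(lig$atoms))
  for (rg in rings) in_ring[rg] <- TRUE

  kind <- character(0); pos <- NULL; src <- character(0)
  add <- function(k, p, s) {
    kind <<- c(kind, k)
    pos <<- rbind(pos, p)
    src <<- c(src, s)
  }
  for (a in seq_len(nrow(lig$atoms))) {
    if (el[a] %in% c("N", "O") && has_h[a])
      add("HD", cf[a, ], paste0("atom ", a, " (", el[a], "-H donor)"))
    if (el[a] == "O") {
      if (has_h[a])
        add("HA", cf[a, ], paste0("atom ", a, " (hydroxyl O acceptor)"))
      else if (n_heavy[a] == 1L)
        add("HA", cf[a, ], paste0("atom ", a, " (carbonyl/nitro O acceptor)"))
    }
    if (el[a] == "N" && !has_h[a] && in_ring[a] && n_heavy[a] == 2L)
      add("HA", cf[a, ], paste0("atom ", a, " (pyridine-type N acceptor)"))
  }
  for (rg in rings) {
    if (all(el[rg] == "C")) {
      add("HY", colMeans(cf[rg, , drop = FALSE]),
          paste0("ring centroid (", paste(sort(rg), collapse = ","), ")"))
      for (a in rg) {
        hal <- nb[[a]][el[nb[[a]]] %in% c("F", "Cl", "Br", "I")]
        if (length(hal))
          add("HY", cf[a, ], paste0("atom ", a, " (halogen-substituted ring C)"))
      }
    }
  }
  if (!length(kind))
    return(features(character(0), matrix(numeric(0), ncol = 3),
                    numeric(0), character(0)))
  features(kind, pos, tolerance, src)
}

# Interface-derived pharmacophore -------------------------------------------------

HYDROPHOBIC_RES <- c("LEU", "ILE", "VAL", "ALA", "PHE", "MET", "TRP")

helix_axis <- function(coords) {
  c0 <- colMeans(coords)
  pc <- prcomp(coords, center = TRUE)
  list(origin = c0, dir = pc$rotation[, 1])
}

#' Derive a complementary ligand-side pharmacophore from hot-spot residues
#'
#' The reference frame (frame 1) is used. For each protein donor group
#' (N/O with hydrogens) one HA feature is projected `hbond_dist` Angstrom
#' from the donor heavy atom along the direction of its most exposed
#' hydrogen; for each protein acceptor (O without hydrogen) one HD feature
#' is projected `hbond_dist` along the extended antecedent-to-acceptor
#' direction; for each hydrophobic side chain one HY feature is placed
#' `hy_dist` from the side-chain carbon centroid along the outward normal
#' from the chain's helix axis. Feature order is deterministic (residue
#' number, then atom name).
#'
#' @param x parameterized `hx_structure`
#' @param hotspots character vector of residue references, e.g.
#'   `c("A:203", "A:204")`, all on one chain
#' @param hbond_dist donor/acceptor projection distance, Angstrom
#' @param hy_dist hydrophobic projection distance, Angstrom
#' @param tolerance per-feature tolerance, Angstrom
#' @param name model name
#' @return an `hx_pharmacophore`
#' @export
derive_interface_pharmacophore <- function(x, hotspots, hbond_dist = 2.9,
                                           hy_dist = 4.0, tolerance = 1.5,
                                           name = "interface") {
  if (!length(hotspots)) stop("hotspot residue list is empty")
  fr <- x$frames[[1]]
  idx_all <- lapply(hotspots, function(r) resolve_residue(x, r))
  chain <- unique(x$atoms$chain[unlist(idx_all)])
  if (length(chain) != 1L) stop("hotspot residues must belong to one chain")
  chain_idx <- which(x$atoms$chain == chain)
  axis <- helix_axis(fr[chain_idx[x$atoms$name[chain_idx] == "CA"], , drop = FALSE])
  att <- structure_bond_guess(x)

  kind <- character(0); pos <- NULL; src <- character(0)
  ord <- order(vapply(idx_all, function(i) x$atoms$resno[i[1]], 0L))
  for (ii in ord) {
    idx <- idx_all[[ii]]
    rn <- x$atoms$resno[idx[1]]; rnm <- x$atoms$resname[idx[1]]
    label <- paste0(chain, ":", rn, " ", rnm)
    heavies <- idx[!x$atoms$is_h[idx]]
    ## donors: one HA per donor heavy atom, along its most exposed hydrogen
    for (dh in sort(heavies[x$atoms$element[heavies] %in% c("N", "O")])) {
      hs <- att$h[att$heavy == dh]
      if (!length(hs)) next
      cand <- t(vapply(hs, function(h) {
        u <- fr[h, ] - fr[dh, ]; u <- u / sqrt(sum(u^2))
        fr[dh, ] + hbond_dist * u
      }, numeric(3)))
      ## exposure: distance to the nearest protein atom of the chain
      expo <- apply(cand, 1, function(p)
        min(sqrt(colSums((t(fr[chain_idx, , drop = FALSE]) - p)^2))))
      best <- which.max(expo)
      kind <- c(kind, "HA"); pos <- rbind(pos, cand[best, ])
      src <- c(src, paste0(label, " donor ", x$atoms$name[dh]))
    }
    ## acceptors: one HD per acceptor oxygen
    for (ac in sort(heavies[x$atoms$element[heavies] == "O"])) {
      if (ac %in% att$heavy) next   # hydroxyl-type: already a donor above
      others <- setdiff(heavies, ac)
      d <- sqrt(colSums((t(fr[others, , drop = FALSE]) - fr[ac, ])^2))
      ante <- others[which.min(d)]
      u <- fr[ac, ] - fr[ante, ]; u <- u / sqrt(sum(u^2))
      kind <- c(kind, "HD"); pos <- rbind(pos, fr[ac, ] + hbond_dist * u)
      src <- c(src, paste0(label, " acceptor ", x$atoms$name[ac]))
    }
    ## hydrophobic side chain: one HY at the outward-projected carbon centroid
    if (rnm %in% HYDROPHOBIC_RES) {
      sc <- heavies[x$atoms$element[heavies] == "C" & x$atoms$name[heavies] != "CA"]
      if (length(sc)) {
        cen <- colMeans(fr[sc, , drop = FALSE])
        along <- sum((cen - axis$origin) * axis$dir)
        foot <- axis$origin + along * axis$dir
        u <- cen - foot; u <- u / sqrt(sum(u^2))
        kind <- c(kind, "HY"); pos <- rbind(pos, cen + hy_dist * u)
        src <- c(src, paste0(label, " hydrophobic side chain"))
      }
    }
  }
  if (length(kind) < 3L)
    stop("hotspot residues yielded ", length(kind),
         " feature(s); a pharmacophore needs at least 3")
  pharmacophore(features(kind, pos, tolerance, src), name = name)
}

# Matching ------------------------------------------------------------------------

enumerate_assignments <- function(model_kinds, ligand_kinds, max_n = 1e6) {
  ## all injective, kind-compatible assignments model index -> ligand index
  cand <- lapply(model_kinds, function(k) which(ligand_kinds == k))
  n_upper <- prod(vapply(cand, length, 0))
  if (n_upper == 0) return(list())
  if (n_upper > max_n)
    stop("assignment enumeration would exceed ", format(max_n, scientific = FALSE),
         " combinations; prune ligand features first")
  out <- list()
  rec <- function(i, cur) {
    if (i > length(cand)) { out[[length(out) + 1L]] <<- cur; return(invisible()) }
    for (v in cand[[i]]) if (!(v %in% cur)) rec(i + 1L, c(cur, v))
  }
  rec(1L, integer(0))
  out
}

#' Match ligand features against a pharmacophore model
#'
#' Exhaustively enumerates kind-compatible injective assignments of model
#' features to ligand features (guarded at 10^6 combinations), superposes
#' each candidate rigidly with [superpose()] and returns the assignment of
#' minimal RMSD; ties break lexicographically on the assignment vector. The
#' match is accepted when the RMSD is at most `gate`.
#'
#' @param ligand_features feature table of one conformer
#' @param model an `hx_pharmacophore`
#' @param gate acceptance RMSD, Angstrom (default 1.0)
#' @return an `hx_match`: list(assignment, rotation, translation, rmsd,
#'   accepted); `rmsd = Inf` when no kind-compatible assignment exists
#' @export
match_pharmacophore <- function(ligand_features, model, gate = 1.0) {
  mk <- model$features$kind
  mx <- feature_xyz(model$features)
  no_match <- structure(list(assignment = integer(0), rotation = diag(3),
                             translation = c(0, 0, 0), rmsd = Inf,
                             accepted = FALSE, gate = gate),
                        class = "hx_match")
  if (!nrow(ligand_features)) return(no_match)
  lk <- ligand_features$kind
  lx <- feature_xyz(ligand_features)
  asg <- enumerate_assignments(mk, lk)
  if (!length(asg)) return(no_match)
  best <- NULL
  for (a in asg) {
    sp <- superpose(lx[a, , drop = FALSE], mx)
    if (is.null(best) || sp$rmsd < best$rmsd - 1e-12 ||
        (abs(sp$rmsd - best$rmsd) <= 1e-12 &&
         paste(a, collapse = ",") < paste(best$assignment, collapse = ","))) {
      best <- list(assignment = a, rotation = sp$rotation,
                   translation = sp$translation, rmsd = sp$rmsd)
    }
  }
  structure(c(best, list(accepted = best$rmsd <= gate, gate = gate)),
            class = "hx_match")
}

#' @export
print.hx_match <- function(x, ...) {
  cat("hx_match: rmsd =", format(x$rmsd, digits = 4),
      if (x$accepted) "(accepted)" else "(rejected)", "\n")
  invisible(x)
}
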