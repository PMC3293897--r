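# Deterministic synthetic systems ----------------------------------------------
#
# Generators for every fixture the pipeline needs: a toy antiparallel
# two-helix dimer with planted interface contacts, Gaussian-jittered
# coordinate ensembles standing in for MD production frames, and ligand
# libraries of constructed actives and decoys. Every generator is a pure
# function of its spec and seed. The side chains are reduced pseudo-atom
# models (3-6 atoms), sufficient to realize donors, acceptors, charges and
# hydrophobic tips geometrically; they are not rotamer-accurate chemistry,
# and the jitter is not physical dynamics.

local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = .GlobalEnv))
    else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

unit <- function(v) v / sqrt(sum(v^2))

perp_unit <- function(u) {
  e <- diag(3)[, which.min(abs(u))]
  unit(pracma_cross(u, e))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Specification of a synthetic two-helix dimer
#'
#' Default contacts mirror the interaction pattern of an antiparallel
#' helix-helix dimerization interface: on each chain a glutamine-like donor
#' and a lysine-like donor hydrogen-bond to the two carboxylate oxygens of a
#' glutamate-like acceptor on the partner chain, and leucine-like side
#' chains form a hydrophobic contact across the interface.
#'
#' @param n_res residues per helix (at least 8)
#' @param first_resno first residue number (default 200)
#' @param separation helix axis separation, Angstrom
#' @param rise helical rise per residue, Angstrom
#' @param twist helical twist per residue, degrees
#' @param hbond_target planted donor-heavy to acceptor distance, Angstrom
#' @param planted_contacts plant the donor/acceptor contacts (FALSE gives an
#'   inert all-alanine dimer)
#' @param hydrophobic_patch plant the leucine-like contact
#' @param hydrophobic_target tip-to-tip contact distance, Angstrom
#' @param seed integer seed (kept in the spec for provenance; the default
#'   dimer geometry is fully deterministic)
#' @return a `dimer_spec` list
#' @export
dimer_spec <- function(n_res = 11L, first_resno = 200L, separation = 10,
                       rise = 1.5, twist = 100, hbond_target = 2.9,
                       planted_contacts = TRUE, hydrophobic_patch = TRUE,
                       hydrophobic_target = 4.0, seed = 1L) {
  if (n_res < 8L) stop("n_res must be at least 8")
  list(n_res = as.integer(n_res), first_resno = as.integer(first_resno),
       separation = separation, rise = rise, twist = twist,
       hbond_target = hbond_target, planted_contacts = planted_contacts,
       hydrophobic_patch = hydrophobic_patch,
       hydrophobic_target = hydrophobic_target, seed = as.integer(seed))
}

#' Build a toy antiparallel two-helix dimer with planted contacts
#'
#' Two ideal helices (CA trace with the spec's rise and twist) run
#' antiparallel at the spec's axis separation. Planted residues carry
#' reduced pseudo side chains whose donor/acceptor tips are positioned
#' analytically so every planted hydrogen bond hits its target distance
#' within 1e-6 Angstrom; every atom is parameterized from the built-in
#' table, so chain charges equal the formal sum (+1 lysine, -1 glutamate,
#' net 0 per chain).
#'
#' @param spec a [dimer_spec()]
#' @return list(structure = parameterized 1-frame `hx_structure`,
#'   parameters = the parameter table used)
#' @export
make_toy_dimer <- function(spec = dimer_spec()) {
  n <- spec$n_res; r0 <- spec$first_resno
  a_rad <- 2.3
  zmax <- spec$rise * (n - 1)
  ca <- function(chain, i) {   # i is 0-based residue index
    th <- spec$twist * i * pi / 180
    if (chain == "A")
      c(-spec$separation / 2 + a_rad * cos(th), a_rad * sin(th), spec$rise * i)
    else
      c(spec$separation / 2 + a_rad * cos(th), -a_rad * sin(th),
        zmax - spec$rise * i)
  }
  ## planted roles, mirrored on both chains (residue offsets from first_resno)
  roles <- list(A = rep("ALA", n), B = rep("ALA", n))
  set_role <- function(ch, off, nm) roles[[ch]][off + 1L] <<- nm
  if (spec$planted_contacts) for (ch in c("A", "B")) {
    set_role(ch, 3L, "GLN"); set_role(ch, 4L, "LYS"); set_role(ch, 7L, "GLU")
  }
  ## hydrophobic pair at the helix ends, clear of the polar contact cluster:
  ## antiparallel geometry pairs offset o on A with offset n-1-o on B
  if (spec$hydrophobic_patch) { set_role("A", 1L, "LEU"); set_role("B", n - 2L, "LEU") }
  contacts <- if (spec$planted_contacts) list(
    list(donor = c("A", 3L), acceptor = c("B", 7L), o = "OE1"),
    list(donor = c("A", 4L), acceptor = c("B", 7L), o = "OE2"),
    list(donor = c("B", 3L), acceptor = c("A", 7L), o = "OE1"),
    list(donor = c("B", 4L), acceptor = c("A", 7L), o = "OE2")) else list()

  atoms <- list(); coords <- list()
  serial <- 0L
  add_atom <- function(name, resname, chain, off, element, xyz) {
    serial <<- serial + 1L
    atoms[[serial]] <<- data.frame(
      serial = serial, name = name, resname = resname, chain = chain,
      resno = r0 + off, element = element, charge = 0, epsilon = 0,
      rmin_half = 0, radius = 0, is_h = element == "H",
      stringsAsFactors = FALSE)
    coords[[serial]] <<- xyz
  }

  ## precompute donor tip positions (they anchor the acceptor oxygens too)
  t <- spec$hbond_target
  donor_tips <- list()   # key "chain:off" -> list(n_pos, u, kind)
  for (cc in contacts) {
    dch <- cc$donor[1]; doff <- as.integer(cc$donor[2])
    ach <- cc$acceptor[1]; aoff <- as.integer(cc$acceptor[2])
    pA <- ca(dch, doff); pB <- ca(ach, aoff)
    L <- sqrt(sum((pB - pA)^2))
    if ((L - t) / 2 < 1.5)
      stop("planted contact unrealizable: helices too close (CA distance ",
           round(L, 2), " A for target ", t, " A)")
    u <- unit(pB - pA)
    n_pos <- pA + ((L - t) / 2) * u
    donor_tips[[paste(dch, doff)]] <- list(
      n_pos = n_pos, u = u, kind = roles[[dch]][doff + 1L],
      o_pos = n_pos + t * u, o_name = cc$o, acceptor = c(ach, aoff))
  }
  acceptor_oxy <- list()  # key "chain:off" -> named positions
  for (dt in donor_tips) {
    key <- paste(dt$acceptor[1], dt$acceptor[2])
    acceptor_oxy[[key]] <- c(acceptor_oxy[[key]],
                             setNames(list(dt$o_pos), dt$o_name))
  }

  for (ch in c("A", "B")) for (i in seq_len(n) - 1L) {
    nm <- roles[[ch]][i + 1L]
    p <- ca(ch, i)
    add_atom("CA", nm, ch, i, "C", p)
    key <- paste(ch, i)
    if (nm == "GLN" && !is.null(donor_tips[[key]])) {
      dt <- donor_tips[[key]]
      w <- perp_unit(dt$u)
      add_atom("CD", nm, ch, i, "C", dt$n_pos - 1.33 * dt$u)
      add_atom("NE2", nm, ch, i, "N", dt$n_pos)
      add_atom("HE21", nm, ch, i, "H", dt$n_pos + 1.0 * dt$u)
      add_atom("HE22", nm, ch, i, "H", dt$n_pos + 1.0 * unit(-0.35 * dt$u + w))
    } else if (nm == "LYS" && !is.null(donor_tips[[key]])) {
      dt <- donor_tips[[key]]
      w1 <- perp_unit(dt$u); w2 <- unit(pracma_cross(dt$u, w1))
      add_atom("CE", nm, ch, i, "C", dt$n_pos - 1.5 * dt$u)
      add_atom("NZ", nm, ch, i, "N", dt$n_pos)
      add_atom("HZ1", nm, ch, i, "H", dt$n_pos + 1.0 * dt$u)
      add_atom("HZ2", nm, ch, i, "H",
               dt$n_pos + 1.0 * unit(-0.33 * dt$u + 0.94 * w1))
      add_atom("HZ3", nm, ch, i, "H",
               dt$n_pos + 1.0 * unit(-0.33 * dt$u - 0.47 * w1 + 0.82 * w2))
    } else if (nm == "GLU" && !is.null(acceptor_oxy[[key]])) {
      oxy <- acceptor_oxy[[key]]
      mid <- colMeans(do.call(rbind, oxy))
      cd <- mid + 0.7 * unit(p - mid)
      add_atom("CD", nm, ch, i, "C", cd)
      for (on in names(oxy)) add_atom(on, nm, ch, i, "O", oxy[[on]])
    } else if (nm == "LEU") {
      partner <- if (ch == "A") "B" else "A"
      pB <- ca(partner, n - 1L - i)
      L <- sqrt(sum((pB - p)^2)); u <- unit(pB - p)
      cg <- p + ((L - spec$hydrophobic_target) / 2) * u
      w <- perp_unit(u)
      add_atom("CG", nm, ch, i, "C", cg)
      add_atom("CD1", nm, ch, i, "C", cg + 1.5 * w)
      add_atom("CD2", nm, ch, i, "C", cg - 1.5 * w)
    }
  }
  atoms <- do.call(rbind, atoms)
  xyz <- do.call(rbind, coords)
  st <- assign_parameters(new_structure(atoms, list(xyz)))
  list(structure = st, parameters = default_parameter_table())
}

#' Gaussian-jittered coordinate ensemble
#'
#' Frame 1 is the unjittered reference; frames 2..n_frames add i.i.d.
#' Gaussian noise (sd `sigma` per coordinate) to the reference. A stand-in
#' for MD production frames, not physical dynamics.
#'
#' @param x an `hx_structure` (its frame 1 is the reference)
#' @param sigma noise standard deviation, Angstrom
#' @param n_frames total frames including the reference
#' @param seed integer seed
#' @return `hx_structure` with `n_frames` frames
#' @export
jitter_ensemble <- function(x, sigma = 0.1, n_frames = 20L, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  ref <- x$frames[[1]]
  frames <- local_seed(seed, {
    lapply(seq_len(n_frames), function(k) {
      if (k == 1L) ref
      else ref + matrix(stats::rnorm(length(ref), 0, sigma), nrow = nrow(ref))
    })
  })
  new_structure(x$atoms, frames)
}

# Ligand library ------------------------------------------------------------------

#' Specification of a synthetic ligand library
#'
#' @param n_actives ligands built to satisfy the pharmacophore
#' @param n_decoys ligands built to violate it (cycling through a displaced
#'   hydrophobic ring, a displaced donor, and a donor-to-methyl kind swap)
#' @param displacement decoy feature displacement, Angstrom
#' @param n_analogs actives with the nitro-like charged acceptor replaced by
#'   a neutral carbonyl (same geometry; still pharmacophore-compatible)
#' @param noise uniform placement noise half-width for actives, Angstrom
#' @param seed integer seed
#' @return a `library_spec` list
#' @export
library_spec <- function(n_actives = 10L, n_decoys = 40L, displacement = 2.5,
                         n_analogs = 0L, noise = 0.25, seed = 1L) {
  if (noise >= 0.3) stop("active placement noise must stay below 0.3 A")
  list(n_actives = as.integer(n_actives), n_decoys = as.integer(n_decoys),
       displacement = displacement, n_analogs = as.integer(n_analogs),
       noise = noise, seed = as.integer(seed))
}

## build one ligand from per-feature group positions
build_feature_ligand <- function(name, kinds, points, center, nitro_idx,
                                 charged_acceptor = TRUE, radial_point = NULL,
                                 avoid = NULL) {
  atoms <- list(); coords <- list(); bonds <- list(); groups <- list()
  add <- function(element, charge, xyz, nm = element) {
    k <- length(atoms) + 1L
    atoms[[k]] <<- data.frame(name = paste0(nm, k), element = element,
                              charge = charge, epsilon = 0, rmin_half = 0,
                              radius = 0, is_h = element == "H",
                              stringsAsFactors = FALSE)
    coords[[k]] <<- xyz
    k
  }
  bond <- function(i, j, order = 1L)
    bonds[[length(bonds) + 1L]] <<- data.frame(i = i, j = j, order = order)
  anchors <- integer(0)
  for (f in seq_along(kinds)) {
    p <- points[f, ]
    u_in <- unit(center - p)
    u_perp <- perp_unit(u_in)
    if (kinds[f] == "HD") {
      nid <- add("N", -0.70, p)
      h1 <- add("H", 0.35, p - 1.0 * u_in)
      h2 <- add("H", 0.35, p + 1.0 * u_perp)
      bond(nid, h1); bond(nid, h2)
      anchors <- c(anchors, nid)
    } else if (kinds[f] == "HA" && f == nitro_idx && charged_acceptor) {
      nid <- add("N", 0.65, p + 1.22 * u_in)
      o1 <- add("O", -0.55, p)
      o2 <- add("O", -0.55, p + 1.22 * u_in + 1.22 * u_perp)
      bond(nid, o1, 2L); bond(nid, o2, 1L)
      groups$nitro <- c(nid, o1, o2)
      anchors <- c(anchors, nid)
    } else if (kinds[f] == "HA" && f == nitro_idx) {
      cid <- add("C", 0.45, p + 1.23 * u_in)
      o1 <- add("O", -0.45, p)
      bond(cid, o1, 2L)
      groups$nitro <- c(cid, o1)   # neutral carbonyl replacing the nitro
      anchors <- c(anchors, cid)
    } else if (kinds[f] == "HA") {
      cid <- add("C", 0.45, p + 1.23 * u_in)
      o1 <- add("O", -0.45, p)
      bond(cid, o1, 2L)
      anchors <- c(anchors, cid)
    } else if (kinds[f] == "CH3") {
      ## featureless methyl (used by kind-swap decoys in place of a donor)
      cid <- add("C", 0, p)
      for (k in 1:3) {
        h <- add("H", 0, p + 1.09 * unit(-u_in + 0.8 * (k - 2) * u_perp))
        bond(cid, h)
      }
      anchors <- c(anchors, cid)
    } else if (kinds[f] == "HY") {
      ## ring plane tangent to the receptor surface when it is known
      normal <- if (!is.null(avoid)) {
        d2 <- colSums((t(avoid) - p)^2)
        unit(p - avoid[which.min(d2), ])
      } else if (!is.null(radial_point)) unit(p - radial_point) else u_in
      e1 <- perp_unit(normal)
      e2 <- unit(pracma_cross(normal, e1))
      ring <- integer(6)
      for (k in 0:5) {
        th <- k * pi / 3
        pos <- p + 1.39 * (cos(th) * e1 + sin(th) * e2)
        ring[k + 1L] <- add("C", 0, pos)
        if (k > 0) {
          h <- add("H", 0, p + 2.47 * (cos(th) * e1 + sin(th) * e2))
          bond(ring[k + 1L], h)
        }
      }
      for (k in 1:6) bond(ring[k], ring[k %% 6 + 1L], if (k %% 2) 2L else 1L)
      anchors <- c(anchors, ring[1])
    }
  }
  ## chain of linker carbons, one per group, keeps every valence plausible
  linkers <- integer(length(anchors))
  for (k in seq_along(anchors)) {
    ap <- coords[[anchors[k]]]
    lp <- ap + 1.5 * unit(center - ap)
    linkers[k] <- add("C", 0, lp)
    bond(anchors[k], linkers[k])
    if (k > 1) bond(linkers[k - 1L], linkers[k])
  }
  hl <- add("H", 0, coords[[linkers[1]]] + c(0, 0, 1.09))
  bond(linkers[1], hl)
  lig <- new_ligand(name, do.call(rbind, atoms), do.call(rbind, bonds),
                    list(do.call(rbind, coords)), groups)
  ## LJ/radius parameters from the built-in table; keep constructed charges
  q <- lig$atoms$charge
  lig <- assign_parameters(lig)
  lig$atoms$charge <- q
  lig
}

#' Generate a synthetic active/decoy ligand library
#'
#' Actives place one chemical group per model feature (amine at HD points,
#' carbonyl at HA points, a nitro group at the final HA point, a benzene
#' ring centered on HY points) with uniform placement noise below 0.3 A, on
#' a rigid linker scaffold; each active gets a second, rigidly rotated
#' conformer. Decoys cycle through three violations: hydrophobic ring
#' displaced by `displacement`, a donor displaced by `displacement`, and
#' donors swapped to methyls. Construction is matcher-audited: every active
#' must pass the 1.0-A gate and every decoy must fail it (decoy
#' displacements are escalated, never reduced, if a violation is too mild);
#' a construction that cannot satisfy the audit is an error.
#'
#' @param spec a [library_spec()]
#' @param model the reference `hx_pharmacophore`
#' @param away_from optional 3-vector (e.g. receptor centroid); the linker
#'   scaffold is pushed away from it to keep scaffolds out of the receptor
#' @param avoid optional matrix of receptor heavy-atom coordinates used to
#'   orient ring planes tangent to the receptor surface
#' @return list of `hx_ligand` (actives, then analogs, then decoys)
#' @export
make_ligand_library <- function(spec = library_spec(), model,
                                away_from = NULL, avoid = NULL) {
  if (nrow(model$features) < 3L) stop("model needs at least 3 features")
  kinds <- model$features$kind
  pts <- feature_xyz(model$features)
  nitro_idx <- { w <- which(kinds == "HA"); if (length(w)) w[length(w)] else 0L }
  center <- colMeans(pts)
  if (!is.null(away_from)) center <- center + 2.0 * unit(center - away_from)

  local_seed(spec$seed, {
    rnd_dir <- function() unit(stats::rnorm(3))
    noisy_pts <- function() pts + matrix(stats::runif(length(pts), -spec$noise,
                                                      spec$noise) / sqrt(3),
                                         nrow = nrow(pts))
    rotate_conf <- function(cf) {
      R <- rotation_about(c(0, 0, 1), 30)
      cen <- colMeans(cf)
      sweep(sweep(cf, 2, cen) %*% t(R), 2, cen + c(3, 0, 0), "+")
    }
    lib <- list()
    build_active <- function(name, charged = TRUE) {
      lg <- build_feature_ligand(name, kinds, noisy_pts(), center, nitro_idx,
                                 charged_acceptor = charged,
                                 radial_point = away_from, avoid = avoid)
      lg$conformers[[2]] <- rotate_conf(lg$conformers[[1]])
      m <- match_pharmacophore(type_ligand_features(lg, 1), model, gate = 1.0)
      if (!m$accepted)
        stop("library construction audit failed: active '", name,
             "' rejected (rmsd ", round(m$rmsd, 3), ")")
      lg
    }
    for (k in seq_len(spec$n_actives))
      lib[[length(lib) + 1L]] <- build_active(sprintf("active_%02d", k))
    for (k in seq_len(spec$n_analogs))
      lib[[length(lib) + 1L]] <- build_active(sprintf("analog_%02d", k),
                                              charged = FALSE)
    modes <- c("displace_hy", "displace_hd", "kind_swap")
    for (k in seq_len(spec$n_decoys)) {
      mode <- modes[(k - 1L) %% 3L + 1L]
      name <- sprintf("decoy_%02d_%s", k, mode)
      disp <- spec$displacement
      dirv <- rnd_dir()
      for (try in 1:6) {
        p2 <- pts
        k2 <- kinds
        if (mode == "displace_hy") {
          tgt <- which(kinds == "HY")[1]
          if (is.na(tgt)) tgt <- 1L
          p2[tgt, ] <- p2[tgt, ] + disp * dirv
        } else if (mode == "displace_hd") {
          tgt <- which(kinds == "HD")[1]
          if (is.na(tgt)) tgt <- nrow(p2)
          p2[tgt, ] <- p2[tgt, ] + disp * dirv
        } else {
          k2[kinds == "HD"] <- "CH3"   # donors become plain methyls
        }
        lg <- build_feature_ligand(name, k2, p2, center, nitro_idx,
                                   radial_point = away_from, avoid = avoid)
        m <- match_pharmacophore(type_ligand_features(lg, 1), model, gate = 1.0)
        if (!m$accepted) break
        disp <- disp * 1.4
        if (try == 6)
          stop("library construction audit failed: decoy '", name,
               "' still matches at displacement ", round(disp, 2))
      }
      lib[[length(lib) + 1L]] <- lg
    }
    lib
  })
}
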