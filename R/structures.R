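# Data model: parameterized structures and ligands ---------------------------
#
# A `hx_structure` is a list with
#   atoms : data.frame(serial, name, resname, chain, resno, element,
#                      charge, epsilon, rmin_half, radius, is_h)
#   frames: list of N x 3 coordinate matrices (Angstrom); frames[[1]] is the
#           reference frame. Frame iteration order is the list order and is
#           preserved by every operation in the package.
#
# A `hx_ligand` is a list with
#   name      : molecule name
#   atoms     : data.frame(name, element, charge, epsilon, rmin_half, radius, is_h)
#   bonds     : data.frame(i, j, order) with 1-based atom indices
#   conformers: list of N x 3 coordinate matrices (Angstrom)
#   groups    : optional named list of atom index vectors (e.g. nitro)

ATOM_COLS <- c("serial", "name", "resname", "chain", "resno", "element",
               "charge", "epsilon", "rmin_half", "radius", "is_h")

new_structure <- function(atoms, frames) {
  stopifnot(is.data.frame(atoms), length(frames) >= 1L)
  atoms <- atoms[, ATOM_COLS]
  for (k in seq_along(frames)) {
    fr <- as.matrix(frames[[k]])
    if (nrow(fr) != nrow(atoms) || ncol(fr) != 3L)
      stop("frame ", k, " has wrong dimensions (", nrow(fr), " x ", ncol(fr),
           " for ", nrow(atoms), " atoms)")
    if (!all(is.finite(fr))) stop("non-finite coordinates in frame ", k)
    dimnames(fr) <- NULL
    frames[[k]] <- fr
  }
  if (anyDuplicated(atoms$serial)) stop("atom serials are not unique")
  structure(list(atoms = atoms, frames = frames), class = "hx_structure")
}

new_ligand <- function(name, atoms, bonds, conformers, groups = list()) {
  atoms$is_h <- atoms$element == "H"
  if (nrow(bonds)) {
    bad <- bonds$i < 1 | bonds$i > nrow(atoms) | bonds$j < 1 | bonds$j > nrow(atoms)
    if (any(bad)) stop("bond to nonexistent atom index in ligand '", name, "'")
  }
  conformers <- lapply(conformers, function(m) {
    m <- as.matrix(m)
    stopifnot(nrow(m) == nrow(atoms), ncol(m) == 3L)
    dimnames(m) <- NULL
    m
  })
  structure(list(name = name, atoms = atoms, bonds = bonds,
                 conformers = conformers, groups = groups),
            class = "hx_ligand")
}

#' @export
print.hx_structure <- function(x, ...) {
  cat("hx_structure:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s),",
      nrow(residue_table(x)), "residues,", length(x$frames), "frame(s)\n")
  invisible(x)
}

#' @export
print.hx_ligand <- function(x, ...) {
  cat("hx_ligand '", x$name, "': ", nrow(x$atoms), " atoms, ",
      nrow(x$bonds), " bonds, ", length(x$conformers), " conformer(s)\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms
#' @param x an `hx_structure`
#' @return integer count
#' @export
n_frames <- function(x) length(x$frames)

#' Residue table of a structure
#'
#' One row per residue in deterministic order (chain, then residue number),
#' with the atom index range of each residue.
#'
#' @param x an `hx_structure`
#' @return data.frame(chain, resno, resname, idx = list of atom indices)
#' @export
residue_table <- function(x) {
  key <- paste(x$atoms$chain, x$atoms$resno, sep = "\r")
  idx <- split(seq_len(nrow(x$atoms)), factor(key, levels = unique(key)))
  res <- data.frame(
    chain   = vapply(idx, function(i) x$atoms$chain[i[1]], ""),
    resno   = vapply(idx, function(i) x$atoms$resno[i[1]], 0L),
    resname = vapply(idx, function(i) x$atoms$resname[i[1]], ""),
    stringsAsFactors = FALSE)
  res$idx <- unname(idx)
  ord <- order(res$chain, res$resno)
  res <- res[ord, ]
  rownames(res) <- paste0(res$chain, ":", res$resno)
  res
}

#' Extract one chain as a new structure
#' @param x an `hx_structure`
#' @param chain chain identifier
#' @return `hx_structure` with the selected chain only (all frames kept)
#' @export
select_chain <- function(x, chain) {
  keep <- x$atoms$chain == chain
  if (!any(keep)) stop("no atoms in chain '", chain, "'")
  new_structure(x$atoms[keep, , drop = FALSE],
                lapply(x$frames, function(m) m[keep, , drop = FALSE]))
}

resolve_residue <- function(x, res) {
  ## residue reference: "A:203" or list/vector (chain, resno)
  if (is.character(res) && length(res) == 1L && grepl(":", res)) {
    parts <- strsplit(res, ":", fixed = TRUE)[[1]]
    chain <- parts[1]; resno <- as.integer(parts[2])
  } else {
    chain <- as.character(res[[1]]); resno <- as.integer(res[[2]])
  }
  i <- which(x$atoms$chain == chain & x$atoms$resno == resno)
  if (!length(i)) stop("residue ", chain, ":", resno, " not found")
  i
}

# PDB input/output ------------------------------------------------------------

#' Read a (possibly multi-model) PDB file
#'
#' MODEL/ENDMDL records become frames; a single-model file yields one frame.
#' Coordinates are validated line-by-line before parsing so that malformed
#' ATOM records are reported with their line number. Force-field parameters
#' are zero until [assign_parameters()] is called.
#'
#' @param path PDB file path
#' @param multi_model read all MODEL records as frames (default TRUE)
#' @return an `hx_structure`
#' @export
read_pdb <- function(path, multi_model = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (ln in which(is_atom)) {
    s <- lines[ln]
    if (nchar(s) < 54)
      stop("malformed ATOM record at line ", ln, ": record too short")
    xyz <- suppressWarnings(as.numeric(
      c(substr(s, 31, 38), substr(s, 39, 46), substr(s, 47, 54))))
    if (any(is.na(xyz)))
      stop("malformed ATOM record at line ", ln, ": unreadable coordinates")
  }
  n_per_model <- integer(0)
  if (any(grepl("^MODEL", lines))) {
    cur <- NA_integer_
    for (s in lines) {
      if (grepl("^MODEL", s)) cur <- 0L
      else if (grepl("^ENDMDL", s)) { n_per_model <- c(n_per_model, cur); cur <- NA_integer_ }
      else if (grepl("^(ATOM  |HETATM)", s) && !is.na(cur)) cur <- cur + 1L
    }
    if (length(unique(n_per_model)) > 1L)
      stop("inconsistent atom counts across MODEL records: ",
           paste(n_per_model, collapse = ", "))
  }
  pdb <- bio3d::read.pdb(path, multi = multi_model, verbose = FALSE)
  at <- pdb$atom
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  n <- nrow(at)
  elem <- at$elesy
  if (is.null(elem) || all(!nzchar(trimws(elem))))
    elem <- substr(trimws(at$elety), 1, 1)
  elem <- trimws(elem)
  blank <- !nzchar(elem)
  elem[blank] <- substr(trimws(at$elety[blank]), 1, 1)
  atoms <- data.frame(
    serial = at$eleno, name = trimws(at$elety), resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "A", at$chain), resno = at$resno,
    element = elem, charge = 0, epsilon = 0, rmin_half = 0, radius = 0,
    is_h = elem == "H", stringsAsFactors = FALSE)
  frames <- lapply(seq_len(nrow(xyz)), function(k)
    matrix(xyz[k, ], ncol = 3L, byrow = TRUE))
  if (!multi_model) frames <- frames[1]
  new_structure(atoms, frames)
}

#' Write a structure to PDB (one MODEL per frame)
#' @param x an `hx_structure`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_pdb <- function(x, path) {
  a <- x$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x$frames) > 1L
  for (k in seq_along(x$frames)) {
    fr <- x$frames[[k]]
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial, ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
      a$resname, a$chain, a$resno, fr[, 1], fr[, 2], fr[, 3], 1, 0, a$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# SDF input/output ------------------------------------------------------------

#' Read a multi-record V2000 SDF file into ligands
#'
#' Consecutive records sharing a molecule name and atom count are merged as
#' conformers of one ligand. Parameters (charge/LJ/radius) are zero until
#' [assign_parameters()].
#'
#' @param path SDF file path
#' @return list of `hx_ligand`
#' @export
read_sdf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- readLines(path, warn = FALSE)
  if (!any(nzchar(trimws(txt)))) {
    warning("empty SDF file: ", path)
    return(list())
  }
  sdfs <- ChemmineR::read.SDFset(path)
  ligs <- list()
  for (k in seq_along(ChemmineR::SDFset2SDF(sdfs))) {
    sdf <- sdfs[[k]]
    ab <- ChemmineR::atomblock(sdf)
    bb <- ChemmineR::bondblock(sdf)
    nm <- ChemmineR::header(sdf)[["Molecule_Name"]]
    elem <- sub("_[0-9]+$", "", rownames(ab))
    atoms <- data.frame(
      name = rownames(ab), element = elem,
      charge = 0, epsilon = 0, rmin_half = 0, radius = 0,
      is_h = elem == "H", stringsAsFactors = FALSE)
    if (is.null(dim(bb))) bb <- matrix(bb, nrow = 1L)
    bonds <- if (nrow(bb)) data.frame(i = as.integer(bb[, 1]),
                                      j = as.integer(bb[, 2]),
                                      order = as.integer(bb[, 3]))
             else data.frame(i = integer(0), j = integer(0), order = integer(0))
    if (nrow(bonds) && any(bonds$i > nrow(atoms) | bonds$j > nrow(atoms)))
      stop("bond to nonexistent atom index in record ", k, " of ", path)
    coords <- unname(ab[, 1:3, drop = FALSE])
    prev <- if (length(ligs)) ligs[[length(ligs)]] else NULL
    if (!is.null(prev) && prev$name == nm && nrow(prev$atoms) == nrow(atoms)) {
      prev$conformers[[length(prev$conformers) + 1L]] <- coords
      ligs[[length(ligs)]] <- prev
    } else {
      ligs[[length(ligs) + 1L]] <- new_ligand(nm, atoms, bonds, list(coords))
    }
  }
  ligs
}

#' Write ligands to a multi-record V2000 SDF file
#'
#' Each conformer becomes one record; conformers of a ligand share its name,
#' which is how [read_sdf()] re-merges them.
#'
#' @param ligands a single `hx_ligand` or list of them
#' @param path output file
#' @return `path`, invisibly
#' @export
write_sdf <- function(ligands, path) {
  if (inherits(ligands, "hx_ligand")) ligands <- list(ligands)
  con <- file(path, "w")
  on.exit(close(con))
  for (lig in ligands) {
    for (cf in lig$conformers) {
      writeLines(c(lig$name, "  helixscreen", ""), con)
      writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                         nrow(lig$atoms), nrow(lig$bonds)), con)
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         cf[, 1], cf[, 2], cf[, 3], lig$atoms$element), con)
      if (nrow(lig$bonds))
        writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                           lig$bonds$i, lig$bonds$j, lig$bonds$order), con)
      writeLines(c("M  END", "$$$$"), con)
    }
  }
  invisible(path)
}

# Force-field parameter assignment --------------------------------------------

#' Built-in force-field parameter table
#'
#' A compact lookup of partial charges, Lennard-Jones parameters (Amber
#' convention: well depth epsilon in kcal/mol and half of the pair-minimum
#' distance rmin/2 in Angstrom) and Bondi-style collision radii. Rows with
#' `residue == "*"` match any residue by element and carry zero charge;
#' named rows cover the reduced pseudo-residues used by the synthetic
#' generators, with charges that sum to each residue's formal charge
#' (GLU -1 e, LYS +1 e, others 0). Users reproducing a published charge
#' model supply their own table via `read_parameter_table()`.
#'
#' @return data.frame(residue, atom, charge, epsilon, rmin_half, radius)
#' @export
default_parameter_table <- function() {
  el <- function(element, epsilon, rmin_half, radius)
    data.frame(residue = "*", atom = paste0("element:", element),
               charge = 0, epsilon = epsilon, rmin_half = rmin_half,
               radius = radius, stringsAsFactors = FALSE)
  row <- function(residue, atom, charge, epsilon, rmin_half, radius)
    data.frame(residue = residue, atom = atom, charge = charge,
               epsilon = epsilon, rmin_half = rmin_half, radius = radius,
               stringsAsFactors = FALSE)
  rbind(
    el("C", 0.0860, 1.9080, 1.70),
    el("N", 0.1700, 1.8240, 1.55),
    el("O", 0.2100, 1.6612, 1.52),
    el("S", 0.2500, 2.0000, 1.80),
    el("Cl", 0.2650, 1.9480, 1.75),
    el("H", 0.0157, 0.6000, 1.10),
    ## reduced pseudo-residues of the synthetic dimer (charges sum to formal)
    row("GLN", "NE2", -0.80, 0.1700, 1.8240, 1.55),
    row("GLN", "HE21", 0.40, 0.0157, 0.6000, 1.10),
    row("GLN", "HE22", 0.40, 0.0157, 0.6000, 1.10),
    row("GLU", "CD", 0.50, 0.0860, 1.9080, 1.70),
    row("GLU", "OE1", -0.75, 0.2100, 1.6612, 1.52),
    row("GLU", "OE2", -0.75, 0.2100, 1.6612, 1.52),
    row("LYS", "NZ", -0.30, 0.1700, 1.8240, 1.55),
    row("LYS", "HZ1", 0.433, 0.0157, 0.6000, 1.10),
    row("LYS", "HZ2", 0.433, 0.0157, 0.6000, 1.10),
    row("LYS", "HZ3", 0.434, 0.0157, 0.6000, 1.10))
}

#' Read a user-supplied parameter table
#'
#' Tab-separated columns: residue, atom, charge, epsilon, rmin_half, radius.
#' Use `residue = "*"` and `atom = "element:X"` for element-generic rows.
#'
#' @param path TSV file
#' @return parameter table data.frame
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("residue", "atom", "charge", "epsilon", "rmin_half", "radius")
  if (!all(need %in% names(tab)))
    stop("parameter table must have columns: ", paste(need, collapse = ", "))
  tab[, need]
}

#' Write a parameter table to TSV
#' @param table parameter table data.frame
#' @param path output file
#' @return `path`, invisibly
#' @export
write_parameter_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

lookup_params <- function(resname, name, element, table) {
  n <- length(name)
  out <- data.frame(charge = rep(NA_real_, n), epsilon = NA_real_,
                    rmin_half = NA_real_, radius = NA_real_)
  key_exact <- paste(table$residue, table$atom, sep = "\r")
  hit <- match(paste(resname, name, sep = "\r"), key_exact)
  gen <- match(paste("*", paste0("element:", element), sep = "\r"), key_exact)
  use <- ifelse(is.na(hit), gen, hit)
  miss <- is.na(use)
  if (any(miss))
    stop("unresolvable atoms in parameter table: ",
         paste(unique(paste0(resname[miss], "/", name[miss],
                             " (", element[miss], ")")), collapse = ", "))
  out$charge <- table$charge[use]
  out$epsilon <- table$epsilon[use]
  out$rmin_half <- table$rmin_half[use]
  out$radius <- table$radius[use]
  out
}

#' Assign force-field parameters to a structure or ligand
#'
#' Exact (residue, atom-name) rows take precedence over element-generic rows.
#' Idempotent: reassignment with the same table reproduces the same values.
#'
#' @param x `hx_structure` or `hx_ligand`
#' @param table parameter table (default [default_parameter_table()])
#' @return `x` with charge, epsilon, rmin_half and radius filled
#' @export
assign_parameters <- function(x, table = default_parameter_table()) {
  if (inherits(x, "hx_structure")) {
    p <- lookup_params(x$atoms$resname, x$atoms$name, x$atoms$element, table)
  } else if (inherits(x, "hx_ligand")) {
    p <- lookup_params(rep("*", nrow(x$atoms)), x$atoms$name,
                       x$atoms$element, table)
  } else stop("x must be an hx_structure or hx_ligand")
  x$atoms$charge <- p$charge
  x$atoms$epsilon <- p$epsilon
  x$atoms$rmin_half <- p$rmin_half
  x$atoms$radius <- p$radius
  bad <- !x$atoms$is_h & x$atoms$radius <= 0
  if (any(bad)) stop("non-hydrogen atoms with non-positive radius after assignment")
  x
}

# Rotatable bonds --------------------------------------------------------------

heavy_neighbors <- function(lig) {
  n <- nrow(lig$atoms)
  nb <- vector("list", n)
  for (r in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[r]; j <- lig$bonds$j[r]
    nb[[i]] <- c(nb[[i]], j); nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

bond_in_ring <- function(lig, bi, bj, nb) {
  ## BFS from bj back to bi without using the bond (bi,bj); path <= 7 atoms
  seen <- rep(FALSE, nrow(lig$atoms))
  frontier <- setdiff(nb[[bj]], bi)
  seen[bj] <- TRUE
  depth <- 1L
  while (length(frontier) && depth <= 6L) {
    if (bi %in% frontier) return(TRUE)
    seen[frontier] <- TRUE
    frontier <- unique(unlist(nb[frontier]))
    frontier <- frontier[!seen[frontier]]
    depth <- depth + 1L
  }
  FALSE
}

#' Count rotatable bonds of a ligand
#'
#' A bond is rotatable when it is a non-ring single bond between two heavy
#' atoms that each carry at least one further heavy neighbor (so terminal
#' bonds such as methyl rotations are excluded).
#'
#' @param lig an `hx_ligand`
#' @return integer count
#' @export
count_rotatable <- function(lig) {
  if (!nrow(lig$bonds)) return(0L)
  nb <- heavy_neighbors(lig)
  heavy <- !lig$atoms$is_h
  n_heavy_nb <- vapply(nb, function(v) sum(heavy[v]), 0L)
  cnt <- 0L
  for (r in seq_len(nrow(lig$bonds))) {
    i <- lig$bonds$i[r]; j <- lig$bonds$j[r]
    if (lig$bonds$order[r] != 1L) next
    if (!heavy[i] || !heavy[j]) next
    if (n_heavy_nb[i] < 2L || n_heavy_nb[j] < 2L) next
    if (bond_in_ring(lig, i, j, nb)) next
    cnt <- cnt + 1L
  }
  cnt
}
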