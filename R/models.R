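#' Atomic model constructor
#'
#' Full-atom or C-alpha-level coordinates in Angstroms. Hetero sites (e.g.
#' structural Zn ions) are carried in a separate table so the restraint
#' machinery can find them.
#'
#' @param atoms data.frame with columns `resno` (integer residue index),
#'   `resid` (3-letter residue name), `elety` (atom name, e.g. "CA"),
#'   `chain`, `x`, `y`, `z` (Angstrom), `elem` (element symbol).
#' @param hetero optional data.frame of hetero sites with columns `elem`,
#'   `x`, `y`, `z` (e.g. one row per Zn ion).
#' @param label free text.
#' @return an object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, hetero = NULL, label = "") {
  req <- c("resno", "resid", "elety", "chain", "x", "y", "z", "elem")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols))
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("empty atomic model")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  atoms$resno <- as.integer(atoms$resno)
  structure(list(atoms = atoms, hetero = hetero, label = as.character(label)[1]),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model: %d atoms, %d residues, %d hetero site(s)%s\n",
              nrow(x$atoms), length(unique(paste(x$atoms$chain, x$atoms$resno))),
              if (is.null(x$hetero)) 0L else nrow(x$hetero),
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Coordinates of a model as an n x 3 matrix
#'
#' For atomic models, `ca_only = TRUE` (default) returns one point per
#' residue at the C-alpha position; bead models return bead centers.
#'
#' @param model an `atomic_model` or `bead_model`.
#' @param ca_only for atomic models, keep C-alpha atoms only.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
model_coords <- function(model, ca_only = TRUE) {
  if (inherits(model, "bead_model")) return(model$centers)
  a <- model$atoms
  if (ca_only && any(a$elety == "CA")) a <- a[a$elety == "CA", ]
  unname(as.matrix(a[, c("x", "y", "z")]))
}

#' Dummy-atom bead model constructor
#'
#' The low-resolution shape representation used by ab initio envelope
#' reconstruction: equal spheres on (typically) a hexagonal lattice, each
#' with an occupancy weight in `[0, 1]`.
#'
#' @param centers n x 3 matrix of bead centers, Angstrom.
#' @param bead_radius uniform bead radius, Angstrom, > 0.
#' @param occupancy per-bead weight in `[0, 1]`; default 1.
#' @param tol allowed fractional overlap: beads closer than
#'   `2 * bead_radius * (1 - tol)` are an error.
#' @param label free text.
#' @return an object of class `bead_model`.
#' @export
bead_model <- function(centers, bead_radius, occupancy = NULL, tol = 0.1,
                       label = "") {
  centers <- as.matrix(centers)
  if (ncol(centers) != 3) stop("centers must be n x 3")
  if (any(!is.finite(centers))) stop("non-finite bead centers")
  if (!is.numeric(bead_radius) || bead_radius <= 0) stop("bead_radius must be > 0")
  if (is.null(occupancy)) occupancy <- rep(1, nrow(centers))
  if (length(occupancy) != nrow(centers) || any(occupancy < 0 | occupancy > 1))
    stop("occupancy must be one weight in [0,1] per bead")
  if (nrow(centers) >= 2) {
    dmin <- min(stats::dist(centers))
    if (dmin < 2 * bead_radius * (1 - tol))
      stop(sprintf("beads overlap: min center distance %.3f < %.3f",
                   dmin, 2 * bead_radius * (1 - tol)))
  }
  structure(list(centers = unname(centers), bead_radius = bead_radius,
                 occupancy = as.numeric(occupancy), label = as.character(label)[1]),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf("bead_model: %d beads, radius %.2f A, volume %.0f A^3%s\n",
              nrow(x$centers), x$bead_radius, bead_volume(x),
              if (nzchar(x$label)) paste0(", '", x$label, "'") else ""))
  invisible(x)
}

#' Occupied volume of a bead model
#'
#' Sum of occupancy-weighted bead volumes (4/3 pi r^3 per bead).
#' @param model a `bead_model`.
#' @return volume in cubic Angstrom.
#' @export
bead_volume <- function(model) {
  sum(model$occupancy) * 4 / 3 * pi * model$bead_radius^3
}

#' Read a PDB file as an atomic or bead model
#'
#' Uses the standard PDB reader from bio3d. Files whose residues are all
#' named `DUM` follow the dummy-atom convention of envelope programs and are
#' returned as a `bead_model` (occupancy column = bead weight; bead radius
#'  from the minimum center distance / 2 unless given). Zn and other
#' HETATM sites of atomic models are returned in the `hetero` table.
#'
#' @param path PDB file path.
#' @param bead_radius override for the bead radius of dummy-atom files.
#' @return an `atomic_model` or `bead_model`.
#' @export
read_model <- function(path, bead_radius = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  if (nrow(a) == 0) stop("no ATOM/HETATM records in ", path)
  if (all(a$resid == "DUM")) {
    centers <- as.matrix(a[, c("x", "y", "z")])
    if (is.null(bead_radius)) {
      if (nrow(centers) < 2) stop("cannot infer bead radius from a single bead")
      bead_radius <- min(stats::dist(centers)) / 2
    }
    occ <- a$o
    occ[is.na(occ)] <- 1
    return(bead_model(centers, bead_radius, occupancy = occ,
                      label = basename(path)))
  }
  het <- a[a$type == "HETATM" & a$resid != "HOH", ]
  atoms <- a[a$type == "ATOM", c("resno", "resid", "elety", "chain",
                                 "x", "y", "z", "elesy")]
  if (nrow(atoms) == 0) atoms <- a[, c("resno", "resid", "elety", "chain",
                                       "x", "y", "z", "elesy")]
  names(atoms)[names(atoms) == "elesy"] <- "elem"
  atoms$chain[is.na(atoms$chain)] <- "A"
  blank <- is.na(atoms$elem) | !nzchar(trimws(atoms$elem))
  atoms$elem[blank] <- substr(trimws(atoms$elety[blank]), 1, 1)
  hetero <- if (nrow(het) > 0) {
    el <- trimws(het$elesy)
    el[!nzchar(el)] <- trimws(het$elety[!nzchar(el)])
    data.frame(elem = el, x = het$x, y = het$y, z = het$z)
  }
  atomic_model(atoms, hetero = hetero, label = basename(path))
}

#' Write an atomic or bead model to a PDB file
#'
#' Bead models are written in the dummy-atom dialect (residue `DUM`, atom
#' `CA`, occupancy column = bead weight). Hetero sites of atomic models are
#' written as HETATM records.
#'
#' @param model `atomic_model` or `bead_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (inherits(model, "bead_model")) {
    n <- nrow(model$centers)
    xyz <- as.vector(t(model$centers))
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = seq_len(n), resid = rep("DUM", n),
                     elety = rep("CA", n), chain = rep("A", n),
                     o = model$occupancy, b = rep(0, n))
    return(invisible(path))
  }
  a <- model$atoms
  het <- model$hetero
  n <- nrow(a)
  type <- rep("ATOM", n)
  resno <- a$resno; resid <- a$resid; elety <- a$elety; chain <- a$chain
  elesy <- a$elem
  xyz <- as.vector(t(as.matrix(a[, c("x", "y", "z")])))
  if (!is.null(het) && nrow(het) > 0) {
    type <- c(type, rep("HETATM", nrow(het)))
    resno <- c(resno, max(a$resno) + seq_len(nrow(het)))
    resid <- c(resid, toupper(substr(het$elem, 1, 3)))
    elety <- c(elety, toupper(het$elem))
    chain <- c(chain, rep(chain[1], nrow(het)))
    elesy <- c(elesy, het$elem)
    xyz <- c(xyz, as.vector(t(as.matrix(het[, c("x", "y", "z")]))))
  }
  bio3d::write.pdb(file = path, xyz = xyz, type = type, resno = resno,
                   resid = resid, elety = elety, chain = chain,
                   elesy = elesy, o = rep(1, length(resno)),
                   b = rep(0, length(resno)))
  invisible(path)
}
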