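# signed dihedral angle (radians) defined by four points, IUPAC convention
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  -atan2(sum(m1 * n2), sum(n1 * n2))
}

#' Protein angular value from phi/psi angles
#'
#' \deqn{PAV_i = \frac{180}{\pi} \arccos(\cos(\psi_i + \varphi_i))}
#' The arccos-of-cos folding maps the circular sum \eqn{\psi + \varphi}
#' onto `[0, 180]` degrees, removing the range-definition ambiguity of
#' circular variables so profiles of different models can be compared
#' point-wise.
#'
#' @param phi,psi backbone dihedrals in degrees (vectors).
#' @return PAV values in degrees, `[0, 180]`.
#' @export
pav <- function(phi, psi) {
  180 / pi * acos(pmin(pmax(cos((psi + phi) * pi / 180), -1), 1))
}

#' Per-residue PAV profile of a model
#'
#' Computes backbone phi/psi dihedrals from N, C-alpha, C coordinates and
#' folds them into the protein angular value. The first residue (no phi)
#' and the last (no psi) are omitted, as are residues flanking a chain
#' break (consecutive C-alpha distance above 4.5 Angstrom). Alternatively,
#' precomputed angles can be supplied directly.
#'
#' @param model an `atomic_model` with N, CA, C atoms; or `NULL` when
#'   `phi`/`psi` are given.
#' @param phi,psi optional precomputed dihedrals, degrees, with `resno`.
#' @param resno residue indices accompanying precomputed angles.
#' @return a `pav_profile` data.frame: `resno`, `phi`, `psi`, `pav`
#'   (degrees), with the model label as an attribute.
#' @export
pav_profile <- function(model = NULL, phi = NULL, psi = NULL, resno = NULL) {
  if (is.null(model)) {
    stopifnot(length(phi) == length(psi))
    if (is.null(resno)) resno <- seq_along(phi)
    out <- data.frame(resno = resno, phi = phi, psi = psi, pav = pav(phi, psi))
    class(out) <- c("pav_profile", "data.frame")
    return(out)
  }
  a <- model$atoms
  res <- unique(a$resno[a$elety == "CA"])
  if (length(res) < 3) stop("fewer than 3 residues")
  get_atom <- function(rn, name) {
    row <- a[a$resno == rn & a$elety == name, ]
    if (nrow(row) == 0) return(NULL)
    c(row$x[1], row$y[1], row$z[1])
  }
  ca <- t(vapply(res, function(rn) get_atom(rn, "CA"), numeric(3)))
  dca <- sqrt(rowSums(diff(ca)^2))
  broken_after <- c(dca > 4.5 | diff(res) != 1, TRUE)  # break after residue i?
  broken_before <- c(TRUE, broken_after[-length(res)])
  rows <- lapply(seq_along(res), function(i) {
    if (broken_before[i] || broken_after[i]) return(NULL)
    rn <- res[i]
    Cm <- get_atom(res[i - 1], "C"); Ni <- get_atom(rn, "N")
    CAi <- get_atom(rn, "CA"); Ci <- get_atom(rn, "C")
    Np <- get_atom(res[i + 1], "N")
    if (is.null(Cm) || is.null(Ni) || is.null(Ci) || is.null(Np)) return(NULL)
    phi_i <- dihedral(Cm, Ni, CAi, Ci) * 180 / pi
    psi_i <- dihedral(Ni, CAi, Ci, Np) * 180 / pi
    data.frame(resno = rn, phi = phi_i, psi = psi_i, pav = pav(phi_i, psi_i))
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no residue with both phi and psi defined")
  out <- do.call(rbind, rows)
  attr(out, "model_label") <- model$label
  class(out) <- c("pav_profile", "data.frame")
  out
}

#' PAV matrix across a model ensemble
#'
#' Rows = models, columns = residues shared by every profile (residues
#' missing in any model are excluded column-wise).
#'
#' @param profiles list of >= 2 `pav_profile`s (or models, converted via
#'   [pav_profile()]).
#' @return numeric matrix with residue indices as column names.
#' @export
pav_matrix <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "pav_profile")) p else pav_profile(p))
  shared <- Reduce(intersect, lapply(profiles, function(p) p$resno))
  if (length(shared) < 10) stop("fewer than 10 shared residues")
  shared <- sort(shared)
  m <- t(vapply(profiles, function(p) p$pav[match(shared, p$resno)],
                numeric(length(shared))))
  colnames(m) <- shared
  rownames(m) <- vapply(seq_along(profiles), function(i) {
    lb <- attr(profiles[[i]], "model_label")
    if (is.null(lb) || !nzchar(lb)) paste0("model", i) else lb
  }, "")
  m
}

#' PCA of PAV profiles
#'
#' Column-mean-centered principal component analysis of a models x
#' residues PAV matrix: the coordinate system in which conformational
#' families of an ensemble separate.
#'
#' @param mat matrix from [pav_matrix()].
#' @param n_components number of components to keep.
#' @return list with `scores` (models x components), `loadings`,
#'   `explained` (variance fractions, non-increasing, summing to <= 1).
#' @export
pav_pca <- function(mat, n_components = 2) {
  if (nrow(mat) < 2) stop("need at least 2 rows")
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  expl <- if (tot > 0) pc$sdev^2 / tot else rep(0, length(pc$sdev))
  k <- min(n_components, ncol(pc$x))
  list(scores = pc$x[, seq_len(k), drop = FALSE],
       loadings = pc$rotation[, seq_len(k), drop = FALSE],
       explained = expl[seq_len(k)])
}

#' Hierarchical clustering of PAV profiles
#'
#' Agglomerative clustering (average linkage, Euclidean metric by default)
#' of the rows of a PAV matrix.
#'
#' @param mat matrix from [pav_matrix()].
#' @param k number of clusters for the returned labels.
#' @param linkage linkage method passed to [stats::hclust()].
#' @return list with `tree` (hclust object) and `labels` (cluster id per
#'   row at `k`).
#' @export
pav_hcluster <- function(mat, k = 2, linkage = "average") {
  if (k > nrow(mat)) stop("k exceeds the number of models")
  tree <- stats::hclust(stats::dist(mat), method = linkage)
  list(tree = tree, labels = stats::cutree(tree, k = k))
}
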