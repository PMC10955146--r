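# Electron counts of amino-acid residues (residue = amino acid minus water,
# neutral side chains) used as coarse-grained form factors at residue level.
.residue_electrons <- c(
  GLY = 30, ALA = 38, SER = 46, PRO = 52, VAL = 54, THR = 54, CYS = 54,
  LEU = 62, ILE = 62, ASN = 60, ASP = 60, GLN = 68, GLU = 68, LYS = 70,
  MET = 70, HIS = 72, PHE = 78, ARG = 84, TYR = 86, TRP = 98)

.element_electrons <- c(H = 1, C = 6, N = 7, O = 8, S = 16, P = 15,
                        ZN = 30, FE = 26, SE = 34)

# scatterer coordinates and form factors for a model at a given level
scatterers <- function(model, level = c("residue", "atom")) {
  if (inherits(model, "bead_model")) {
    keep <- model$occupancy > 0
    return(list(xyz = model$centers[keep, , drop = FALSE],
                f = model$occupancy[keep]))
  }
  level <- match.arg(level)
  a <- model$atoms
  if (level == "residue") {
    ca <- a[a$elety == "CA", ]
    if (nrow(ca) == 0) stop("no C-alpha atoms for residue-level profile")
    f <- .residue_electrons[ca$resid]
    f[is.na(f)] <- mean(.residue_electrons)
    list(xyz = unname(as.matrix(ca[, c("x", "y", "z")])), f = unname(f))
  } else {
    f <- .element_electrons[toupper(trimws(a$elem))]
    f[is.na(f)] <- 6
    list(xyz = unname(as.matrix(a[, c("x", "y", "z")])), f = unname(f))
  }
}

# weighted pair-distance histogram: bin centers at multiples of `bin`
pair_histogram <- function(xyz, f, bin = 0.1) {
  n <- nrow(xyz)
  if (n < 2) return(list(d = numeric(0), w = numeric(0)))
  d <- as.vector(stats::dist(xyz))
  j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  i <- sequence((n - 1L):1L) + j
  w <- f[i] * f[j]
  idx <- as.integer(round(d / bin)) + 1L
  wb <- as.vector(rowsum(w, idx))
  wd <- as.vector(rowsum(w * d, idx))
  centers <- wd / wb   # weighted mean distance per bin: second-order accurate
  keep <- centers > 0
  list(d = centers[keep], w = wb[keep], w0 = sum(wb[!keep]))
}

#' Theoretical scattering profile by the Debye formula
#'
#' Computes \eqn{I(q) = \sum_i \sum_j f_i f_j \sin(q d_{ij})/(q d_{ij})}
#' for an atomic or bead model, with \eqn{\sin(0)/0 = 1}. At residue level
#' one scatterer per residue is placed at the C-alpha position with a form
#' factor equal to the residue's electron count. Pair distances are binned
#' (default 0.1 Angstrom) so the q loop scales with the number of bins, not
#' the number of pairs; the binning error is well below typical measurement
#' noise. Excluded-volume and hydration-layer contrast terms are omitted:
#' profiles are meant for relative model comparison, not absolute-scale
#' solution fitting.
#'
#' @param model `atomic_model` or `bead_model`.
#' @param q_grid momentum transfer values, \eqn{\mathrm{\AA}^{-1}}.
#' @param level `"residue"` (one scatterer per C-alpha) or `"atom"`.
#' @param bin distance bin width, Angstrom; `0` disables binning.
#' @return a [saxs_curve()] on `q_grid` (q = 0 entries allowed here and
#'   returned via the limit; such a grid is for theory only).
#' @export
debye_profile <- function(model, q_grid, level = c("residue", "atom"),
                          bin = 0.1) {
  sc <- scatterers(model, level)
  if (nrow(sc$xyz) == 0) stop("empty model")
  q <- as.numeric(q_grid)
  self_term <- sum(sc$f^2)
  if (nrow(sc$xyz) == 1) {
    I <- rep(self_term, length(q))
  } else if (bin > 0) {
    h <- pair_histogram(sc$xyz, sc$f, bin)
    qd <- outer(q, h$d)
    s <- sin(qd) / qd
    s[qd == 0] <- 1
    I <- self_term + (h$w0 %||% 0) * 2 + 2 * as.vector(s %*% h$w)
  } else {
    n <- nrow(sc$xyz)
    d <- as.vector(stats::dist(sc$xyz))
    j <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
    i <- sequence((n - 1L):1L) + j
    w <- sc$f[i] * sc$f[j]
    qd <- outer(q, d)
    s <- sin(qd) / qd
    s[qd == 0] <- 1
    I <- self_term + 2 * as.vector(s %*% w)
  }
  structure(list(q = q, I = I, sigma = NULL,
                 label = paste0("debye:", if (!is.null(model$label)) model$label else ""),
                 q_max_usable = NULL),
            class = "saxs_curve")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a calculated profile to an experimental curve
#'
#' Scales the calculated curve onto the experimental one by analytic
#' weighted least squares and reports the reduced chi-square, the package's
#' reciprocal-space validation metric. With `fit_offset = TRUE` a constant
#' background is fitted alongside the scale (2-parameter weighted linear
#' solve).
#'
#' @param calc calculated [saxs_curve()] (interpolated onto the
#'   experimental grid over the overlapping q range).
#' @param exp experimental [saxs_curve()] with `sigma`.
#' @param fit_offset also fit an additive constant.
#' @return a `fit_report` list: `chi2` (reduced), `scale`, `offset`,
#'   `n_points`, `nsd` (`NA` until filled by dual-space validation).
#' @export
fit_profile <- function(calc, exp, fit_offset = FALSE) {
  if (is.null(exp$sigma)) stop("experimental curve must carry sigma")
  qlo <- max(min(calc$q), min(exp$q))
  qhi <- min(max(calc$q), max(exp$q))
  keep <- exp$q >= qlo & exp$q <= qhi
  if (sum(keep) < 10) stop("fewer than 10 shared q points")
  qe <- exp$q[keep]; Ie <- exp$I[keep]; se <- exp$sigma[keep]
  Ic <- stats::approx(calc$q, calc$I, xout = qe)$y
  w <- 1 / se^2
  if (fit_offset) {
    fit <- stats::lm.wfit(cbind(Ic, 1), Ie, w)
    scale <- fit$coefficients[1]; offset <- fit$coefficients[2]
    resid <- Ie - scale * Ic - offset
    dof <- length(qe) - 2
  } else {
    scale <- sum(w * Ie * Ic) / sum(w * Ic^2)
    offset <- 0
    resid <- Ie - scale * Ic
    dof <- length(qe) - 1
  }
  chi2 <- sum((resid / se)^2) / dof
  structure(list(chi2 = chi2, scale = unname(scale), offset = unname(offset),
                 n_points = length(qe), nsd = NA_real_),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("fit_report: chi2 = %.3f, scale = %.4g, offset = %.4g, n = %d%s\n",
              x$chi2, x$scale, x$offset, x$n_points,
              if (is.finite(x$nsd)) sprintf(", NSD = %.3f", x$nsd) else ""))
  invisible(x)
}

#' Radius of gyration of a model from its coordinates
#'
#' @param model `atomic_model` or `bead_model`.
#' @param weights `"electrons"` (form-factor weighted; occupancy for bead
#'   models) or `"uniform"`.
#' @return Rg in Angstrom.
#' @export
model_rg <- function(model, weights = c("electrons", "uniform")) {
  weights <- match.arg(weights)
  if (weights == "electrons") {
    sc <- scatterers(model, "residue")
    xyz <- sc$xyz; w <- sc$f
  } else {
    xyz <- model_coords(model)
    w <- rep(1, nrow(xyz))
  }
  ctr <- colSums(xyz * w) / sum(w)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  sqrt(sum(w * d2) / sum(w))
}
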