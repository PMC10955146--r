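row_mins <- function(m) m[cbind(seq_len(nrow(m)), max.col(-m, ties.method = "first"))]

# mean nearest-neighbor distance within a point set
mean_nn_dist <- function(xyz) {
  if (nrow(xyz) < 2) stop("set of fewer than 2 points has no neighbor scale")
  dm <- as.matrix(stats::dist(xyz))
  diag(dm) <- Inf
  mean(row_mins(dm))
}

# squared cross nearest-neighbor distances, both directions
cross_nn2 <- function(A, B) {
  dm2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  dm2[dm2 < 0] <- 0
  list(a2b = row_mins(dm2), b2a = row_mins(t(dm2)))
}

#' Normalized spatial discrepancy between two point sets
#'
#' \deqn{NSD^2 = \frac{1}{2}\left[\frac{1}{N_1 d_2^2}\sum_i \min_j \rho^2(s_{1i}, S_2)
#'  + \frac{1}{N_2 d_1^2}\sum_j \min_i \rho^2(s_{2j}, S_1)\right]}
#' with \eqn{d_k} the mean nearest-neighbor distance within set k. Zero for
#' coinciding sets; values below 1 are typical among independent envelope
#' reconstructions of the same data, below 3 between an envelope and a
#' full-atom model.
#'
#' @param A,B n x 3 coordinate matrices (or models; coordinates extracted
#'   with [model_coords()]).
#' @return the NSD value.
#' @export
nsd_value <- function(A, B) {
  if (!is.matrix(A)) A <- model_coords(A)
  if (!is.matrix(B)) B <- model_coords(B)
  dA <- mean_nn_dist(A); dB <- mean_nn_dist(B)
  nn <- cross_nn2(A, B)
  sqrt(0.5 * (sum(nn$a2b) / (nrow(A) * dB^2) + sum(nn$b2a) / (nrow(B) * dA^2)))
}

# rotation matrix from z-y-x Euler angles
euler_rot <- function(ang) {
  ca <- cos(ang); sa <- sin(ang)
  Rz <- matrix(c(ca[1], -sa[1], 0, sa[1], ca[1], 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(ca[2], 0, sa[2], 0, 1, 0, -sa[2], 0, ca[2]), 3, byrow = TRUE)
  Rx <- matrix(c(1, 0, 0, 0, ca[3], -sa[3], 0, sa[3], ca[3]), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Superpose one model onto another by minimizing the NSD
#'
#' The search mirrors the standard envelope-superposition strategy:
#' centroid superposition, alignment of the principal (inertia) axes over
#' all proper sign combinations, the same again for the inverted (mirror)
#' copy — solution scattering cannot distinguish enantiomers — and a local
#' rotation + translation refinement (Nelder-Mead) from the best discrete
#' candidate.
#'
#' @param reference,mobile models or n x 3 coordinate matrices.
#' @param refine run the local refinement (default TRUE).
#' @param maxit Nelder-Mead iteration budget of the local refinement.
#' @return list with `nsd`, `transform` (list `R`, `t`, `inverted`:
#'   aligned = `(mobile * inv) %*% t(R) + t`), and `aligned` (the
#'   transformed mobile coordinates).
#' @export
align_nsd <- function(reference, mobile, refine = TRUE, maxit = 200) {
  A <- if (is.matrix(reference)) reference else model_coords(reference)
  B <- if (is.matrix(mobile)) mobile else model_coords(mobile)
  if (nrow(A) < 2 || nrow(B) < 2) stop("need at least 2 points per model")
  cA <- colMeans(A); cB <- colMeans(B)
  A0 <- sweep(A, 2, cA); B0 <- sweep(B, 2, cB)
  PA <- svd(A0)$v; PB <- svd(B0)$v
  best <- NULL
  for (inv in c(1, -1)) {
    Bi <- B0 * inv
    PBi <- svd(Bi)$v
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
      s3 <- s1 * s2 * sign(det(PA) * det(PBi))  # keep the rotation proper
      R <- PA %*% diag(c(s1, s2, s3)) %*% t(PBi)
      if (det(R) < 0) next
      val <- nsd_value(A0, Bi %*% t(R))
      if (is.null(best) || val < best$nsd)
        best <- list(nsd = val, R = R, inv = inv)
    }
  }
  if (refine) {
    Bi <- B0 * best$inv
    obj <- function(par) {
      R <- euler_rot(par[1:3]) %*% best$R
      nsd_value(A0, sweep(Bi %*% t(R), 2, par[4:6], "+"))
    }
    opt <- stats::optim(rep(0, 6), obj, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-6))
    if (opt$value < best$nsd) {
      best$nsd <- opt$value
      best$R <- euler_rot(opt$par[1:3]) %*% best$R
      best$shift <- opt$par[4:6]
    }
  }
  shift <- best$shift %||% c(0, 0, 0)
  R <- best$R
  t_full <- cA + shift - as.vector(R %*% (cB * best$inv))
  aligned <- sweep((B * best$inv) %*% t(R), 2, t_full, "+")
  list(nsd = best$nsd,
       transform = list(R = R, t = t_full, inverted = best$inv == -1),
       aligned = aligned)
}

#' Average a set of envelope reconstructions
#'
#' All models are aligned onto the one with the lowest mean NSD to the
#' others; models whose mean NSD exceeds mean + 2 SD are excluded as
#' outliers. Aligned beads are snapped onto the reference lattice, giving a
#' per-site occupancy in `[0, 1]` (fraction of models placing a bead
#' there); the volume-corrected averaged model keeps the top-occupancy
#' sites, cut so its volume matches the median input-model volume.
#'
#' @param models list of >= 2 `bead_model`s from [anneal_beads()].
#' @return list with `model` (volume-corrected `bead_model`, carrying
#'   lattice attributes for [refine_beads()]), `occupancy_model` (all
#'   touched sites, occupancy-weighted), `mean_nsd` (mean pairwise NSD of
#'   kept models), `pairwise_nsd` (matrix), `excluded` (indices).
#' @export
average_models <- function(models) {
  n <- length(models)
  if (n < 2) stop("need at least 2 models")
  P <- matrix(0, n, n)
  tf <- vector("list", n * n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- align_nsd(models[[i]], models[[j]], maxit = 80)
    P[i, j] <- P[j, i] <- al$nsd
    tf[[(i - 1) * n + j]] <- al
  }
  mean_nsd_i <- rowSums(P) / (n - 1)
  keep <- mean_nsd_i <= mean(mean_nsd_i) + 2 * stats::sd(mean_nsd_i)
  if (sum(keep) < 2) keep <- rep(TRUE, n)
  ref <- which(keep)[which.min(mean_nsd_i[keep])]
  sites <- attr(models[[ref]], "lattice_sites")
  if (is.null(sites)) stop("models must carry lattice_sites (from anneal_beads)")
  spacing <- 2 * models[[ref]]$bead_radius
  hits <- matrix(0, nrow(sites), sum(keep))
  col <- 0
  for (j in which(keep)) {
    col <- col + 1
    pts <- if (j == ref) models[[j]]$centers else {
      al <- if (j > ref) tf[[(ref - 1) * n + j]] else NULL
      if (!is.null(al)) al$aligned else align_nsd(models[[ref]], models[[j]])$aligned
    }
    d2 <- outer(rowSums(sites^2), rowSums(pts^2), "+") - 2 * sites %*% t(pts)
    nearest <- apply(d2, 2, which.min)
    ok <- sqrt(pmax(d2[cbind(nearest, seq_along(nearest))], 0)) <= 0.75 * spacing
    hits[unique(nearest[ok]), col] <- 1
  }
  occupancy <- rowMeans(hits)
  touched <- occupancy > 0
  occ_model <- bead_model(sites[touched, , drop = FALSE],
                          models[[ref]]$bead_radius,
                          occupancy = occupancy[touched],
                          label = "occupancy-weighted average")
  n_target <- round(stats::median(vapply(models[keep], function(m)
    nrow(m$centers), 0)))
  ord <- order(occupancy, decreasing = TRUE)
  sel_sites <- ord[seq_len(min(n_target, sum(touched)))]
  sel <- logical(nrow(sites)); sel[sel_sites] <- TRUE
  avg <- bead_model(sites[sel, , drop = FALSE], models[[ref]]$bead_radius,
                    label = "volume-corrected average")
  attr(avg, "lattice_sites") <- sites
  attr(avg, "occupied") <- sel
  attr(avg, "occupancy_map") <- occupancy
  off <- P[keep, keep]
  list(model = avg, occupancy_model = occ_model,
       mean_nsd = mean(off[upper.tri(off)]), pairwise_nsd = P,
       excluded = which(!keep))
}
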