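# Kabsch least-squares superposition: rotation/translation mapping B onto A
kabsch <- function(A, B) {
  cA <- colMeans(A); cB <- colMeans(B)
  H <- crossprod(sweep(B, 2, cB), sweep(A, 2, cA))
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cA - as.vector(R %*% cB)
  list(R = R, t = t_vec)
}

apply_kabsch <- function(tf, X) sweep(X %*% t(tf$R), 2, tf$t, "+")

#' Dual-space validation of an atomic model
#'
#' The two validation metrics used throughout the pipeline: the reduced
#' chi-square of the model's Debye profile against the experimental curve
#' (reciprocal space) and the normalized spatial discrepancy between the
#' envelope beads and the model's C-alpha set (direct space). A good
#' full-atom model fits with chi-square near 1 and NSD below 3 against its
#' envelope.
#'
#' @param model an `atomic_model`.
#' @param curve experimental [saxs_curve()] with `sigma`.
#' @param envelope a `bead_model`.
#' @return a `fit_report` with the `nsd` slot filled.
#' @export
validate_dual <- function(model, curve, envelope) {
  calc <- debye_profile(model, curve$q)
  rep <- fit_profile(calc, curve)
  rep$nsd <- align_nsd(envelope, model_coords(model))$nsd
  rep
}

#' Splice two overlapping construct models into one
#'
#' Superposes model B onto model A by Kabsch least squares over the
#' C-alpha atoms of the shared residue range (the "lever arm"), then takes
#' A's residues over `take_from_A` and transformed B's residues over
#' `take_from_B`. Junction geometry is sanity-checked: consecutive C-alpha
#' distances at the splice points must fall in 2.9 to 4.1 Angstrom
#' (cis/trans peptide adjacency); violations are reported, not fatal.
#'
#' @param modelA,modelB `atomic_model`s with overlapping residue numbering.
#' @param overlap_range integer residue range present in both models.
#' @param take_from_A,take_from_B integer residue sets partitioning the
#'   output sequence.
#' @return an `atomic_model` with
#'   `attr(, "junctions")` = data.frame of junction C-alpha distances and
#'   an `ok` flag, and `attr(, "overlap_rmsd")` (C-alpha RMSD over the
#'   lever arm after superposition).
#' @export
splice_models <- function(modelA, modelB, overlap_range, take_from_A,
                          take_from_B) {
  if (length(intersect(take_from_A, take_from_B)) > 0)
    stop("take ranges overlap: residue-numbering conflict")
  ovl <- sort(overlap_range)
  caA <- modelA$atoms[modelA$atoms$elety == "CA", ]
  caB <- modelB$atoms[modelB$atoms$elety == "CA", ]
  shared <- intersect(intersect(ovl, caA$resno), caB$resno)
  if (length(shared) < 10) stop("overlap of fewer than 10 residues")
  XA <- as.matrix(caA[match(shared, caA$resno), c("x", "y", "z")])
  XB <- as.matrix(caB[match(shared, caB$resno), c("x", "y", "z")])
  tf <- kabsch(XA, XB)
  rmsd_ovl <- sqrt(mean(rowSums((apply_kabsch(tf, XB) - XA)^2)))
  partA <- modelA$atoms[modelA$atoms$resno %in% take_from_A, ]
  partB <- modelB$atoms[modelB$atoms$resno %in% take_from_B, ]
  if (nrow(partB) > 0) {
    xyzB <- apply_kabsch(tf, as.matrix(partB[, c("x", "y", "z")]))
    partB$x <- xyzB[, 1]; partB$y <- xyzB[, 2]; partB$z <- xyzB[, 3]
  }
  out <- rbind(partA, partB)
  out <- out[order(out$resno), ]
  m <- atomic_model(out, hetero = modelA$hetero,
                    label = "spliced model")
  ca <- out[out$elety == "CA", ]
  dca <- sqrt(rowSums(diff(as.matrix(ca[, c("x", "y", "z")]))^2))
  step1 <- diff(ca$resno) == 1
  # junctions: consecutive residues drawn from different source models
  srcA <- ca$resno %in% take_from_A
  junction <- step1 & (srcA[-length(srcA)] != srcA[-1])
  jd <- data.frame(resno = ca$resno[-1][junction], ca_dist = dca[junction],
                   ok = dca[junction] >= 2.9 & dca[junction] <= 4.1)
  attr(m, "junctions") <- jd
  attr(m, "overlap_rmsd") <- rmsd_ovl
  m
}

#' Combine two construct envelopes into one restraint map
#'
#' Each envelope is aligned (by NSD) onto the C-alpha set of its
#' corresponding residue range of the full model, both are rasterized onto
#' one common grid, and the maps are merged by voxel-wise maximum — the
#' union density used as a single flexible-fitting restraint when two
#' overlapping constructs were measured separately.
#'
#' @param envA,envB `bead_model`s.
#' @param model the full-length `atomic_model` covering both ranges.
#' @param rangeA,rangeB integer residue ranges the envelopes correspond to.
#' @param voxel grid voxel, Angstrom.
#' @return a [density_grid()].
#' @export
combine_envelopes <- function(envA, envB, model, rangeA, rangeB, voxel = 3) {
  ca <- model$atoms[model$atoms$elety == "CA", ]
  ptsA <- as.matrix(ca[ca$resno %in% rangeA, c("x", "y", "z")])
  ptsB <- as.matrix(ca[ca$resno %in% rangeB, c("x", "y", "z")])
  if (nrow(ptsA) < 3 || nrow(ptsB) < 3) stop("model does not cover the ranges")
  alA <- align_nsd(ptsA, envA)
  alB <- align_nsd(ptsB, envB)
  mA <- bead_model(alA$aligned, envA$bead_radius, occupancy = envA$occupancy, tol = 2)
  mB <- bead_model(alB$aligned, envB$bead_radius, occupancy = envB$occupancy, tol = 2)
  sigma <- max(envA$bead_radius, envB$bead_radius)
  pad <- 3 * sigma
  allpts <- rbind(alA$aligned, alB$aligned)
  lo <- apply(allpts, 2, min) - pad
  hi <- apply(allpts, 2, max) + pad
  dim3 <- pmax(ceiling((hi - lo) / voxel) + 1, 2)
  gA <- bead_density(mA, voxel = voxel, kernel_sigma = sigma,
                     bbox = list(origin = lo, dim = dim3))
  gB <- bead_density(mB, voxel = voxel, kernel_sigma = sigma,
                     bbox = list(origin = lo, dim = dim3))
  density_grid(lo, voxel, pmax(gA$values, gB$values))
}

#' Envelope-restrained flexible fitting of a C-alpha model
#'
#' A deterministic, coarse-grained counterpart of density-restrained
#' molecular dynamics fitting: gradient descent with backtracking line
#' search on
#' \deqn{U = -w \sum_i \rho(x_i) + k_{bond}\sum_i (|x_{i+1}-x_i| - 3.8)^2
#'  + k_{dom}\sum_{domains} |x - \hat{x}_{ref}|^2 + \sum_{Zn} k (|x_i-x_j| - r_0)^2}
#' where \eqn{\rho} is the trilinear-interpolated map density (analytic
#' gradient), virtual C-alpha bonds keep the chain connected, and each
#' rigid domain is tethered to its reference coordinates after optimal
#' superposition (recomputed every step), the surrogate of targeted MD.
#' The map weight `w` is auto-scaled so the map force magnitude matches the
#' bond force magnitude at step 0. `k_dom = Inf` freezes domains exactly
#' (rigid-body projection each step). Zn-site restraints default to the
#' metal-coordination convention: spring constant 50 energy units per
#' square Angstrom and reference distance 2.5 Angstrom.
#'
#' @param model C-alpha level `atomic_model`.
#' @param grid target [density_grid()].
#' @param rigid_domains list of integer residue-index vectors (positions in
#'   the C-alpha chain) held near their starting geometry.
#' @param zn_restraints optional data.frame with columns `i`, `j` (C-alpha
#'   chain positions), and optionally `k` (default 50), `r0` (default 2.5).
#' @param steps number of descent steps.
#' @param step_size initial step, Angstrom per unit force.
#' @param k_bond,k_dom force constants (energy units per square Angstrom).
#' @param w map weight; `NULL` = auto-scale.
#' @param cap_frac the map potential saturates at this fraction of the
#'   density maximum, so atoms already inside well-covered density feel no
#'   map force (the standard trick that keeps fitted regions undistorted).
#' @param kernel_sigma rasterization sigma for the CORR metric.
#' @return list with `model` (refined), `trajectory` (data.frame of per-step
#'   `energy`, `corr`, `rmsd_to_start`), `w`.
#' @export
flexfit <- function(model, grid, rigid_domains = list(), zn_restraints = NULL,
                    steps = 100, step_size = 0.5, k_bond = 10, k_dom = 10,
                    w = NULL, cap_frac = 0.5, kernel_sigma = NULL) {
  grid_fit <- grid
  grid_fit$values <- pmin(grid$values, cap_frac * max(grid$values))
  X0 <- model_coords(model)
  n <- nrow(X0)
  X <- X0
  d0 <- 3.8
  # virtual bonds: consecutive C-alpha pairs at plausible adjacency in the
  # start model; longer pairs are chain breaks and carry no bond
  bonded <- sqrt(rowSums(diff(X0)^2)) <= 4.5
  frozen <- identical(k_dom, Inf)
  refs <- lapply(rigid_domains, function(ii) X0[ii, , drop = FALSE])
  if (!is.null(zn_restraints)) {
    if (is.null(zn_restraints$k)) zn_restraints$k <- 50
    if (is.null(zn_restraints$r0)) zn_restraints$r0 <- 2.5
  }
  energy_grad <- function(X) {
    di <- density_interp(grid_fit, X)
    U_map <- -sum(di$value)
    G_map <- -di$grad
    dX <- diff(X)
    len <- sqrt(rowSums(dX^2))
    dev <- ifelse(bonded, len - d0, 0)
    U_bond <- k_bond * sum(dev^2)
    unit <- dX / pmax(len, 1e-9)
    f <- 2 * k_bond * dev * unit
    G_bond <- matrix(0, n, 3)
    G_bond[-n, ] <- G_bond[-n, , drop = FALSE] - f
    G_bond[-1, ] <- G_bond[-1, , drop = FALSE] + f
    U_dom <- 0
    G_dom <- matrix(0, n, 3)
    if (!frozen && k_dom > 0) {
      for (k in seq_along(rigid_domains)) {
        ii <- rigid_domains[[k]]
        tf <- kabsch(X[ii, , drop = FALSE], refs[[k]])
        tgt <- apply_kabsch(tf, refs[[k]])
        dd <- X[ii, , drop = FALSE] - tgt
        U_dom <- U_dom + k_dom * sum(dd^2)
        G_dom[ii, ] <- G_dom[ii, , drop = FALSE] + 2 * k_dom * dd
      }
    }
    U_zn <- 0
    G_zn <- matrix(0, n, 3)
    if (!is.null(zn_restraints)) {
      for (r in seq_len(nrow(zn_restraints))) {
        i <- zn_restraints$i[r]; j <- zn_restraints$j[r]
        v <- X[i, ] - X[j, ]
        L <- sqrt(sum(v^2))
        dev <- L - zn_restraints$r0[r]
        U_zn <- U_zn + zn_restraints$k[r] * dev^2
        g <- 2 * zn_restraints$k[r] * dev * v / max(L, 1e-9)
        G_zn[i, ] <- G_zn[i, ] + g
        G_zn[j, ] <- G_zn[j, ] - g
      }
    }
    list(U = list(map = U_map, bond = U_bond, dom = U_dom, zn = U_zn),
         G = list(map = G_map, other = G_bond + G_dom + G_zn))
  }
  eg <- energy_grad(X)
  if (is.null(w)) {
    # scale the map force so it matches the force of a half-Angstrom bond
    # stretch: strong enough to move domains, weak enough not to shred them
    gm <- sqrt(rowSums(eg$G$map^2))
    fm <- mean(gm[gm > 0])
    w <- if (is.finite(fm) && fm > 0) k_bond / fm else 1
  }
  total_U <- function(eg) w * eg$U$map + eg$U$bond + eg$U$dom + eg$U$zn
  project_frozen <- function(X) {
    for (k in seq_along(rigid_domains)) {
      ii <- rigid_domains[[k]]
      tf <- kabsch(X[ii, , drop = FALSE], refs[[k]])
      X[ii, ] <- apply_kabsch(tf, refs[[k]])
    }
    X
  }
  if (frozen) X <- project_frozen(X)
  eg <- energy_grad(X)
  U <- total_U(eg)
  eta <- step_size
  traj <- data.frame(step = integer(0), energy = numeric(0),
                     corr = numeric(0), rmsd_to_start = numeric(0))
  record <- function(s, U, X) {
    cr <- tryCatch(density_corr(grid, X, kernel_sigma = kernel_sigma),
                   error = function(e) NA_real_)
    rbind(traj, data.frame(step = s, energy = U, corr = cr,
                           rmsd_to_start = sqrt(mean(rowSums((X - X0)^2)))))
  }
  traj <- record(0L, U, X)
  for (s in seq_len(steps)) {
    G <- w * eg$G$map + eg$G$other
    if (any(!is.finite(G))) stop("non-finite gradient at step ", s)
    accepted <- FALSE
    for (bt in 1:20) {
      Xn <- X - eta * G
      if (frozen) Xn <- project_frozen(Xn)
      egn <- energy_grad(Xn)
      Un <- total_U(egn)
      if (is.finite(Un) && Un <= U) { accepted <- TRUE; break }
      eta <- eta / 2
    }
    if (!accepted) break
    X <- Xn; eg <- egn; U <- Un
    eta <- min(eta * 1.2, step_size * 4)
    traj <- record(s, U, X)
  }
  atoms <- model$atoms
  ca_idx <- which(atoms$elety == "CA")
  atoms$x[ca_idx] <- X[, 1]; atoms$y[ca_idx] <- X[, 2]; atoms$z[ca_idx] <- X[, 3]
  out <- atomic_model(atoms[ca_idx, , drop = FALSE], label = "flexfit refined")
  list(model = out, trajectory = traj, w = w)
}

#' Pearson correlation between loaded concentration and usable q range
#'
#' The simple diagnostic of whether higher loading concentration buys
#' signal: the Pearson correlation between the concentration loaded on the
#' column and the maximum usable momentum transfer of the resulting
#' dataset.
#'
#' @param table data.frame with columns `concentration` and `qmax` (or any
#'   two-column numeric table).
#' @return the Pearson correlation coefficient.
#' @export
concentration_qmax_correlation <- function(table) {
  x <- table[[if ("concentration" %in% names(table)) "concentration" else 1]]
  y <- table[[if ("qmax" %in% names(table)) "qmax" else 2]]
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  stats::cor(x, y)
}

#' SEC-SAXS dataset summary table of the NSD3 C-terminal constructs
#'
#' Per-dataset parameters of the eight SEC-SAXS datasets measured on the
#' two NSD3 C-terminal constructs (loaded concentration, usable q_max
#' before and after re-binning, Guinier and real-space Rg, Dmax, estimated
#' MW), shipped as a plain-text fixture for examples and reference checks.
#'
#' @return data.frame, one row per dataset.
#' @export
nsd3_dataset_table <- function() {
  utils::read.csv(system.file("extdata", "nsd3_secsaxs_table.csv",
                              package = "saxstruct"),
                  stringsAsFactors = FALSE)
}
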