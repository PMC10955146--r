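# shared fixture builders; everything is generated in code, seeded

# analytic sphere curve with multiplicative noise plus an absolute floor
# (the floor keeps the deep form-factor minima from getting infinite weight)
sphere_curve <- function(R = 30, noise = 0.01, seed = 1, n = 512) {
  so <- sphere_oracles(R)
  qg <- default_q_grid(n)
  s <- noise * so$I(qg) + noise * 1e-2
  set.seed(seed)
  saxs_curve(qg, so$I(qg) + rnorm(n, sd = s), s, label = "sphere fixture")
}

# C-alpha chain with full N/CA/C backbone from a compact random walk
random_backbone <- function(n_res = 12, seed = 1, step = c(1.2, 0.2, -0.1),
                            jitter = 0.3) {
  set.seed(seed)
  xyz <- matrix(0, 3 * n_res, 3)
  pos <- c(0, 0, 0)
  for (i in seq_len(3 * n_res)) {
    pos <- pos + step + rnorm(3, sd = jitter)
    xyz[i, ] <- pos
  }
  atomic_model(data.frame(
    resno = rep(seq_len(n_res), each = 3), resid = "ALA",
    elety = rep(c("N", "CA", "C"), n_res), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    elem = rep(c("N", "C", "C"), n_res)))
}

# dumbbell truth + a copy with domain 2 rotated about the linker midpoint
perturbed_dumbbell <- function(angle_deg = 30) {
  db <- toy_preset("dumbbell")
  tr <- attr(db, "truth")
  X <- model_coords(db)
  n <- nrow(X)
  rngs <- lapply(tr$domain_ranges, function(r) r[1]:r[2])
  d2 <- rngs[[2]]
  linker <- setdiff(seq_len(n), c(rngs[[1]], d2))
  hinge <- colMeans(X[linker, , drop = FALSE])
  th <- angle_deg * pi / 180
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  Xp <- X
  Xp[d2, ] <- sweep(sweep(X[d2, ], 2, hinge) %*% t(Rz), 2, hinge, "+")
  pert <- atomic_model(data.frame(
    resno = seq_len(n), resid = "ALA", elety = "CA", chain = "A",
    x = Xp[, 1], y = Xp[, 2], z = Xp[, 3], elem = "C"))
  list(truth = db, perturbed = pert, X = X, Xp = Xp, domains = rngs)
}

rmsd <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

# mean buffer intensities over given frame indices (frames x q matrix rows)
series_matrix_for_tests <- function(series, frames) {
  m <- do.call(rbind, lapply(series$frames, function(f) f$I))
  m[match(frames, series$frame_index), , drop = FALSE]
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, byrow = TRUE)
}
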