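test_that("Kabsch superposition matches a quaternion-method oracle", {
  # quaternion (Horn) absolute-orientation oracle
  horn <- function(A, B) {
    cA <- colMeans(A); cB <- colMeans(B)
    M <- crossprod(sweep(B, 2, cB), sweep(A, 2, cA))
    S <- matrix(0, 4, 4)
    tr <- sum(diag(M))
    S[1, 1] <- tr
    S[1, 2:4] <- S[2:4, 1] <- c(M[2, 3] - M[3, 2], M[3, 1] - M[1, 3],
                                M[1, 2] - M[2, 1])
    for (i in 1:3) for (j in 1:3)
      S[i + 1, j + 1] <- M[i, j] + M[j, i] - (i == j) * tr
    qv <- eigen(S, symmetric = TRUE)$vectors[, 1]
    w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
    matrix(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2),
           3, byrow = TRUE)
  }
  for (seed in 1:5) {
    set.seed(seed)
    A <- matrix(rnorm(45, sd = 10), 15, 3)
    B <- matrix(rnorm(45, sd = 10), 15, 3)
    tf <- saxstruct:::kabsch(A, B)
    Rh <- horn(A, B)
    res_k <- sum((saxstruct:::apply_kabsch(tf, B) - A)^2)
    ch <- colMeans(A) - as.vector(Rh %*% colMeans(B))
    res_h <- sum((sweep(B %*% t(Rh), 2, ch, "+") - A)^2)
    expect_equal(res_k, res_h, tolerance = 1e-9)
    expect_equal(det(tf$R), 1, tolerance = 1e-9)
  }
})

test_that("splice_models is exact for identical and rigidly moved inputs", {
  db <- toy_preset("dumbbell")
  X <- model_coords(db)
  n <- nrow(X)
  same <- splice_models(db, db, overlap_range = 200:300,
                        take_from_A = 1:250, take_from_B = 251:n)
  expect_equal(model_coords(same), X, tolerance = 1e-10)
  # B = rigid copy of A
  at <- db$atoms
  xyz <- sweep(X %*% t(rotation_z(25)), 2, c(10, 5, -2), "+")
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  mB <- atomic_model(at)
  sp <- splice_models(db, mB, overlap_range = 200:300,
                      take_from_A = 1:250, take_from_B = 251:n)
  expect_lt(rmsd(model_coords(sp), X), 1e-3)
  expect_lt(attr(sp, "overlap_rmsd"), 1e-6)
  jd <- attr(sp, "junctions")
  expect_true(all(jd$ok))
  expect_error(splice_models(db, mB, overlap_range = 200:204,
                             take_from_A = 1:250, take_from_B = 251:n),
               "fewer than 10")
  expect_error(splice_models(db, mB, overlap_range = 200:300,
                             take_from_A = 1:250, take_from_B = 250:n),
               "conflict")
})

test_that("splicing two independently perturbed halves stays near the truth", {
  db <- toy_preset("dumbbell")
  X <- model_coords(db)
  n <- nrow(X)
  rngs <- lapply(attr(db, "truth")$domain_ranges, function(r) r[1]:r[2])
  perturb <- function(idx, sd, seed) {
    set.seed(seed)
    at <- db$atoms
    at[idx, c("x", "y", "z")] <- at[idx, c("x", "y", "z")] +
      matrix(rnorm(3 * length(idx), sd = sd), ncol = 3)
    atomic_model(at)
  }
  ovl <- 230:280                      # shared central region, kept clean
  mA <- perturb(setdiff(rngs[[2]], ovl), 2, 1)   # A corrupted away from its half
  mB <- perturb(setdiff(rngs[[1]], ovl), 2, 2)
  sp <- splice_models(mA, mB, overlap_range = ovl,
                      take_from_A = 1:255, take_from_B = 256:n)
  expect_lt(rmsd(model_coords(sp), X), 2)
})

test_that("validate_dual: exact self-fit and monotone degradation", {
  m <- toy_preset("sphere")
  q <- default_q_grid(128)
  calc <- debye_profile(m, q)
  cv <- saxs_curve(q, calc$I, 0.01 * calc$I + 1e-4 * max(calc$I))
  env <- bead_model(fill_shape("sphere", radius = 30, spacing = 8), 4, tol = 2)
  rep0 <- validate_dual(m, cv, env)
  expect_lt(rep0$chi2, 1e-10)
  expect_lt(rep0$nsd, 3)
  # corrupt half the residues by 30 A: both metrics must increase
  set.seed(3)
  at <- m$atoms
  idx <- sample(nrow(at), nrow(at) %/% 2)
  at[idx, c("x", "y", "z")] <- at[idx, c("x", "y", "z")] +
    matrix(rnorm(3 * length(idx), sd = 30 / sqrt(3)), ncol = 3)
  bad <- atomic_model(at)
  rep1 <- validate_dual(bad, cv, env)
  expect_gt(rep1$chi2, rep0$chi2)
  expect_gt(rep1$nsd, rep0$nsd)
})

test_that("combine_envelopes covers both lobes and dominates each input", {
  db <- toy_preset("dumbbell")
  rngs <- lapply(attr(db, "truth")$domain_ranges, function(r) r[1]:r[2])
  e1 <- bead_model(fill_shape("sphere", radius = 15, spacing = 6), 3, tol = 2)
  e2 <- bead_model(sweep(fill_shape("sphere", radius = 15, spacing = 6),
                         2, c(3, 1, 0), "+"), 3, tol = 2)
  g12 <- combine_envelopes(e1, e2, db, rngs[[1]], rngs[[2]])
  g21 <- combine_envelopes(e2, e1, db, rngs[[2]], rngs[[1]])
  # commutative up to the alignment's stochastic-free determinism
  expect_equal(dim(g12$values), dim(g21$values))
  expect_gt(density_corr(g12, db), 0.9)
  # voxel-wise max dominates each rasterized input
  X <- model_coords(db)
  ca1 <- X[rngs[[1]], , drop = FALSE]
  al1 <- align_nsd(ca1, e1)
  m1 <- bead_model(al1$aligned, 3, occupancy = e1$occupancy, tol = 2)
  r1 <- bead_density(m1, voxel = 3, kernel_sigma = 3,
                     bbox = list(origin = g12$origin, dim = dim(g12$values)))
  expect_true(all(g12$values - r1$values > -1e-9))
})

test_that("flexfit is stationary at the generating structure", {
  fix <- perturbed_dumbbell()
  grid <- bead_density(bead_model(fix$X, bead_radius = 4, tol = 2),
                       voxel = 3, kernel_sigma = 4)
  ff <- flexfit(fix$truth, grid, rigid_domains = fix$domains, steps = 15,
                kernel_sigma = 4)
  expect_lt(max(ff$trajectory$rmsd_to_start), 0.5)
  expect_gt(ff$trajectory$corr[1], 0.99)
  # energy is non-increasing over accepted steps
  expect_true(all(diff(ff$trajectory$energy) <= 1e-9))
})

test_that("flexfit recovers a rotated domain: CORR rises, RMSD-to-truth halves", {
  fix <- perturbed_dumbbell(30)
  grid <- bead_density(bead_model(fix$X, bead_radius = 4, tol = 2),
                       voxel = 3, kernel_sigma = 4)
  ff <- flexfit(fix$perturbed, grid, rigid_domains = fix$domains,
                steps = 150, kernel_sigma = 4)
  tr <- ff$trajectory
  expect_gt(tr$corr[nrow(tr)], tr$corr[1])
  rmsd0 <- rmsd(fix$Xp, fix$X)
  rmsd1 <- rmsd(model_coords(ff$model), fix$X)
  expect_lt(rmsd1, 0.5 * rmsd0)
})

test_that("flexfit with frozen domains moves domains rigidly only", {
  fix <- perturbed_dumbbell(20)
  grid <- bead_density(bead_model(fix$X, bead_radius = 4, tol = 2),
                       voxel = 3, kernel_sigma = 4)
  ff <- flexfit(fix$perturbed, grid, rigid_domains = fix$domains,
                steps = 25, k_dom = Inf, kernel_sigma = 4)
  Xf <- model_coords(ff$model)
  for (ii in fix$domains) {
    tf <- saxstruct:::kabsch(Xf[ii, , drop = FALSE], fix$Xp[ii, , drop = FALSE])
    intra <- rmsd(saxstruct:::apply_kabsch(tf, fix$Xp[ii, , drop = FALSE]),
                  Xf[ii, , drop = FALSE])
    expect_lt(intra, 0.1)
  }
  # inter-domain geometry did change
  expect_gt(rmsd(Xf, fix$Xp), 0.5)
})

test_that("flexfit honors harmonic metal-site restraints", {
  fix <- perturbed_dumbbell(10)
  grid <- bead_density(bead_model(fix$X, bead_radius = 4, tol = 2),
                       voxel = 3, kernel_sigma = 4)
  n <- nrow(fix$Xp)
  zn <- data.frame(i = c(10, 40), j = c(25, 60))
  ff <- flexfit(fix$perturbed, grid, rigid_domains = list(), zn_restraints = zn,
                steps = 60, k_bond = 1, kernel_sigma = 4)
  Xf <- model_coords(ff$model)
  d <- sqrt(rowSums((Xf[zn$i, ] - Xf[zn$j, ])^2))
  d0 <- sqrt(rowSums((fix$Xp[zn$i, ] - fix$Xp[zn$j, ])^2))
  # restrained pairs pulled toward the 2.5 A reference distance
  expect_true(all(abs(d - 2.5) < abs(d0 - 2.5)))
})

test_that("density cross-correlation: self, outside support, linear rescale", {
  db <- toy_preset("dumbbell")
  X <- model_coords(db)
  grid <- bead_density(bead_model(X, bead_radius = 4, tol = 2),
                       voxel = 3, kernel_sigma = 4)
  expect_gt(density_corr(grid, X, kernel_sigma = 4), 0.999)
  expect_lt(abs(density_corr(grid, X + 500, kernel_sigma = 4)), 0.05)
  g2 <- grid; g2$values <- grid$values * 3.7
  expect_equal(density_corr(g2, X, kernel_sigma = 4),
               density_corr(grid, X, kernel_sigma = 4), tolerance = 1e-12)
  flat <- grid; flat$values[] <- 1
  expect_error(density_corr(flat, X, kernel_sigma = 4), "zero-variance")
})

test_that("concentration/qmax Pearson: exact lines and sign", {
  expect_equal(concentration_qmax_correlation(
    data.frame(concentration = 1:5, qmax = 2 * (1:5) + 3)), 1)
  expect_equal(concentration_qmax_correlation(
    data.frame(concentration = 1:5, qmax = -(1:5))), -1)
  expect_error(concentration_qmax_correlation(
    data.frame(concentration = c(1, 1, 1), qmax = 1:3)), "zero variance")
  expect_error(concentration_qmax_correlation(
    data.frame(concentration = 1:2, qmax = 1:2)), "at least 3")
})
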