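# a small, fast annealing problem: sphere target with a coarse lattice
small_sphere_problem <- function(seed = 1) {
  cv <- sphere_curve(24, noise = 0.01, seed = seed, n = 256)
  list(curve = cv, dmax = 48, bead_radius = 4)
}

test_that("annealing reconstructs a sphere: Rg, NSD to ideal, determinism", {
  pb <- small_sphere_problem()
  runs <- anneal_beads(pb$curve, pb$dmax, n_runs = 2, seed = 3,
                       bead_radius = pb$bead_radius)
  ideal <- bead_model(fill_shape("sphere", radius = 24, spacing = 7), 3.5,
                      tol = 2)
  for (r in runs) {
    expect_equal(model_rg(r, "uniform"), sqrt(3 / 5) * 24, tolerance = 0.05)
    expect_lt(align_nsd(ideal, r)$nsd, 1.0)
    fit <- attr(r, "fit")
    expect_lte(fit$energy_final, fit$energy_initial)
    expect_equal(fit$disconnected, 0)
  }
  # fixed seed gives a bit-identical reconstruction
  again <- anneal_beads(pb$curve, pb$dmax, n_runs = 2, seed = 3,
                        bead_radius = pb$bead_radius)
  expect_identical(runs[[1]]$centers, again[[1]]$centers)
  expect_identical(runs[[2]]$centers, again[[2]]$centers)
})

test_that("annealing rejects a Dmax smaller than four bead diameters", {
  pb <- small_sphere_problem()
  expect_error(anneal_beads(pb$curve, 20, bead_radius = 4), "4 bead diameters")
})

test_that("NSD: identity, symmetry, rigid-motion invariance, exhaustive oracle", {
  set.seed(8)
  # an anisotropic shape: principal axes are well defined, so the
  # axis-alignment search can undo an arbitrary rigid motion
  A <- fill_shape("ellipsoid", semiaxes = c(16, 10, 6), spacing = 5)
  expect_equal(nsd_value(A, A), 0)
  B <- sweep(A %*% t(rotation_z(37)), 2, c(8, -4, 11), "+")
  al <- align_nsd(A, B)
  expect_lt(al$nsd, 0.01)
  # symmetry of the underlying discrepancy
  C <- A + matrix(rnorm(length(A), sd = 1), nrow(A), 3)
  expect_equal(nsd_value(A, C), nsd_value(C, A))
  expect_error(align_nsd(matrix(0, 1, 3), A), "2 points")

  # exhaustive oracle on two unit cubes, one vertex displaced:
  # centered sets compared over the discrete candidate space
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cube2 <- cube
  cube2[8, ] <- cube2[8, ] + c(1, 0, 0)
  val <- nsd_value(scale(cube, scale = FALSE), scale(cube2, scale = FALSE))
  # direct evaluation of the NSD formula by brute force
  d1 <- mean(apply(`diag<-`(as.matrix(dist(cube)), Inf), 1, min))
  d2 <- mean(apply(`diag<-`(as.matrix(dist(cube2)), Inf), 1, min))
  cA <- scale(cube, scale = FALSE); cB <- scale(cube2, scale = FALSE)
  dm <- as.matrix(dist(rbind(cA, cB)))[1:8, 9:16]
  brute <- sqrt(0.5 * (sum(apply(dm, 1, min)^2) / (8 * d2^2) +
                       sum(apply(dm, 2, min)^2) / (8 * d1^2)))
  expect_equal(val, brute, tolerance = 1e-12)
  # the search cannot do worse than the identity candidate
  expect_lte(align_nsd(cube, cube2)$nsd, brute + 1e-9)
})

test_that("averaging keeps identical models intact and reports volumes", {
  pb <- small_sphere_problem()
  runs <- anneal_beads(pb$curve, pb$dmax, n_runs = 1, seed = 5,
                       bead_radius = pb$bead_radius)
  five <- rep(runs[1], 5)
  avg <- average_models(five)
  expect_equal(avg$mean_nsd, 0, tolerance = 1e-6)
  expect_equal(sort(avg$occupancy_model$occupancy), rep(1, nrow(runs[[1]]$centers)))
  expect_equal(nrow(avg$model$centers), nrow(runs[[1]]$centers))
  # volume within one bead volume of the median input volume
  expect_lte(abs(bead_volume(avg$model) - bead_volume(runs[[1]])),
             4 / 3 * pi * pb$bead_radius^3 + 1e-9)
})

test_that("averaging excludes a gross outlier", {
  pb <- small_sphere_problem()
  runs <- anneal_beads(pb$curve, pb$dmax, n_runs = 6, seed = 5,
                       bead_radius = pb$bead_radius)
  # outlier: a long thin rod, nothing like the consistent sphere runs
  rod <- bead_model(cbind(seq(0, 320, by = 8), 0, 0), pb$bead_radius)
  attr(rod, "lattice_sites") <- attr(runs[[1]], "lattice_sites")
  avg <- average_models(c(runs, list(rod)))
  expect_true(7 %in% avg$excluded)
})

test_that("refinement from an eroded start improves the fit and keeps the core", {
  pb <- small_sphere_problem()
  runs <- anneal_beads(pb$curve, pb$dmax, n_runs = 3, seed = 2,
                       bead_radius = pb$bead_radius)
  avg <- average_models(runs)
  # erode: drop a third of the selected beads
  start <- avg$model
  occ <- attr(start, "occupied")
  on <- which(occ)
  set.seed(1)
  occ[sample(on, length(on) %/% 3)] <- FALSE
  eroded <- start
  attr(eroded, "occupied") <- occ
  sites <- attr(start, "lattice_sites")
  eroded$centers <- sites[occ, , drop = FALSE]
  eroded$occupancy <- rep(1, sum(occ))
  ref <- refine_beads(eroded, pb$curve, seed = 4)
  f <- attr(ref, "fit")
  expect_lt(f$energy_final, f$energy_initial)
  # frozen high-occupancy core survives in the output
  frozen <- attr(ref, "frozen")
  if (any(frozen)) {
    kept <- attr(ref, "occupied")
    expect_true(all(kept[frozen]))
  }
})

test_that("bead_density conserves mass and separates distant beads", {
  one <- bead_model(matrix(c(0, 0, 0), 1, 3), 3)
  g <- bead_density(one, voxel = 2)
  idx <- which(g$values == max(g$values), arr.ind = TRUE)[1, ]
  ctr <- g$origin + (idx - 1) * g$voxel
  expect_equal(unname(ctr), c(0, 0, 0), tolerance = 2)
  mass <- sum(g$values) * g$voxel^3
  expect_equal(mass, (2 * pi * 3^2)^1.5, tolerance = 0.01)
  # translation leaves the integral unchanged
  g2 <- bead_density(bead_model(matrix(c(50, 20, -30), 1, 3), 3), voxel = 2)
  expect_equal(sum(g2$values) * g2$voxel^3, mass, tolerance = 1e-6)
  # two beads 1 voxel apart merge; 10 sigma apart resolve
  near <- bead_model(rbind(c(0, 0, 0), c(2, 0, 0)), 1, tol = 1)
  gn <- bead_density(near, voxel = 1, kernel_sigma = 2)
  mid <- saxstruct:::density_interp(gn, matrix(c(1, 0, 0), 1, 3))$value
  expect_gt(mid, 0.9 * max(gn$values))
  far <- bead_model(rbind(c(0, 0, 0), c(20, 0, 0)), 1, tol = 1)
  gf <- bead_density(far, voxel = 1, kernel_sigma = 2)
  midf <- saxstruct:::density_interp(gf, matrix(c(10, 0, 0), 1, 3))$value
  expect_lt(midf, 0.01 * max(gf$values))
})
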