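test_that("Guinier fit is exact on exact Guinier data", {
  q <- seq(0.004, 0.08, length.out = 120)
  I <- 100 * exp(-q^2 * 25^2 / 3)
  g <- guinier_fit(saxs_curve(q, I, 0.001 * I))
  expect_equal(g$rg, 25, tolerance = 1e-8)
  expect_equal(g$i0, 100, tolerance = 1e-8)
  expect_lte(max(g$q_range_used) * g$rg, 1.3 + 1e-9)
  # unweighted (sigma-free) path is exact too
  g2 <- guinier_fit(saxs_curve(q, I))
  expect_equal(g2$rg, 25, tolerance = 1e-8)
})

test_that("Guinier Rg of the analytic sphere is sqrt(3/5) R within 1 percent", {
  for (seed in 1:3) {
    cv <- sphere_curve(30, noise = 0.002, seed = seed)
    g <- guinier_fit(cv)
    expect_equal(g$rg, sqrt(3 / 5) * 30, tolerance = 0.01)
  }
})

test_that("Guinier errors on non-decaying data and drops aggregated leading points", {
  q <- seq(0.01, 0.1, length.out = 50)
  expect_error(guinier_fit(saxs_curve(q, rep(5, 50), rep(0.01, 50))),
               "no Guinier region")
  # low-q upturn (aggregation): auto_start must discard it
  I <- 100 * exp(-q^2 * 20^2 / 3)
  I[1:3] <- I[1:3] * c(1.8, 1.5, 1.3)
  g <- guinier_fit(saxs_curve(q, I, 0.001 * I), auto_start = TRUE)
  expect_equal(g$rg, 20, tolerance = 0.005)
  expect_gt(g$q_range_used[1], q[3])
})

test_that("IFT of the analytic sphere matches the closed-form P(r)", {
  cv <- sphere_curve(30, noise = 0.01, seed = 1)
  dd <- ift(cv, 60)
  so <- sphere_oracles(30)
  p_hat <- dd$p / max(dd$p)
  p_true <- so$p(dd$r) / max(so$p(dd$r))
  expect_lt(sqrt(mean((p_hat - p_true)^2)), 0.02)
  expect_equal(dd$p[1], 0)
  expect_equal(dd$p[length(dd$p)], 0, tolerance = 1e-10)
  expect_equal(dd$rg_real, so$rg, tolerance = 0.005)
})

test_that("IFT back-transform reproduces the input at the reported chi2", {
  cv <- sphere_curve(25, noise = 0.02, seed = 9)
  dd <- ift(cv, 50)
  bt <- pr_backtransform(dd, dd$curve$q)
  chi2 <- sum(((dd$curve$I - bt$I) / dd$curve$sigma)^2) /
    max(length(dd$curve$q) - dd$n_basis, 1)
  expect_equal(chi2, dd$fit_chi2, tolerance = 1e-8)
})

test_that("IFT of a two-point interference curve peaks near the pair distance", {
  # cross term of the two-point Debye profile (the self term is a constant
  # that belongs to r = 0, outside the P(r) support)
  bm <- bead_model(rbind(c(0, 0, 0), c(50, 0, 0)), bead_radius = 1)
  qg <- default_q_grid(256)
  I <- debye_profile(bm, qg)$I - 2
  cv <- saxs_curve(qg, I, 0.01 * abs(I) + 1e-3)
  dd <- ift(cv, 60)
  expect_equal(dd$r[which.max(dd$p)], 50, tolerance = 0.1)
})

test_that("IFT flags a Dmax the data cannot constrain", {
  cv <- sphere_curve(30, noise = 0.01, seed = 2)
  expect_false(ift(cv, 60)$dmax_unconstrained)
  expect_true(ift(cv, 3000)$dmax_unconstrained)
})

test_that("find_dmax recovers 2R for a sphere and the length of a rod-like toy", {
  cv <- sphere_curve(30, noise = 0.01, seed = 1)
  fd <- find_dmax(cv)
  expect_equal(fd$dmax, 60, tolerance = 0.05)
  expect_true(all(is.finite(fd$profile$score)))
  expect_true(all(diff(fd$profile$dmax) > 0))

  rod <- make_toy_structure(list(list(shape = "ellipsoid",
                                      semiaxes = c(55, 6, 6))), seed = 1)
  truth <- attr(rod, "truth")$dmax
  cvr <- simulate_curve(rod, noise_a = 0.005, seed = 3)
  fdr <- find_dmax(cvr)
  expect_equal(fdr$dmax, truth, tolerance = 0.10)
})

test_that("real_space_params: moments, spike limit, scale invariance", {
  so <- sphere_oracles(30)
  r <- seq(0, 60, length.out = 401)
  dd <- list(r = r, p = so$p(r))
  rp <- real_space_params(dd)
  expect_equal(rp$rg_real, so$rg, tolerance = 0.005)
  # narrow spike at r0: rg -> r0 / sqrt(2)
  r0 <- 40
  spike <- list(r = seq(0, 60, length.out = 2001),
                p = exp(-(seq(0, 60, length.out = 2001) - r0)^2 / (2 * 0.1^2)))
  expect_equal(real_space_params(spike)$rg_real, r0 / sqrt(2), tolerance = 1e-3)
  # scaling P leaves rg unchanged
  rp2 <- real_space_params(list(r = r, p = 7.3 * so$p(r)))
  expect_equal(rp2$rg_real, rp$rg_real)
  expect_equal(rp2$i0_real, 7.3 * rp$i0_real)
  expect_error(real_space_params(list(r = r, p = -so$p(r))), "non-positive")
})

test_that("pr_quality scores a clean sphere high and penalizes negative area", {
  cv <- sphere_curve(30, noise = 0.01, seed = 1)
  dd <- ift(cv, 60)
  q <- pr_quality(dd)
  expect_gt(q$score, 0.9)
  expect_true(all(unlist(q) >= 0 & unlist(q) <= 1))
  # inject 20 percent negative area: positivity sub-score = 0.8 exactly
  dd2 <- dd
  area <- sum(abs(dd2$p))
  k <- length(dd2$p)
  dd2$p[seq(k - 40, k - 21)] <- -area * 0.2 / 20
  dd2$p[seq_len(k - 41)] <- dd2$p[seq_len(k - 41)] * 0.8 * area /
    sum(abs(dd2$p[seq_len(k - 41)]))
  di <- pr_quality(dd2)
  expect_equal(di$positivity, 0.8, tolerance = 0.02)
  expect_lt(di$score, q$score)
})

test_that("pr_quality degrades as curve noise increases", {
  scores <- vapply(c(0.005, 0.05, 0.3), function(a) {
    mean(vapply(1:3, function(s)
      pr_quality(ift(sphere_curve(30, noise = a, seed = s), 60))$score, 0))
  }, 0)
  expect_true(all(diff(scores) < 0.02))  # non-increasing up to small jitter
})

test_that("Porod-volume MW: sphere volume, linear scaling, intensity invariance", {
  cv <- sphere_curve(30, noise = 0.01, seed = 1)
  dd <- ift(cv, 60)
  mw <- estimate_mw(cv, dd)
  V_true <- 4 / 3 * pi * 30^3
  expect_equal(mw$porod_volume, V_true, tolerance = 0.05)
  expect_equal(mw$mw_kda, mw$porod_volume / 1600)
  # uniform intensity scaling cancels
  cv2 <- saxs_curve(cv$q, 2 * cv$I, 2 * cv$sigma)
  dd2 <- ift(cv2, 60, alpha = dd$alpha)
  mw2 <- estimate_mw(cv2, dd2)
  expect_equal(mw2$porod_volume, mw$porod_volume, tolerance = 1e-6)
})

test_that("sequence MW matches an independent protein-analysis oracle", {
  # reference values from biopython ProteinAnalysis.molecular_weight()
  expect_equal(sequence_mw("G") * 1000, 75.0666, tolerance = 2e-5)
  expect_equal(sequence_mw("ACDEFGHIKLMNPQRSTVWY") * 1000, 2395.7134,
               tolerance = 2e-5)
  expect_equal(sequence_mw("MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ") * 1000,
               3935.5547, tolerance = 2e-5)
  expect_error(sequence_mw(""), "empty")
  expect_error(sequence_mw("GAVX"), "unknown")
})
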