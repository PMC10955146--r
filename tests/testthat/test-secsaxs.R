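make_series <- function(n_frames = 40, seed = 11) {
  m <- toy_preset("sphere")
  simulate_secsaxs(list(list(model = m, center = 25, width = 5, amplitude = 80)),
                   n_frames = n_frames, buffer_level = 1,
                   q_grid = default_q_grid(128), seed = seed)
}

test_that("chromatogram is linear in the intensities", {
  s <- make_series()
  chr <- chromatogram(s)
  expect_length(chr, 40)
  # doubling one frame's I doubles its chromatogram value
  s2 <- s
  s2$frames[[10]]$I <- 2 * s$frames[[10]]$I
  chr2 <- chromatogram(s2)
  expect_equal(chr2[10], 2 * chr[10])
  expect_equal(chr2[-10], chr[-10])
  # identical frames -> constant chromatogram
  s3 <- frame_series(rep(s$frames[10], 5))
  expect_equal(diff(chromatogram(s3)), rep(0, 4))
})

test_that("frame_rg recovers the species Rg under the peak and NA elsewhere", {
  s <- make_series()
  buf <- saxs_curve(s$q, rep(1, length(s$q)))
  rgv <- frame_rg(s, buf)
  truth <- attr(s, "truth")$species[[1]]$rg
  under_peak <- abs(seq_len(40) - 25) <= 4
  expect_true(all(abs(rgv$rg[under_peak] / truth - 1) < 0.05))
  # far from the peak the signal is buffer only: missing, not an error
  expect_true(anyNA(rgv$rg[c(1, 2, 40)]))
})

test_that("exact Guinier frames give exact per-frame Rg", {
  q <- default_q_grid(128)
  I <- 50 * exp(-q^2 * 30^2 / 3)
  frames <- replicate(5, saxs_curve(q, I, 0.001 * I), simplify = FALSE)
  s <- frame_series(frames)
  rgv <- frame_rg(s, NULL)
  expect_equal(rgv$rg, rep(30, 5), tolerance = 1e-6)
})

test_that("select_window matches an exhaustive window-search oracle", {
  # synthetic per-frame Rg table with one outlier at the window edge
  set.seed(7)
  n <- 20
  rg <- c(30 + rnorm(n - 1, sd = 0.05), 33)
  se <- rep(0.1, n)
  rgv <- data.frame(frame_index = 1:n, rg = rg, rg_se = se)
  s <- make_series(n)
  win <- select_window(s, rgv, 1:n)
  expect_false(win$fallback)
  expect_lt(win$last_frame, n)  # outlier excluded

  # oracle: brute force over all contiguous windows
  kappa_tol <- stats::median(se)
  best <- NULL
  for (a in 1:n) for (b in a:n) {
    if (b - a + 1 < 3) next
    sdv <- sd(rg[a:b])
    if (sdv <= kappa_tol) {
      cand <- list(a = a, b = b, len = b - a + 1, s = sdv)
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && cand$s < best$s)) best <- cand
    }
  }
  expect_equal(c(win$first_frame, win$last_frame), c(best$a, best$b))
})

test_that("select_window falls back to the length-3 minimum on drifting Rg", {
  n <- 15
  rgv <- data.frame(frame_index = 1:n, rg = 30 + (1:n) * 0.8,
                    rg_se = rep(0.05, n))
  s <- make_series(n)
  win <- select_window(s, rgv, 1:n)
  expect_true(win$fallback)
  expect_equal(win$n_frames, 3)
  # oracle: the minimizing length-3 window of a linear drift is any window;
  # sigma equals the drift sd
  expect_equal(win$sigma_rg, sd(30 + (1:3) * 0.8))
})

test_that("constant Rg series selects the whole peak region", {
  n <- 12
  rgv <- data.frame(frame_index = 1:n, rg = rep(30, n), rg_se = rep(0.1, n))
  s <- make_series(n)
  win <- select_window(s, rgv, 3:10)
  expect_equal(c(win$first_frame, win$last_frame), c(3, 10))
  expect_equal(win$sigma_rg, 0)
})

test_that("average_and_subtract recovers an injected signal and propagates sigma", {
  q <- default_q_grid(64)
  signal <- 10 * exp(-q^2 * 20^2 / 3)
  buffer <- rep(2, 64)
  frames <- c(
    replicate(4, saxs_curve(q, buffer + signal, rep(0.1, 64)), simplify = FALSE),
    replicate(4, saxs_curve(q, buffer, rep(0.1, 64)), simplify = FALSE))
  s <- frame_series(frames)
  out <- average_and_subtract(s, 1:4, 5:8)
  expect_equal(out$I, signal, tolerance = 1e-12)
  expect_equal(out$sigma, rep(sqrt(0.1^2 / 4 + 0.1^2 / 4), 64))
  expect_true(attr(out, "subtracted"))
  # single-frame window
  out1 <- average_and_subtract(s, 1, 5:8)
  expect_equal(out1$I, signal, tolerance = 1e-12)
  # empty buffer: flagged, not subtracted
  out2 <- average_and_subtract(s, 1:4, integer(0))
  expect_false(attr(out2, "subtracted"))
  expect_equal(out2$I, buffer + signal)
  # n identical frames shrink sigma by sqrt(n)
  expect_equal(attr(out, "subtracted"), TRUE)
  expect_error(average_and_subtract(s, 1:4, 4:6), "disjoint")
})

test_that("compare_datasets: identity, scale invariance, detected offset", {
  cv <- sphere_curve(25, noise = 0.02, seed = 3, n = 200)
  self <- compare_datasets(cv, cv)
  expect_equal(self$chi2, 0)
  expect_equal(self$p_value, 1)
  doubled <- saxs_curve(cv$q, 2 * cv$I, 2 * cv$sigma)
  sc <- compare_datasets(cv, doubled)
  expect_lt(sc$chi2, 1e-10)
  expect_equal(sc$scale, 2, tolerance = 1e-9)
  # 5-sigma offset on half the points is flagged at alpha = 0.01
  I2 <- cv$I
  half <- seq(1, 200, by = 2)
  I2[half] <- I2[half] + 5 * cv$sigma[half]
  off <- compare_datasets(cv, saxs_curve(cv$q, I2, cv$sigma))
  expect_lt(off$p_value, 0.01)
})

test_that("compare_datasets verdict is symmetric after mutual scaling", {
  a <- sphere_curve(25, noise = 0.02, seed = 5, n = 150)
  b <- sphere_curve(25, noise = 0.02, seed = 6, n = 150)
  b <- saxs_curve(b$q, 3 * b$I, 3 * b$sigma)
  ab <- compare_datasets(a, b)
  ba <- compare_datasets(b, a)
  expect_equal(ab$p_value > 0.01, ba$p_value > 0.01)
  expect_equal(ab$chi2, ba$chi2, tolerance = 0.05)
})

test_that("rebin preserves constant curves, shrinks sigma, keeps q range", {
  q <- seq(0.01, 0.3, length.out = 2000)
  cv <- saxs_curve(q, rep(7, 2000), rep(1, 2000))
  expect_identical(rebin(cv, merge_every = 1), cv)
  rb <- rebin(cv, merge_every = 4)
  expect_equal(rb$I, rep(7, length(rb$I)))
  expect_equal(rb$sigma[1], 0.5)
  lg <- rebin(cv, "log", n_points = 800)
  expect_lte(length(lg$q), 800)
  expect_true(all(diff(lg$q) > 0))
  expect_gte(min(lg$q), min(q))
  expect_lte(max(lg$q), max(q))
  expect_equal(lg$I, rep(7, length(lg$q)))
  expect_error(rebin(cv, "log", n_points = 4), ">= 5")
})
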