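#' Guinier analysis of the low-q region
#'
#' Weighted linear regression of ln I on q^2 over the low-q region, iterated
#' so that the final fitting range satisfies q_max * Rg <= `qrg_limit`
#' (1.3 is the standard cutoff for globular particles). With
#' `auto_start = TRUE`, leading points deviating more than 3 sigma from the
#' fit line (aggregation or beamstop artifacts) are dropped.
#'
#' @param curve a [saxs_curve()]; sigma optional (unweighted fit if absent).
#' @param qrg_limit upper bound on q * Rg in the fitted range.
#' @param auto_start drop deviating leading points.
#' @param min_points minimum number of points in the fit (>= 8).
#' @return a `guinier_result` list: `rg`, `rg_se`, `i0`, `q_range_used`,
#'   `r2`, `n_points`.
#' @export
guinier_fit <- function(curve, qrg_limit = 1.3, auto_start = TRUE,
                        min_points = 8) {
  pos <- curve$I > 0
  # leading run of positive intensities (Guinier region lives at low q)
  first_bad <- which(!pos)[1]
  n_lead <- if (is.na(first_bad)) length(curve$q) else first_bad - 1
  if (n_lead < min_points) stop("fewer than ", min_points, " usable low-q points")
  q <- curve$q[seq_len(n_lead)]
  I <- curve$I[seq_len(n_lead)]
  s <- curve$sigma[seq_len(n_lead)]
  x <- q^2
  y <- log(I)
  w <- if (!is.null(s)) (I / s)^2 else rep(1, n_lead)  # var(ln I) = (sigma/I)^2

  fit_range <- function(i0, i1) {
    ii <- i0:i1
    fit <- stats::lm.wfit(cbind(1, x[ii]), y[ii], w[ii])
    list(b = fit$coefficients[1], m = fit$coefficients[2], ii = ii, fit = fit)
  }
  lo <- 1L
  # start from a generous low-q window (a fifth of the usable points): a
  # minimal window in nearly flat, noisy data can show a spurious slope
  hi <- min(n_lead, max(min_points, ceiling(n_lead / 5)))
  iterate_qrg <- function(lo, hi) {
    for (iter in 1:40) {
      f <- fit_range(lo, hi)
      if (!is.finite(f$m) || f$m >= 0)
        stop("no Guinier region (non-decaying low-q data)")
      rg <- sqrt(-3 * f$m)
      hi_new <- max(which(q * rg <= qrg_limit), lo + min_points - 1L)
      hi_new <- min(hi_new, n_lead)
      if (hi_new == hi) break
      hi <- hi_new
    }
    hi
  }
  for (pass in 1:4) {
    hi <- iterate_qrg(lo, hi)
    if (!auto_start) break
    # judge each leading point against a fit that excludes it, so an
    # aggregation upturn cannot mask itself by bending the fit
    lo0 <- lo
    repeat {
      if (lo + min_points > n_lead) break
      hi_eff <- min(n_lead, max(hi, lo + min_points))
      f <- fit_range(lo + 1L, hi_eff)
      if (!is.finite(f$m)) break
      pred <- f$b + f$m * x[lo]
      sd_pt <- if (!is.null(s)) s[lo] / I[lo] else stats::sd(f$fit$residuals)
      if (abs(y[lo] - pred) > 3 * sd_pt) lo <- lo + 1L else break
    }
    if (lo == lo0) break
  }
  # linearity check: when the data resolve curvature beyond the noise
  # (reduced chi2 of the linear fit well above 1), shrink the range until
  # the Guinier line is statistically consistent with the points
  if (!is.null(s)) {
    repeat {
      f <- fit_range(lo, hi)
      dof <- length(f$ii) - 2
      chi2red <- sum(w[f$ii] * f$fit$residuals^2) / max(dof, 1)
      if (chi2red <= 3 || hi - lo + 1 <= min_points) break
      hi <- hi - 1L
    }
  }
  f <- fit_range(lo, hi)
  if (!is.finite(f$m) || f$m >= 0) stop("no Guinier region (non-decaying low-q data)")
  ii <- f$ii
  # curvature correction: if the residual quadratic term in q^2 is
  # statistically resolved (precise data curve visibly within qRg <= 1.3),
  # take the q^2 -> 0 slope of the quadratic fit, which removes the
  # systematic Rg bias of the plain Guinier line for globular shapes
  slope <- f$m; intercept <- f$b
  if (length(ii) >= min_points + 2) {
    Xq <- cbind(1, x[ii], x[ii]^2)
    fq <- stats::lm.wfit(Xq, y[ii], w[ii])
    cov_q <- tryCatch(solve(crossprod(Xq * sqrt(w[ii]))), error = function(e) NULL)
    if (!is.null(cov_q)) {
      s2q <- sum(w[ii] * fq$residuals^2) / max(length(ii) - 3, 1)
      t_c <- abs(fq$coefficients[3]) / sqrt(s2q * cov_q[3, 3])
      if (is.finite(t_c) && t_c > 3 && is.finite(fq$coefficients[2]) &&
          fq$coefficients[2] < 0) {
        slope <- fq$coefficients[2]; intercept <- fq$coefficients[1]
      }
    }
  }
  rg <- unname(sqrt(-3 * slope))
  i0 <- unname(exp(intercept))
  if (!is.finite(rg) || rg < 0.5)
    stop("no Guinier region (non-decaying low-q data)")
  res <- f$fit$residuals
  # weighted standard errors of the slope -> Rg
  X <- cbind(1, x[ii])
  XtWX_inv <- solve(crossprod(X * sqrt(w[ii])))
  dof <- length(ii) - 2
  s2 <- sum(w[ii] * res^2) / max(dof, 1)
  se_m <- sqrt(s2 * XtWX_inv[2, 2])
  rg_se <- if (is.finite(se_m)) 3 * se_m / (2 * rg) else NA_real_
  ybar <- sum(w[ii] * y[ii]) / sum(w[ii])
  r2 <- 1 - sum(w[ii] * res^2) / sum(w[ii] * (y[ii] - ybar)^2)
  structure(list(rg = rg, rg_se = rg_se, i0 = i0,
                 q_range_used = c(q[ii[1]], q[ii[length(ii)]]),
                 r2 = r2, n_points = length(ii)),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("guinier_result: Rg = %.2f +/- %.2f A, I0 = %.4g, q in [%.4g, %.4g] (n = %d, qRg_max = %.2f, R2 = %.4f)\n",
              x$rg, x$rg_se, x$i0, x$q_range_used[1], x$q_range_used[2],
              x$n_points, x$q_range_used[2] * x$rg, x$r2))
  invisible(x)
}
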