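#' Chromatogram of a SEC-SAXS frame series
#'
#' Total scattered intensity per frame: the trapezoidal integral of I(q)
#' over q. This is the elution-profile proxy used to locate peaks and
#' buffer regions.
#'
#' @param series a [frame_series()].
#' @return numeric vector, one value per frame.
#' @export
chromatogram <- function(series) {
  vapply(series$frames, function(f) trapz(f$q, f$I), 0)
}

#' Per-frame radius of gyration across a SEC-SAXS run
#'
#' Subtracts a buffer curve from each frame and runs a Guinier fit on the
#' result. Frames where the fit fails (no decaying Guinier region, e.g.
#' buffer-only frames) yield `NA`, not an error.
#'
#' @param series a [frame_series()].
#' @param buffer_curve a [saxs_curve()] on the same q grid (may be all
#'   zero for pre-subtracted data), or `NULL`.
#' @param qrg_limit Guinier range cutoff passed to [guinier_fit()].
#' @return data.frame with columns `frame_index`, `rg`, `rg_se` (Angstrom).
#' @export
frame_rg <- function(series, buffer_curve = NULL, qrg_limit = 1.3) {
  q <- series$q
  bI <- if (is.null(buffer_curve)) rep(0, length(q)) else {
    if (length(buffer_curve$q) != length(q) || max(abs(buffer_curve$q - q)) > 1e-9)
      stop("buffer_curve must share the series q grid")
    buffer_curve$I
  }
  res <- lapply(series$frames, function(f) {
    I <- f$I - bI
    out <- tryCatch({
      cv <- saxs_curve(q[I > 0], I[I > 0], f$sigma[I > 0], label = f$label)
      g <- guinier_fit(cv, qrg_limit = qrg_limit)
      c(g$rg, g$rg_se)
    }, error = function(e) c(NA_real_, NA_real_))
    out
  })
  m <- do.call(rbind, res)
  if (all(is.na(m[, 1]))) stop("Guinier fit failed on every frame")
  data.frame(frame_index = series$frame_index, rg = m[, 1], rg_se = m[, 2])
}

#' Select a homogeneous frame window under an elution peak
#'
#' Among all contiguous frame windows inside `peak_region` whose frames all
#' have a valid per-frame Rg, returns the longest one whose Rg standard
#' deviation (sigma over the window) does not exceed `kappa` times the
#' median per-frame Rg uncertainty, i.e. the longest stretch whose Rg
#' scatter is within measurement error. Ties are broken by smaller sigma,
#' then by earlier start. If no window of length >= 3 satisfies the bound,
#' the global sigma-minimizing window of length 3 is returned with
#' `fallback = TRUE`.
#'
#' @param series a [frame_series()].
#' @param rg_values data.frame from [frame_rg()].
#' @param peak_region integer vector of frame indices delimiting the peak
#'   (only its range is used).
#' @param kappa homogeneity threshold multiplier (default 1).
#' @return a `selection_window` list: `first_frame`, `last_frame`,
#'   `mean_rg`, `sigma_rg`, `n_frames`, `fallback`.
#' @export
select_window <- function(series, rg_values, peak_region, kappa = 1.0) {
  lo <- min(peak_region); hi <- max(peak_region)
  sub <- rg_values[rg_values$frame_index >= lo & rg_values$frame_index <= hi, ]
  ok <- is.finite(sub$rg)
  if (sum(ok) < 3) stop("fewer than 3 frames with valid Rg in peak_region")
  tol <- kappa * stats::median(sub$rg_se[ok], na.rm = TRUE)
  if (!is.finite(tol)) tol <- kappa * stats::sd(sub$rg[ok]) # all-SE-missing fallback
  idx <- sub$frame_index
  n <- nrow(sub)
  best <- NULL
  best_fb <- NULL
  for (a in seq_len(n)) {
    if (!ok[a]) next
    for (b in a:n) {
      if (!ok[b]) break            # window must be contiguous in valid frames
      len <- b - a + 1
      if (len < 3) next
      s <- stats::sd(sub$rg[a:b])
      cand <- list(a = idx[a], b = idx[b], len = len, s = s,
                   mean = mean(sub$rg[a:b]))
      if (is.null(best_fb) && len == 3) best_fb <- cand
      if (len == 3 && (cand$s < best_fb$s)) best_fb <- cand
      if (s <= tol) {
        if (is.null(best) || len > best$len ||
            (len == best$len && s < best$s) ||
            (len == best$len && s == best$s && idx[a] < best$a))
          best <- cand
      }
    }
  }
  fallback <- is.null(best)
  if (fallback) best <- best_fb
  structure(list(first_frame = best$a, last_frame = best$b,
                 mean_rg = best$mean, sigma_rg = best$s,
                 n_frames = best$len, fallback = fallback),
            class = "selection_window")
}

#' @export
print.selection_window <- function(x, ...) {
  cat(sprintf("selection_window: frames %d-%d (n = %d), <Rg> = %.2f A, sigma<Rg> = %.3f A%s\n",
              x$first_frame, x$last_frame, x$n_frames, x$mean_rg, x$sigma_rg,
              if (x$fallback) " [fallback]" else ""))
  invisible(x)
}

#' Average sample frames and subtract the averaged buffer
#'
#' Mean of the window frames minus mean of the buffer frames, with point-wise
#' uncertainty propagated as
#' \eqn{\sqrt{\sigma_s^2/n_s + \sigma_b^2/n_b}}. With an empty buffer set
#' the window is averaged without subtraction and the result is flagged
#' (`attr(curve, "subtracted") == FALSE`).
#'
#' @param series a [frame_series()].
#' @param window a `selection_window` or an integer vector of frame indices.
#' @param buffer_frames integer vector of buffer frame indices (disjoint
#'   from the window), possibly empty.
#' @return a [saxs_curve()].
#' @export
average_and_subtract <- function(series, window, buffer_frames = integer(0)) {
  win_idx <- if (inherits(window, "selection_window"))
    seq(window$first_frame, window$last_frame) else as.integer(window)
  if (length(intersect(win_idx, buffer_frames)) > 0)
    stop("window and buffer_frames must be disjoint")
  pos <- match(win_idx, series$frame_index)
  if (any(is.na(pos))) stop("window frames not in series")
  Im <- series_matrix(series)
  Sm <- series_sigma_matrix(series)
  ns <- length(pos)
  I_s <- colMeans(Im[pos, , drop = FALSE])
  var_s <- if (!is.null(Sm)) colMeans(Sm[pos, , drop = FALSE]^2) / ns
  if (length(buffer_frames) == 0) {
    out <- saxs_curve(series$q, I_s,
                      if (!is.null(Sm)) sqrt(var_s),
                      label = "averaged (no buffer subtraction)")
    attr(out, "subtracted") <- FALSE
    return(out)
  }
  bpos <- match(as.integer(buffer_frames), series$frame_index)
  if (any(is.na(bpos))) stop("buffer frames not in series")
  nb <- length(bpos)
  I_b <- colMeans(Im[bpos, , drop = FALSE])
  var_b <- if (!is.null(Sm)) colMeans(Sm[bpos, , drop = FALSE]^2) / nb
  out <- saxs_curve(series$q, I_s - I_b,
                    if (!is.null(Sm)) sqrt(var_s + var_b),
                    label = "averaged, buffer subtracted")
  attr(out, "subtracted") <- TRUE
  out
}

#' Pick buffer frames automatically
#'
#' Default convention: the `n` lowest-chromatogram frames preceding the
#' first peak (the elution baseline before any protein elutes).
#'
#' @param series a [frame_series()].
#' @param n number of buffer frames (default 20).
#' @return integer vector of frame indices.
#' @export
auto_buffer_frames <- function(series, n = 20) {
  chr <- chromatogram(series)
  first_peak <- which.max(chr > stats::median(chr) + 2 * stats::mad(chr))
  if (first_peak <= 1) first_peak <- which.max(chr)
  pre <- seq_len(max(first_peak - 1, 1))
  ord <- pre[order(chr[pre])]
  series$frame_index[utils::head(ord, n)]
}

#' Test whether two scattering curves sample the same distribution
#'
#' Interpolates B onto A's grid over the shared q range, scales A onto B by
#' analytic weighted least squares, and computes the reduced chi-square with
#' the combined point-wise uncertainty. The p-value comes from the
#' chi-square distribution with N - 1 degrees of freedom (one scale
#' fitted); at the conventional alpha = 0.01 a p-value above the threshold
#' means the two datasets are statistically compatible.
#'
#' @param curveA,curveB [saxs_curve()] objects with `sigma`.
#' @return list with `chi2` (reduced), `p_value`, `scale`, `n_points`.
#' @export
compare_datasets <- function(curveA, curveB) {
  if (is.null(curveA$sigma) || is.null(curveB$sigma))
    stop("both curves must carry sigma")
  qlo <- max(min(curveA$q), min(curveB$q))
  qhi <- min(max(curveA$q), max(curveB$q))
  keep <- curveA$q >= qlo & curveA$q <= qhi
  if (sum(keep) < 10) stop("fewer than 10 shared q points")
  qa <- curveA$q[keep]; Ia <- curveA$I[keep]; sa <- curveA$sigma[keep]
  Bi <- interp_curve(curveB, qa)
  Ib <- Bi$I; sb <- Bi$sigma
  # scale A -> B; with residual c*Ia - Ib the combined variance is
  # c^2 sa^2 + sb^2, so iterate the weights once
  cc <- 1
  for (it in 1:3) {
    w <- 1 / (cc^2 * sa^2 + sb^2)
    cc <- sum(w * Ia * Ib) / sum(w * Ia^2)
  }
  resid2 <- (cc * Ia - Ib)^2 / (cc^2 * sa^2 + sb^2)
  dof <- length(qa) - 1
  chi2 <- sum(resid2) / dof
  p <- stats::pchisq(sum(resid2), df = dof, lower.tail = FALSE)
  list(chi2 = chi2, p_value = p, scale = cc, n_points = length(qa))
}

#' Re-bin a scattering curve
#'
#' Either merges every run of `merge_every` consecutive points, or re-bins
#' onto `n_points` bins with edges linear or logarithmic in q. Within each
#' bin the intensity is the inverse-variance-weighted mean,
#' \eqn{\sigma_{bin} = (\sum \sigma^{-2})^{-1/2}}, and q is the weighted
#' mean q; empty bins are dropped. Curves without sigma use unweighted
#' means and stay sigma-free.
#'
#' @param curve a [saxs_curve()].
#' @param mode `"linear"` or `"log"` bin spacing (used with `n_points`).
#' @param n_points target number of bins (>= 5).
#' @param merge_every merge consecutive runs of this many points (>= 1;
#'   1 is the identity).
#' @return a [saxs_curve()].
#' @export
rebin <- function(curve, mode = c("log", "linear"), n_points = NULL,
                  merge_every = NULL) {
  mode <- match.arg(mode)
  n <- length(curve$q)
  if (!is.null(merge_every)) {
    k <- as.integer(merge_every)
    if (k < 1) stop("merge_every must be >= 1")
    if (k == 1) return(curve)
    grp <- (seq_len(n) - 1L) %/% k
  } else {
    if (is.null(n_points)) stop("give n_points or merge_every")
    if (n_points < 5) stop("n_points must be >= 5")
    if (n_points >= n) return(curve)
    edges <- if (mode == "linear") {
      seq(min(curve$q), max(curve$q), length.out = n_points + 1)
    } else {
      exp(seq(log(min(curve$q)), log(max(curve$q)), length.out = n_points + 1))
    }
    edges[1] <- edges[1] * (1 - 1e-9)
    edges[n_points + 1] <- edges[n_points + 1] * (1 + 1e-9)
    grp <- cut(curve$q, breaks = edges, include.lowest = TRUE, labels = FALSE)
  }
  w <- if (!is.null(curve$sigma)) 1 / curve$sigma^2 else rep(1, n)
  sw <- as.vector(rowsum(w, grp))
  qb <- as.vector(rowsum(w * curve$q, grp)) / sw
  Ib <- as.vector(rowsum(w * curve$I, grp)) / sw
  sb <- if (!is.null(curve$sigma)) 1 / sqrt(sw)
  ord <- order(qb)
  saxs_curve(qb[ord], Ib[ord], if (!is.null(sb)) sb[ord],
             label = paste0(curve$label, " [rebinned]"),
             q_max_usable = curve$q_max_usable)
}
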