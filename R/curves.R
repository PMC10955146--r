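#' Scattering curve constructor
#'
#' A one-dimensional solution scattering curve: momentum transfer `q`
#' (\eqn{\mathrm{\AA}^{-1}}), intensity `I` (arbitrary units) and, optionally,
#' the 1-sigma uncertainty of `I`. This is the universal currency of the
#' package: every analysis step consumes or produces one.
#'
#' @param q numeric vector of momentum transfer values, \eqn{\mathrm{\AA}^{-1}},
#'   strictly increasing and positive.
#' @param I numeric vector of intensities, same length as `q`.
#' @param sigma optional numeric vector of 1-sigma uncertainties (> 0).
#' @param label free-text label carried through to file headers.
#' @param q_max_usable optional analysis cutoff in \eqn{\mathrm{\AA}^{-1}}.
#' @return An object of class `saxs_curve`: a list with elements `q`, `I`,
#'   `sigma` (possibly `NULL`), `label`, `q_max_usable`.
#' @export
saxs_curve <- function(q, I, sigma = NULL, label = "", q_max_usable = NULL) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I))
    stop("q and I must have the same length")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q))
      stop("sigma must have the same length as q")
    if (any(!is.finite(sigma)) || any(sigma <= 0))
      stop("sigma must be finite and > 0")
  }
  if (any(!is.finite(q)) || any(!is.finite(I)))
    stop("q and I must be finite")
  if (any(q <= 0)) stop("q must be positive")
  if (any(diff(q) <= 0)) stop("q must be strictly increasing")
  structure(list(q = q, I = I, sigma = sigma, label = as.character(label)[1],
                 q_max_usable = q_max_usable),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat(sprintf("saxs_curve: %d points, q in [%.4g, %.4g] A^-1%s%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) ", no sigma" else "",
              if (nzchar(x$label)) paste0(", label '", x$label, "'") else ""))
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$q)

#' Restrict a curve to a q interval
#'
#' @param curve a [saxs_curve()].
#' @param qmin,qmax inclusive bounds in \eqn{\mathrm{\AA}^{-1}}.
#' @return the truncated `saxs_curve`.
#' @export
trim_curve <- function(curve, qmin = -Inf, qmax = Inf) {
  keep <- curve$q >= qmin & curve$q <= qmax
  if (sum(keep) < 2) stop("fewer than 2 points left after trimming")
  saxs_curve(curve$q[keep], curve$I[keep],
             if (is.null(curve$sigma)) NULL else curve$sigma[keep],
             label = curve$label, q_max_usable = curve$q_max_usable)
}

#' Read a 3-column scattering curve (.dat)
#'
#' Parses the plain-text `q I [sigma]` format used by SASBDB and the ATSAS
#' suite. Lines starting with `#` (or other non-numeric header/footer lines)
#' are skipped; rows with non-positive q or non-finite values are dropped
#' with a message. Points are sorted by q on load. Curves whose q maximum
#' exceeds 3 are rejected: SAXS data on proteins never extend that far in
#' \eqn{\mathrm{\AA}^{-1}}, so such a file is almost certainly in
#' \eqn{\mathrm{nm}^{-1}} and silent unit conversion is a classic source of
#' error.
#'
#' @param path file path.
#' @param label curve label; defaults to the file name.
#' @return a [saxs_curve()].
#' @export
read_dat <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(l) {
    f <- suppressWarnings(as.numeric(strsplit(l, "[ \t,]+")[[1]]))
    if (length(f) >= 2 && !any(is.na(f[1:2]))) f else NULL
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) stop("no numeric data rows in ", path)
  ncol <- min(vapply(rows, length, 1L))
  m <- do.call(rbind, lapply(rows, function(r) r[seq_len(min(ncol, 3))]))
  has_sigma <- ncol >= 3 && all(is.finite(m[, 3]))
  ok <- is.finite(m[, 1]) & is.finite(m[, 2]) & m[, 1] > 0
  if (has_sigma) ok <- ok & is.finite(m[, 3]) & m[, 3] > 0
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message("read_dat: dropped ", n_dropped, " unusable row(s)")
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < 5) stop("fewer than 5 usable rows in ", path)
  m <- m[!duplicated(m[, 1]), , drop = FALSE]
  m <- m[order(m[, 1]), , drop = FALSE]
  if (max(m[, 1]) > 3)
    stop("q_max > 3: data appear to be in nm^-1, not A^-1; convert before loading")
  saxs_curve(m[, 1], m[, 2], if (has_sigma) m[, 3] else NULL, label = label)
}

#' Write a scattering curve to a .dat file
#'
#' @param curve a [saxs_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  hdr <- sprintf("# %s", if (nzchar(curve$label)) curve$label else "saxstruct curve")
  cols <- c("q (A^-1)", "I", if (!is.null(curve$sigma)) "sigma")
  hdr <- c(hdr, paste0("# ", paste(cols, collapse = "  ")))
  body <- if (is.null(curve$sigma)) {
    sprintf("%.6e %.6e", curve$q, curve$I)
  } else {
    sprintf("%.6e %.6e %.6e", curve$q, curve$I, curve$sigma)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' SEC-SAXS frame series constructor
#'
#' An ordered collection of scattering curves from one SEC-SAXS injection.
#' All frames must share one identical q grid.
#'
#' @param frames list of [saxs_curve()] objects on a common q grid.
#' @param frame_index integer frame indices, strictly increasing.
#' @param exposure exposure time per frame, seconds.
#' @return an object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_index = seq_along(frames), exposure = 3) {
  stopifnot(length(frames) >= 1)
  q0 <- frames[[1]]$q
  same <- vapply(frames, function(f) {
    length(f$q) == length(q0) && max(abs(f$q - q0)) < 1e-12
  }, TRUE)
  if (!all(same)) stop("all frames must share an identical q grid")
  frame_index <- as.integer(frame_index)
  if (length(frame_index) != length(frames) || any(diff(frame_index) <= 0))
    stop("frame_index must be strictly increasing, one per frame")
  structure(list(frames = frames, frame_index = frame_index,
                 exposure = exposure, q = q0),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("frame_series: %d frames x %d q-points, exposure %g s/frame\n",
              length(x$frames), length(x$q), x$exposure))
  invisible(x)
}

#' @export
length.frame_series <- function(x) length(x$frames)

# intensity matrix (frames x q) of a series
series_matrix <- function(series) {
  do.call(rbind, lapply(series$frames, function(f) f$I))
}

series_sigma_matrix <- function(series) {
  s <- lapply(series$frames, function(f) f$sigma)
  if (any(vapply(s, is.null, TRUE))) return(NULL)
  do.call(rbind, s)
}

# trapezoidal integral
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# linear interpolation of a curve onto a new q grid (no extrapolation)
interp_curve <- function(curve, q_new) {
  I <- stats::approx(curve$q, curve$I, xout = q_new, rule = 1)$y
  sigma <- if (!is.null(curve$sigma))
    stats::approx(curve$q, curve$sigma, xout = q_new, rule = 1)$y
  list(q = q_new, I = I, sigma = sigma)
}
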