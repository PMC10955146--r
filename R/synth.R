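#' Cubic-lattice points filling a solid shape
#'
#' Pseudo-atom positions at `spacing` on a cubic lattice inside a sphere
#' or ellipsoid, used to build toy domains and ideal reference bead sets.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param radius sphere radius, Angstrom.
#' @param semiaxes length-3 ellipsoid semi-axes, Angstrom.
#' @param spacing lattice constant, Angstrom.
#' @return n x 3 matrix of coordinates.
#' @export
fill_shape <- function(shape = c("sphere", "ellipsoid"), radius = NULL,
                       semiaxes = NULL, spacing = 3.8) {
  shape <- match.arg(shape)
  ax <- if (shape == "sphere") rep(radius, 3) else semiaxes
  stopifnot(length(ax) == 3, all(ax > 0))
  g <- lapply(ax, function(a) seq(-a, a, by = spacing))
  pts <- as.matrix(expand.grid(x = g[[1]], y = g[[2]], z = g[[3]]))
  keep <- rowSums(sweep(pts, 2, ax, "/")^2) <= 1
  unname(pts[keep, , drop = FALSE])
}

#' Generate a toy multi-domain C-alpha structure with known ground truth
#'
#' Builds a chain of globular domains (spheres or ellipsoids filled with
#' pseudo C-alpha sites at 3.8 Angstrom spacing) connected by extended
#' linkers, emulating a flexible multi-domain protein. Domain placement
#' directions are drawn at random (seeded); overlapping placements are
#' retried. The generating Rg and Dmax are recorded in
#' `attr(model, "truth")`.
#'
#' @param domains list of domain specs: `list(shape = "sphere", radius = R)`
#'   or `list(shape = "ellipsoid", semiaxes = c(a, b, c))`.
#' @param linker_length linker length(s) in Angstrom between consecutive
#'   domain surfaces (recycled).
#' @param spacing lattice / linker spacing, Angstrom (3.8 = C-alpha step).
#' @param seed RNG seed for placement directions.
#' @param straight place all domains along +x (deterministic, maximally
#'   extended); default uses random directions within 60 degrees of +x.
#' @return an [atomic_model()] of C-alpha sites (`resid = "ALA"`), with
#'   `attr(model, "truth") = list(rg, dmax, domain_ranges)`.
#' @export
make_toy_structure <- function(domains, linker_length = 10, spacing = 3.8,
                               seed = 1, straight = FALSE) {
  stopifnot(length(domains) >= 1)
  if (!is.null(seed)) set.seed(seed)
  linker_length <- rep_len(linker_length, max(length(domains) - 1, 1))
  eff_radius <- function(d) {
    if (identical(d$shape, "ellipsoid")) max(d$semiaxes) else d$radius
  }
  centers <- matrix(0, nrow = length(domains), ncol = 3)
  for (i in seq_along(domains)[-1]) {
    gap <- eff_radius(domains[[i - 1]]) + linker_length[i - 1] +
      eff_radius(domains[[i]])
    placed <- FALSE
    for (attempt in 1:100) {
      dir <- if (straight) c(1, 0, 0) else {
        v <- c(1, stats::rnorm(2, sd = 0.4))
        v / sqrt(sum(v^2))
      }
      cand <- centers[i - 1, ] + dir * gap
      clash <- FALSE
      if (i > 2) {
        for (j in seq_len(i - 2)) {
          if (sqrt(sum((cand - centers[j, ])^2)) <
              eff_radius(domains[[j]]) + eff_radius(domains[[i]])) clash <- TRUE
        }
      }
      if (!clash) { centers[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("could not place domain ", i, " without overlap")
  }
  coords <- NULL
  ranges <- list()
  resno <- 0L
  for (i in seq_along(domains)) {
    d <- domains[[i]]
    pts <- sweep(fill_shape(d$shape %||% "sphere", radius = d$radius,
                            semiaxes = d$semiaxes, spacing = spacing),
                 2, centers[i, ], "+")
    ranges[[i]] <- c(resno + 1L, resno + nrow(pts))
    resno <- resno + nrow(pts)
    coords <- rbind(coords, pts)
    if (i < length(domains)) {
      # extended linker along the inter-domain axis, between the surfaces
      dir <- centers[i + 1, ] - centers[i, ]
      len <- sqrt(sum(dir^2)); dir <- dir / len
      t0 <- eff_radius(domains[[i]])
      t1 <- len - eff_radius(domains[[i + 1]])
      if (t1 > t0 + spacing) {
        ts <- seq(t0 + spacing, t1 - spacing / 2, by = spacing)
        lk <- sweep(outer(ts, dir), 2, centers[i, ], "+")
        resno <- resno + nrow(lk)
        coords <- rbind(coords, lk)
      }
    }
  }
  n <- nrow(coords)
  atoms <- data.frame(resno = seq_len(n), resid = "ALA", elety = "CA",
                      chain = "A", x = coords[, 1], y = coords[, 2],
                      z = coords[, 3], elem = "C")
  m <- atomic_model(atoms, label = "toy structure")
  ctr <- colMeans(coords)
  rg <- sqrt(mean(rowSums(sweep(coords, 2, ctr)^2)))
  dmax <- max(stats::dist(coords))
  attr(m, "truth") <- list(rg = rg, dmax = dmax, domain_ranges = ranges)
  m
}

#' Toy-structure presets
#'
#' `"sphere"`: one R = 30 Angstrom globule. `"dumbbell"`: two R = 15
#' Angstrom domains 80 Angstrom apart (Dmax about 110). `"nsd3"`: three
#' domains sized like the PWWP2 (84 aa), AWS-SET-postSET (249 aa) and PHD4
#' (105 aa) regions of the NSD3 C-terminus, joined by short linkers — a
#' stand-in with the study system's topology, not its coordinates.
#'
#' @param preset one of `"sphere"`, `"dumbbell"`, `"nsd3"`.
#' @param seed placement seed.
#' @return an [atomic_model()] with ground-truth attributes.
#' @export
toy_preset <- function(preset = c("nsd3", "sphere", "dumbbell"), seed = 1) {
  preset <- match.arg(preset)
  res_radius <- function(n_res, spacing = 3.8) (n_res * spacing^3 * 3 / (4 * pi))^(1 / 3)
  switch(preset,
    sphere = make_toy_structure(list(list(shape = "sphere", radius = 30)),
                                seed = seed),
    dumbbell = make_toy_structure(
      list(list(shape = "sphere", radius = 15),
           list(shape = "sphere", radius = 15)),
      linker_length = 50, seed = seed, straight = TRUE),
    nsd3 = make_toy_structure(
      list(list(shape = "sphere", radius = res_radius(84)),
           list(shape = "ellipsoid", semiaxes = res_radius(249) * c(1.3, 1, 0.85)),
           list(shape = "sphere", radius = res_radius(105))),
      linker_length = c(12, 10), seed = seed))
}

#' Simulate a noisy scattering curve from a model
#'
#' Residue-level Debye profile plus Gaussian noise with a q-dependent
#' standard deviation \eqn{\sigma(q) = a I(q) (1 + b q/q_{max})}: relative
#' noise grows toward high q, as in real SEC-SAXS data where the signal
#' falls orders of magnitude below the low-q level. The sigma column of the
#' returned curve carries the true noise sigma.
#'
#' @param model `atomic_model` or `bead_model`.
#' @param q_grid q values; default 512 points on 0.0026 to 0.340
#'   \eqn{\mathrm{\AA}^{-1}} (a typical bioSAXS camera range).
#' @param i0_scale multiplies the profile so I(0) = `i0_scale`.
#' @param noise_a relative noise level at low q (0 = noiseless, no sigma).
#' @param noise_b high-q noise growth factor.
#' @param seed RNG seed.
#' @return a [saxs_curve()] with `attr(curve, "truth") = list(rg, dmax,
#'   i_true)`.
#' @export
simulate_curve <- function(model, q_grid = default_q_grid(), i0_scale = 1,
                           noise_a = 0.01, noise_b = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prof <- debye_profile(model, q_grid)
  I0 <- debye_profile(model, 0)$I
  I_true <- prof$I / I0 * i0_scale
  if (noise_a > 0) {
    s <- noise_a * I_true * (1 + noise_b * q_grid / max(q_grid))
    I <- I_true + stats::rnorm(length(I_true), sd = s)
    out <- saxs_curve(q_grid, I, s, label = "simulated curve")
  } else {
    out <- saxs_curve(q_grid, I_true, NULL, label = "simulated curve (noiseless)")
  }
  tr <- attr(model, "truth")
  attr(out, "truth") <- list(rg = model_rg(model),
                             dmax = if (!is.null(tr)) tr$dmax else
                               max(stats::dist(model_coords(model))),
                             i_true = I_true)
  out
}

#' Default SEC-SAXS q grid
#'
#' @param n number of points.
#' @return q values on 0.0026 to 0.340 \eqn{\mathrm{\AA}^{-1}}.
#' @export
default_q_grid <- function(n = 512) seq(0.0026, 0.340, length.out = n)

#' Analytic solid-sphere oracles
#'
#' Closed forms for a homogeneous sphere of radius R: the form-factor
#' intensity \eqn{I(q) = [3(\sin(qR) - qR\cos(qR))/(qR)^3]^2} (normalized to
#' I(0) = 1), the pair distance distribution
#' \eqn{p(r) \propto r^2 (1 - 1.5x + 0.5x^3)} with \eqn{x = r/2R},
#' \eqn{R_g = \sqrt{3/5} R} and \eqn{D_{max} = 2R}.
#'
#' @param R sphere radius, Angstrom.
#' @return list with functions `I(q)` and `p(r)` plus `rg`, `dmax`.
#' @export
sphere_oracles <- function(R) {
  I <- function(q) {
    qR <- q * R
    out <- (3 * (sin(qR) - qR * cos(qR)) / qR^3)^2
    out[qR == 0] <- 1
    out
  }
  p <- function(r) {
    x <- r / (2 * R)
    out <- r^2 * (1 - 1.5 * x + 0.5 * x^3)
    out[r < 0 | r > 2 * R] <- 0
    out
  }
  list(I = I, p = p, rg = sqrt(3 / 5) * R, dmax = 2 * R)
}

#' Simulate a SEC-SAXS frame series
#'
#' Emulates an elution with any number of (possibly overlapping) species:
#' frame f of species s contributes
#' `amplitude * exp(-(f - center)^2 / (2 width^2)) * I_s(q)`, on top of a
#' flat buffer level, with the same q-dependent noise model as
#' [simulate_curve()]. A shoulder is simply a species whose elution peak
#' overlaps another's. Per-frame ground-truth composition is recorded in
#' `attr(series, "truth")`.
#'
#' @param species list of `list(model =, center =, width =, amplitude =)`;
#'   `center`/`width` in frames, `amplitude` = I(0) at peak top.
#' @param n_frames number of frames.
#' @param buffer_level flat buffer intensity.
#' @param q_grid q values.
#' @param noise_a,noise_b noise model (see [simulate_curve()]).
#' @param seed RNG seed.
#' @return a [frame_series()] with truth attributes (per-species per-frame
#'   weights, species Rg/Dmax).
#' @export
simulate_secsaxs <- function(species, n_frames = 100, buffer_level = 1,
                             q_grid = default_q_grid(), noise_a = 0.01,
                             noise_b = 4, seed = 1) {
  stopifnot(length(species) >= 1)
  if (!is.null(seed)) set.seed(seed)
  profs <- lapply(species, function(s) {
    p <- debye_profile(s$model, q_grid)
    p$I / debye_profile(s$model, 0)$I  # normalized so I(0) = 1
  })
  wts <- vapply(seq_along(species), function(k) {
    s <- species[[k]]
    s$amplitude * exp(-(seq_len(n_frames) - s$center)^2 / (2 * s$width^2))
  }, numeric(n_frames))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    I_true <- buffer_level + Reduce(`+`, lapply(seq_along(species), function(k)
      wts[f, k] * profs[[k]]))
    sref <- pmax(I_true, buffer_level)
    s <- pmax(noise_a * sref * (1 + noise_b * q_grid / max(q_grid)), 1e-12)
    I <- I_true + stats::rnorm(length(q_grid), sd = s)
    frames[[f]] <- saxs_curve(q_grid, I, s, label = sprintf("frame %d", f))
  }
  series <- frame_series(frames, seq_len(n_frames))
  attr(series, "truth") <- list(
    weights = wts, buffer_level = buffer_level,
    species = lapply(species, function(s) {
      tr <- attr(s$model, "truth")
      list(rg = model_rg(s$model),
           dmax = if (!is.null(tr)) tr$dmax else max(stats::dist(model_coords(s$model))),
           center = s$center, width = s$width, amplitude = s$amplitude)
    }))
  series
}

#' Write the ground-truth manifest of a synthetic object
#'
#' Serializes `attr(x, "truth")` to JSON next to the data it describes, so
#' every simulator output travels with its generating parameters.
#'
#' @param x an object produced by the synthetic-data generators.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  tr <- attr(x, "truth")
  if (is.null(tr)) stop("object has no truth attribute")
  jsonlite::write_json(tr, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
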