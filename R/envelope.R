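# face-centered-cubic search lattice filling a sphere of diameter dmax;
# nearest-neighbor distance = 2 * bead_radius (touching beads)
make_bead_lattice <- function(dmax, bead_radius) {
  spacing <- 2 * bead_radius
  s <- spacing / sqrt(2)
  R <- dmax / 2
  nmax <- ceiling(R / s)
  g <- seq(-nmax, nmax)
  pts <- as.matrix(expand.grid(i = g, j = g, k = g))
  pts <- pts[(pts[, 1] + pts[, 2] + pts[, 3]) %% 2 == 0, , drop = FALSE]
  xyz <- pts * s
  xyz <- xyz[rowSums(xyz^2) <= R^2, , drop = FALSE]
  finish_lattice(unname(xyz), spacing, bead_radius)
}

# neighbor table and 0.1-A distance classes for an explicit site set
finish_lattice <- function(xyz, spacing, bead_radius) {
  n <- nrow(xyz)
  dm <- as.matrix(stats::dist(xyz))
  nbr_list <- lapply(seq_len(n), function(i)
    which(dm[i, ] > 0 & dm[i, ] < spacing * 1.05))
  deg <- max(lengths(nbr_list), 1)
  NBR <- matrix(NA_integer_, n, deg)
  for (i in seq_len(n)) if (length(nbr_list[[i]]))
    NBR[i, seq_along(nbr_list[[i]])] <- nbr_list[[i]]
  cls <- matrix(as.integer(round(dm / 0.1)), n, n)
  list(sites = xyz, spacing = spacing, bead_radius = bead_radius,
       NBR = NBR, deg = deg, cls = cls, n_cls = max(cls),
       cls_d = seq_len(max(cls)) * 0.1)
}

# connected-component membership from a seed over occupied sites (level BFS)
occ_component <- function(occ, NBR, seed) {
  visited <- logical(length(occ))
  visited[seed] <- TRUE
  frontier <- seed
  while (length(frontier)) {
    nb <- as.vector(NBR[frontier, , drop = FALSE])
    nb <- nb[!is.na(nb)]
    nb <- unique(nb[occ[nb] & !visited[nb]])
    visited[nb] <- TRUE
    frontier <- nb
  }
  visited
}

# exact disconnectivity: occupied beads outside the component of the bead
# nearest the occupied centroid
occ_disconnect <- function(occ, lat) {
  occ_idx <- which(occ)
  ctr <- colMeans(lat$sites[occ_idx, , drop = FALSE])
  seed <- occ_idx[which.min(rowSums(sweep(lat$sites[occ_idx, , drop = FALSE],
                                          2, ctr)^2))]
  comp <- occ_component(occ, lat$NBR, seed)
  length(occ_idx) - sum(comp[occ_idx])
}

anneal_chi2 <- function(I_model, target) {
  w <- 1 / target$sigma^2
  cc <- sum(w * target$I * I_model) / sum(w * I_model^2)
  sum(w * (target$I - cc * I_model)^2) / (length(I_model) - 1)
}

model_intensity <- function(occ_idx, lat, sinc_tab) {
  cnt <- tabulate(lat$cls[occ_idx, occ_idx][upper.tri(
    matrix(0, length(occ_idx), length(occ_idx)))], nbins = lat$n_cls)
  length(occ_idx) + 2 * as.vector(sinc_tab %*% cnt)
}

#' Ab initio envelope reconstruction by simulated annealing
#'
#' Reconstructs a dummy-atom envelope from a scattering curve: a
#' face-centered-cubic bead lattice fills a sphere of diameter Dmax; a
#' binary occupancy state is annealed with single-bead flip moves under the
#' energy
#' \deqn{E = \chi^2(\mathrm{Debye\ profile\ of\ occupied\ beads},\ curve)
#'  + \lambda\,(\mathrm{looseness} + \mathrm{disconnectivity})}
#' where looseness is the mean fraction of empty neighbor sites (the
#' compactness prior) and disconnectivity counts occupied beads outside
#' the main connected component (evaluated exactly at every move by a
#' component search). `lambda` is auto-balanced to `lambda_scale` times
#' the chi-square of the random start: strong enough to keep shapes
#' compact and connected, weak enough that the data still steer the final
#' configuration. Geometric cooling (T times 0.9 per
#' chunk of moves) from a temperature at which about half the uphill moves
#' are accepted; a run stops when the in-chunk acceptance rate falls below
#' 1 percent or the move budget is exhausted. Each run is independently
#' seeded, so a fixed `seed` gives a bit-identical set of reconstructions.
#'
#' @param curve a [saxs_curve()] with `sigma`.
#' @param dd a `distance_distribution` supplying Dmax (or a number).
#' @param n_runs number of independent reconstructions.
#' @param bead_radius bead radius, Angstrom; default Dmax/20.
#' @param seed base RNG seed; run r uses `seed + r`.
#' @param n_q number of log-spaced q bins the curve is compressed to for
#'   the annealing target.
#' @param max_moves move budget per run; default `30 * n_sites`.
#' @param t_factor multiplies the auto-selected starting temperature
#'   (used by refinement restarts).
#' @param lambda_scale penalty-to-data balance (see above).
#' @param start optional starting occupancy (logical over lattice sites).
#' @param frozen optional logical: sites that must stay occupied.
#' @param lattice reuse a prebuilt lattice (internal).
#' @return list of `bead_model`s, each with `attr(, "fit")` (final profile
#'   chi2, initial/final energy, bead count, disconnected-bead count) and
#'   lattice attributes for averaging/refinement.
#' @export
anneal_beads <- function(curve, dd, n_runs = 20, bead_radius = NULL,
                         seed = 1, n_q = 40, max_moves = NULL,
                         t_factor = 1, lambda_scale = 0.02, start = NULL,
                         frozen = NULL, lattice = NULL) {
  dmax <- if (inherits(dd, "distance_distribution")) dd$dmax else as.numeric(dd)
  if (is.null(bead_radius)) bead_radius <- dmax / 20
  if (dmax < 8 * bead_radius) stop("Dmax smaller than 4 bead diameters")
  lat <- lattice %||% make_bead_lattice(dmax, bead_radius)
  n <- nrow(lat$sites)
  if (is.null(max_moves)) max_moves <- 30L * n
  target <- rebin(trim_curve(curve, qmax = curve$q_max_usable %||% max(curve$q)),
                  mode = "log", n_points = n_q)
  if (is.null(target$sigma)) stop("anneal_beads needs a curve with sigma")
  wq <- 1 / target$sigma^2
  sinc_tab <- {
    qd <- outer(target$q, lat$cls_d)
    s <- sin(qd) / qd
    s[qd == 0] <- 1
    s
  }
  deg <- lat$deg
  runs <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    set.seed(seed + run)
    occ <- if (is.null(start)) stats::runif(n) < 0.4 else start
    if (!is.null(frozen)) occ[frozen] <- TRUE
    if (sum(occ) < 8) occ[sample.int(n, 8)] <- TRUE
    nbr_occ <- vapply(seq_len(n), function(i) {
      nb <- lat$NBR[i, ]; sum(occ[nb[!is.na(nb)]], na.rm = TRUE)
    }, 0L)
    n_occ <- sum(occ)
    S_edge <- sum(nbr_occ[occ])            # 2 x (edges between occupied)
    disc <- occ_disconnect(occ, lat)
    I_model <- model_intensity(which(occ), lat, sinc_tab)
    chi2 <- anneal_chi2(I_model, target)
    penalty0 <- (1 - S_edge / (deg * n_occ)) + disc
    lambda <- lambda_scale * chi2 / max(penalty0, 0.05)
    energy <- function(chi2, n_occ, S_edge, disc)
      chi2 + lambda * ((1 - S_edge / (deg * max(n_occ, 1))) + disc)
    E <- energy(chi2, n_occ, S_edge, disc)
    E_init <- E

    # candidate evaluation: incremental intensity update, exact
    # disconnectivity by component search on the flipped state
    eval_flip <- function(b) {
      occ_idx <- which(occ)
      others <- occ_idx[occ_idx != b]
      cnt <- tabulate(lat$cls[b, others], nbins = lat$n_cls)
      dI <- 1 + 2 * as.vector(sinc_tab %*% cnt)
      on <- !occ[b]
      I_new <- I_model + (if (on) dI else -dI)
      chi2_new <- anneal_chi2(I_new, target)
      nb <- lat$NBR[b, ]; nb <- nb[!is.na(nb)]
      if (on) {
        n_occ_new <- n_occ + 1L
        S_new <- S_edge + 2L * nbr_occ[b]
      } else {
        n_occ_new <- n_occ - 1L
        S_new <- S_edge - 2L * nbr_occ[b]
      }
      occ2 <- occ
      occ2[b] <- on
      disc_new <- occ_disconnect(occ2, lat)
      list(I_new = I_new, chi2_new = chi2_new, n_occ = n_occ_new,
           S = S_new, disc = disc_new,
           E = energy(chi2_new, n_occ_new, S_new, disc_new), nb = nb, on = on)
    }
    # starting temperature from a probe of uphill move costs
    probe_sites <- sample.int(n, min(50, n))
    dEs <- vapply(probe_sites, function(b) eval_flip(b)$E - E, 0)
    up <- dEs[dEs > 0]
    T <- t_factor * (if (length(up)) mean(up) / log(2) else 1)
    best <- list(E = E, occ = occ)
    moves <- 0L
    chunk <- max(200L, n)
    repeat {
      acc <- 0L
      cand <- sample.int(n, chunk, replace = TRUE)
      for (b in cand) {
        if (!is.null(frozen) && frozen[b]) next
        if (occ[b] && n_occ <= 8L) next
        res <- eval_flip(b)
        dE <- res$E - E
        if (dE <= 0 || stats::runif(1) < exp(-dE / T)) {
          acc <- acc + 1L
          occ[b] <- res$on
          nbr_occ[res$nb] <- nbr_occ[res$nb] + (if (res$on) 1L else -1L)
          n_occ <- res$n_occ; S_edge <- res$S; disc <- res$disc
          I_model <- res$I_new; chi2 <- res$chi2_new; E <- res$E
          if (E < best$E) best <- list(E = E, occ = occ)
        }
      }
      moves <- moves + chunk
      T <- T * 0.9
      if (acc < 0.01 * chunk || moves >= max_moves) break
    }
    occ <- best$occ
    oi <- which(occ)
    bm <- bead_model(lat$sites[oi, , drop = FALSE], bead_radius,
                     label = sprintf("anneal run %d", run))
    I_fin <- model_intensity(oi, lat, sinc_tab)
    attr(bm, "fit") <- list(chi2 = anneal_chi2(I_fin, target),
                            energy_initial = E_init, energy_final = best$E,
                            n_beads = length(oi),
                            disconnected = occ_disconnect(occ, lat))
    attr(bm, "lattice_sites") <- lat$sites
    attr(bm, "occupied") <- occ
    runs[[run]] <- bm
  }
  runs
}

#' Refine an averaged envelope against the data
#'
#' Restarts the annealing from the occupancy state of an averaged model at
#' low temperature, with the high-occupancy core frozen (always occupied),
#' mirroring the refinement stage that follows multi-model averaging. The
#' returned model is the best-energy state visited, so its energy never
#' exceeds the starting one.
#'
#' @param start averaged `bead_model` carrying an occupancy map (from
#'   [average_models()]).
#' @param curve the experimental [saxs_curve()].
#' @param seed RNG seed.
#' @param core_occupancy occupancy above which a site is frozen.
#' @param ... passed to [anneal_beads()].
#' @return a `bead_model` with fit attributes and `attr(, "frozen")`.
#' @export
refine_beads <- function(start, curve, seed = 1, core_occupancy = 0.7, ...) {
  sites <- attr(start, "lattice_sites")
  occ0 <- attr(start, "occupied")
  occ_w <- attr(start, "occupancy_map")
  if (is.null(sites) || is.null(occ0))
    stop("start must carry lattice attributes (use average_models output)")
  lat <- finish_lattice(unname(as.matrix(sites)), 2 * start$bead_radius,
                        start$bead_radius)
  frozen <- if (!is.null(occ_w)) occ_w >= core_occupancy & occ0
  else rep(FALSE, nrow(sites))
  res <- anneal_beads(curve, dd = 2 * max(sqrt(rowSums(sites^2))),
                      n_runs = 1, bead_radius = start$bead_radius,
                      seed = seed, t_factor = 0.05,
                      start = occ0, frozen = frozen, lattice = lat, ...)[[1]]
  attr(res, "frozen") <- frozen
  res
}
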