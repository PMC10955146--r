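#' Density grid constructor
#'
#' A regular 3-D grid of non-negative density values, defined by its origin
#' (coordinates of the first voxel center, Angstrom) and cubic voxel size.
#'
#' @param origin length-3 numeric, Angstrom.
#' @param voxel voxel edge, Angstrom, > 0.
#' @param values 3-D numeric array, finite and >= 0.
#' @return an object of class `density_grid`.
#' @export
density_grid <- function(origin, voxel, values) {
  stopifnot(length(origin) == 3, voxel > 0, length(dim(values)) == 3)
  if (any(!is.finite(values)) || any(values < 0))
    stop("density values must be finite and >= 0")
  structure(list(origin = as.numeric(origin), voxel = voxel, values = values),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("density_grid: %d x %d x %d voxels of %.1f A, integral %.4g\n",
              d[1], d[2], d[3], x$voxel, sum(x$values) * x$voxel^3))
  invisible(x)
}

# grid axes (voxel centers)
grid_axes <- function(grid) {
  d <- dim(grid$values)
  lapply(1:3, function(k) grid$origin[k] + (seq_len(d[k]) - 1) * grid$voxel)
}

# add Gaussian kernels at points (n x 3) with weights onto an array
accumulate_gaussians <- function(values, axes, voxel, pts, w, sigma) {
  cut <- 4 * sigma
  for (i in seq_len(nrow(pts))) {
    rng <- lapply(1:3, function(k) {
      which(abs(axes[[k]] - pts[i, k]) <= cut)
    })
    if (any(lengths(rng) == 0)) next
    dx <- axes[[1]][rng[[1]]] - pts[i, 1]
    dy <- axes[[2]][rng[[2]]] - pts[i, 2]
    dz <- axes[[3]][rng[[3]]] - pts[i, 3]
    gx <- exp(-dx^2 / (2 * sigma^2))
    gy <- exp(-dy^2 / (2 * sigma^2))
    gz <- exp(-dz^2 / (2 * sigma^2))
    block <- (w[i] * outer(outer(gx, gy), gz))
    values[rng[[1]], rng[[2]], rng[[3]]] <-
      values[rng[[1]], rng[[2]], rng[[3]], drop = FALSE] + block
  }
  values
}

#' Convert a bead model to a density map
#'
#' Sum of occupancy-weighted isotropic Gaussian kernels, one per bead, on a
#' regular grid padded by 3 kernel sigmas — the map form in which an
#' envelope can restrain flexible fitting.
#'
#' @param model a `bead_model` (or `atomic_model`; C-alpha positions with
#'   unit weights are used).
#' @param voxel voxel size, Angstrom.
#' @param kernel_sigma Gaussian sigma, Angstrom; default = bead radius
#'   (3 Angstrom for atomic models).
#' @param bbox optional list `(origin, dim)` to force the grid geometry
#'   (used to rasterize onto an existing grid).
#' @return a [density_grid()].
#' @export
bead_density <- function(model, voxel = 3, kernel_sigma = NULL, bbox = NULL) {
  if (inherits(model, "bead_model")) {
    pts <- model$centers; w <- model$occupancy
    sigma <- kernel_sigma %||% model$bead_radius
  } else {
    pts <- model_coords(model); w <- rep(1, nrow(pts))
    sigma <- kernel_sigma %||% 3
  }
  if (is.null(bbox)) {
    pad <- 3 * sigma
    lo <- apply(pts, 2, min) - pad
    hi <- apply(pts, 2, max) + pad
    dim3 <- pmax(ceiling((hi - lo) / voxel) + 1, 2)
    origin <- lo
  } else {
    origin <- bbox$origin
    dim3 <- bbox$dim
  }
  values <- array(0, dim = dim3)
  grid <- density_grid(origin, voxel, values)
  axes <- grid_axes(grid)
  grid$values <- accumulate_gaussians(values, axes, voxel, pts, w, sigma)
  grid
}

# trilinear interpolation of grid values at points, with analytic gradient
density_interp <- function(grid, pts) {
  d <- dim(grid$values)
  u <- sweep(pts, 2, grid$origin) / grid$voxel  # fractional voxel coords
  val <- numeric(nrow(pts))
  grad <- matrix(0, nrow(pts), 3)
  i0 <- floor(u)
  fr <- u - i0
  inside <- i0[, 1] >= 0 & i0[, 2] >= 0 & i0[, 3] >= 0 &
    i0[, 1] <= d[1] - 2 & i0[, 2] <= d[2] - 2 & i0[, 3] <= d[3] - 2
  for (p in which(inside)) {
    ix <- i0[p, 1] + 1L; iy <- i0[p, 2] + 1L; iz <- i0[p, 3] + 1L
    fx <- fr[p, 1]; fy <- fr[p, 2]; fz <- fr[p, 3]
    c000 <- grid$values[ix, iy, iz];       c100 <- grid$values[ix + 1, iy, iz]
    c010 <- grid$values[ix, iy + 1, iz];   c110 <- grid$values[ix + 1, iy + 1, iz]
    c001 <- grid$values[ix, iy, iz + 1];   c101 <- grid$values[ix + 1, iy, iz + 1]
    c011 <- grid$values[ix, iy + 1, iz + 1]; c111 <- grid$values[ix + 1, iy + 1, iz + 1]
    c00 <- c000 * (1 - fx) + c100 * fx; c10 <- c010 * (1 - fx) + c110 * fx
    c01 <- c001 * (1 - fx) + c101 * fx; c11 <- c011 * (1 - fx) + c111 * fx
    c0 <- c00 * (1 - fy) + c10 * fy; c1 <- c01 * (1 - fy) + c11 * fy
    val[p] <- c0 * (1 - fz) + c1 * fz
    ddx <- ((c100 - c000) * (1 - fy) + (c110 - c010) * fy) * (1 - fz) +
      ((c101 - c001) * (1 - fy) + (c111 - c011) * fy) * fz
    ddy <- ((c10 - c00) * (1 - fz) + (c11 - c01) * fz)
    ddz <- c1 - c0
    grad[p, ] <- c(ddx, ddy, ddz) / grid$voxel
  }
  list(value = val, grad = grad)
}

#' Cross-correlation between a density map and a model
#'
#' Pearson correlation between the target grid and the density simulated
#' from the model on the same grid, over voxels where either map exceeds 1
#' percent of its maximum (empty corners carry no shape information).
#'
#' @param grid target [density_grid()].
#' @param model `bead_model` or `atomic_model` (or an n x 3 coordinate
#'   matrix, rasterized with unit weights).
#' @param kernel_sigma kernel width used to rasterize the model.
#' @return correlation value in `[-1, 1]`.
#' @export
density_corr <- function(grid, model, kernel_sigma = NULL) {
  if (is.matrix(model))
    model <- bead_model(model, bead_radius = kernel_sigma %||% 3, tol = 2)
  sim <- bead_density(model, voxel = grid$voxel, kernel_sigma = kernel_sigma,
                      bbox = list(origin = grid$origin, dim = dim(grid$values)))
  a <- as.vector(grid$values); b <- as.vector(sim$values)
  keep <- a > 0.01 * max(a) | b > 0.01 * max(b, 1e-300)
  if (sum(keep) < 2 || stats::sd(a[keep]) == 0)
    stop("zero-variance target region: correlation undefined")
  if (stats::sd(b[keep]) == 0) return(0)  # model entirely outside the map
  stats::cor(a[keep], b[keep])
}
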