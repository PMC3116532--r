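#' Construct a density map
#'
#' Voxel grid convention (used everywhere in the package): indexing is
#' 1-based in R; the map coordinate of the center of voxel (i, j, k) is
#' `origin + (i - 1/2, j - 1/2, k - 1/2) * spacing`.
#'
#' @param values non-negative 3-D numeric array (nx x ny x nz).
#' @param origin 3-vector, Angstrom: corner of the first voxel.
#' @param spacing voxel edge length, Angstrom. A scalar for isotropic grids;
#'   a 3-vector is accepted (recorded as anisotropic) but density synthesis
#'   requires isotropic spacing.
#' @return object of class `density_map`.
#' @export
density_map <- function(values, origin = c(0, 0, 0), spacing = 1) {
  if (length(dim(values)) != 3) stop("values must be a 3-D array")
  if (any(dim(values) < 1)) stop("all map dimensions must be >= 1")
  if (any(spacing <= 0)) stop("spacing must be positive")
  if (!length(spacing) %in% c(1, 3)) stop("spacing must have length 1 or 3")
  if (any(values < 0)) stop("density values must be non-negative")
  structure(list(values = values, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "density_map: %s voxels, spacing %s A, origin (%.2f, %.2f, %.2f)\n",
    paste(dim(x$values), collapse = " x "),
    paste(format(x$spacing, digits = 4), collapse = " x "),
    x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

spacing3 <- function(map) {
  if (length(map$spacing) == 1) rep(map$spacing, 3) else map$spacing
}

#' Voxel center coordinates along one axis
#' @param map a `density_map`.
#' @param axis 1, 2 or 3.
#' @return numeric vector of center coordinates (Angstrom).
#' @export
voxel_centers <- function(map, axis) {
  sp <- spacing3(map)
  map$origin[axis] + (seq_len(dim(map$values)[axis]) - 0.5) * sp[axis]
}

same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$origin - b$origin)) < tol &&
    max(abs(spacing3(a) - spacing3(b))) < tol
}

#' Gaussian kernel parameters for density synthesis
#'
#' The per-atom kernel is `g(r) = exp(-(3 / (2 sigma^2)) * |r - r_n|^2)`,
#' truncated at `cutoff_radius`. By default `sigma = resolution / 2`, so the
#' default 2-sigma cutoff equals the nominal map resolution. If both `sigma`
#' and `resolution` are supplied, `sigma` wins.
#'
#' @param sigma Gaussian width parameter, Angstrom.
#' @param resolution nominal map resolution, Angstrom (used when `sigma` is
#'   not given).
#' @param cutoff_radius truncation radius, Angstrom (default `2 * sigma`).
#' @return object of class `kernel_params`.
#' @export
kernel_params <- function(sigma = NULL, resolution = NULL,
                          cutoff_radius = NULL) {
  if (is.null(sigma)) {
    if (is.null(resolution)) stop("give either sigma or resolution")
    sigma <- resolution / 2
  }
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(cutoff_radius)) cutoff_radius <- 2 * sigma
  if (cutoff_radius <= 0) stop("cutoff_radius must be positive")
  structure(list(sigma = sigma, cutoff_radius = cutoff_radius),
            class = "kernel_params")
}

erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' Default synthesis grid for a structure
#'
#' Bounding box of the structure padded by the kernel cutoff radius, with
#' voxel spacing `resolution / 3` unless overridden.
#'
#' @param s an `mdmd_structure`.
#' @param kernel a `kernel_params` object.
#' @param spacing voxel spacing, Angstrom (default `2 * kernel$sigma / 3`,
#'   i.e. resolution / 3 under the default sigma mapping).
#' @param pad padding added around the bounding box (default the kernel
#'   cutoff radius).
#' @return an empty (all-zero) `density_map` with the chosen geometry.
#' @export
default_grid <- function(s, kernel, spacing = NULL, pad = NULL) {
  if (is.null(spacing)) spacing <- 2 * kernel$sigma / 3
  if (is.null(pad)) pad <- kernel$cutoff_radius
  xyz <- coords(s)
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  shape <- pmax(1L, as.integer(ceiling((hi - lo) / spacing)))
  density_map(array(0, dim = shape), origin = lo, spacing = spacing)
}

#' Synthesize a simulated density map from atomic coordinates
#'
#' Each voxel receives, from every atom within `cutoff_radius` of its center,
#' the exact integral of the Gaussian kernel over the voxel volume. The
#' kernel is separable, so the integral is the product of one-dimensional
#' Gaussian-integral (erf) differences along x, y and z. Atoms contribute
#' only to voxels whose centers lie within the cutoff sphere.
#'
#' @param s an `mdmd_structure` (may be empty: yields a zero map).
#' @param grid a `density_map` supplying the target geometry (its values are
#'   ignored), or NULL for [default_grid()].
#' @param kernel a `kernel_params` object.
#' @return a `density_map` on the given geometry.
#' @export
simulate_density <- function(s, grid = NULL, kernel) {
  if (is.null(grid)) grid <- default_grid(s, kernel)
  sp <- spacing3(grid)
  if (max(sp) - min(sp) > 1e-9) {
    stop("simulate_density requires isotropic voxel spacing; resample first")
  }
  shape <- dim(grid$values)
  vals <- array(0, dim = shape)
  if (n_atoms(s) == 0) {
    return(density_map(vals, grid$origin, grid$spacing))
  }
  xyz <- coords(s)
  a <- 3 / (2 * kernel$sigma^2)
  sqa <- sqrt(a)
  pref <- sqrt(pi / a) / 2    # per-axis integral scale
  cut <- kernel$cutoff_radius
  cx <- voxel_centers(grid, 1)
  cy <- voxel_centers(grid, 2)
  cz <- voxel_centers(grid, 3)
  h <- sp[1] / 2
  inside_any <- FALSE
  for (n in seq_len(nrow(xyz))) {
    ix <- which(abs(cx - xyz[n, 1]) <= cut)
    iy <- which(abs(cy - xyz[n, 2]) <= cut)
    iz <- which(abs(cz - xyz[n, 3]) <= cut)
    if (!length(ix) || !length(iy) || !length(iz)) next
    inside_any <- TRUE
    dx <- cx[ix] - xyz[n, 1]
    dy <- cy[iy] - xyz[n, 2]
    dz <- cz[iz] - xyz[n, 3]
    gx <- pref * (erf_(sqa * (dx + h)) - erf_(sqa * (dx - h)))
    gy <- pref * (erf_(sqa * (dy + h)) - erf_(sqa * (dy - h)))
    gz <- pref * (erf_(sqa * (dz + h)) - erf_(sqa * (dz - h)))
    block <- outer(outer(gx, gy), gz)
    # spherical truncation by voxel-center distance
    r2 <- outer(outer(dx^2, dy^2, "+"), dz^2, "+")
    block[r2 > cut^2] <- 0
    vals[ix, iy, iz] <- vals[ix, iy, iz] + block
  }
  if (!inside_any) {
    warning("structure lies entirely outside the grid; returning a zero map")
  }
  density_map(vals, grid$origin, grid$spacing)
}

#' Cross-correlation coefficient between two density maps
#'
#' `CC = sum(rho_a * rho_b) / sqrt(sum(rho_a^2) * sum(rho_b^2))` over a
#' common voxel grid. No mean subtraction is applied (an unnormalized cosine
#' similarity, not a Pearson correlation), so for non-negative maps the
#' value lies in [0, 1]. Set `mean_subtract = TRUE` for the Pearson variant.
#'
#' @param map_a,map_b `density_map` objects on identical geometry.
#' @param mean_subtract subtract each map's mean first (default FALSE).
#' @return numeric scalar.
#' @export
cross_correlation <- function(map_a, map_b, mean_subtract = FALSE) {
  if (!same_geometry(map_a, map_b)) {
    stop("map geometries differ (origin/spacing/shape); ",
         "use resample_map() to put them on a common grid")
  }
  va <- as.numeric(map_a$values)
  vb <- as.numeric(map_b$values)
  if (mean_subtract) {
    va <- va - mean(va)
    vb <- vb - mean(vb)
  }
  na <- sum(va * va)
  nb <- sum(vb * vb)
  if (na == 0 || nb == 0) {
    stop("cross-correlation undefined: one of the maps is all-zero")
  }
  sum(va * vb) / sqrt(na * nb)
}

#' Resample a density map onto a new grid
#'
#' Trilinear interpolation between source voxel centers; target voxels whose
#' centers fall outside the source center lattice get 0. Non-negativity is
#' preserved (trilinear weights are convex).
#'
#' @param map a `density_map`.
#' @param target a `density_map` supplying the target geometry, or NULL to
#'   build one from `origin`, `spacing`, `shape`.
#' @param origin,spacing,shape target geometry (used when `target` is NULL).
#' @return a `density_map` on the target geometry.
#' @export
resample_map <- function(map, target = NULL, origin = NULL, spacing = NULL,
                         shape = NULL) {
  if (is.null(target)) {
    if (is.null(origin) || is.null(spacing) || is.null(shape)) {
      stop("give a target map or origin + spacing + shape")
    }
    target <- density_map(array(0, dim = shape), origin, spacing)
  }
  if (same_geometry(map, target)) {
    return(density_map(map$values, map$origin, map$spacing))
  }
  src_sp <- spacing3(map)
  dims <- dim(map$values)
  tc <- expand.grid(x = voxel_centers(target, 1),
                    y = voxel_centers(target, 2),
                    z = voxel_centers(target, 3))
  # fractional (1-based) source indices of the target centers
  f <- cbind((tc$x - map$origin[1]) / src_sp[1] + 0.5,
             (tc$y - map$origin[2]) / src_sp[2] + 0.5,
             (tc$z - map$origin[3]) / src_sp[3] + 0.5)
  i0 <- floor(f)
  w <- f - i0
  out <- numeric(nrow(f))
  valid <- f[, 1] >= 1 & f[, 1] <= dims[1] &
    f[, 2] >= 1 & f[, 2] <= dims[2] &
    f[, 3] >= 1 & f[, 3] <= dims[3]
  if (any(valid)) {
    i0v <- i0[valid, , drop = FALSE]
    wv <- w[valid, , drop = FALSE]
    acc <- numeric(sum(valid))
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      ii <- pmin(pmax(i0v[, 1] + dx, 1), dims[1])
      jj <- pmin(pmax(i0v[, 2] + dy, 1), dims[2])
      kk <- pmin(pmax(i0v[, 3] + dz, 1), dims[3])
      wt <- (if (dx == 1) wv[, 1] else 1 - wv[, 1]) *
        (if (dy == 1) wv[, 2] else 1 - wv[, 2]) *
        (if (dz == 1) wv[, 3] else 1 - wv[, 3])
      lin <- ii + (jj - 1) * dims[1] + (kk - 1) * dims[1] * dims[2]
      acc <- acc + wt * map$values[lin]
    }
    out[valid] <- acc
  }
  density_map(array(pmax(out, 0), dim = dim(target$values)),
              target$origin, target$spacing)
}
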