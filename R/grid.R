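# Axis-aligned 3D scalar fields: container, trilinear sampling and
# central-difference gradients. Used for both atomic densities and
# electrostatic potentials.

#' Axis-aligned scalar grid
#'
#' @param counts integer vector (nx, ny, nz), each >= 2.
#' @param origin world position of grid node (1,1,1), Angstrom.
#' @param spacing per-axis node spacing, Angstrom (positive).
#' @param values numeric array of dim (nx, ny, nz), or a vector of length
#'   nx*ny*nz in x-fastest (R array) order.
#' @return Object of class \code{"scalar_grid"}.
#' @export
scalar_grid <- function(counts, origin, spacing, values) {
  counts <- as.integer(counts)
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  origin <- as.numeric(origin)
  stopifnot(length(counts) == 3, all(counts >= 2),
            length(origin) == 3, length(spacing) == 3, all(spacing > 0))
  if (length(values) != prod(counts))
    stop("value count does not equal nx*ny*nz")
  values <- array(as.numeric(values), dim = counts)
  structure(list(counts = counts, origin = origin, spacing = spacing,
                 values = values),
            class = "scalar_grid")
}

#' @export
print.scalar_grid <- function(x, ...) {
  cat(sprintf("scalar_grid %dx%dx%d, origin (%.3g, %.3g, %.3g), spacing (%.3g, %.3g, %.3g)\n",
              x$counts[1], x$counts[2], x$counts[3],
              x$origin[1], x$origin[2], x$origin[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  value range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Grid node world coordinates along one axis
#' @param grid a \code{scalar_grid}.
#' @param axis 1, 2 or 3.
#' @return numeric vector of node coordinates.
#' @export
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$counts[axis]) - 1) * grid$spacing[axis]
}

grid_max_corner <- function(grid) grid$origin + (grid$counts - 1) * grid$spacing

#' Trilinear interpolation of a scalar grid
#'
#' Standard 8-node trilinear interpolation. Points outside the grid bounds
#' yield \code{NA}, the out-of-domain signal (distinct from any field
#' value).
#'
#' @param grid a [scalar_grid()].
#' @param points a length-3 vector or an n x 3 matrix of world coordinates.
#' @return numeric vector of interpolated values (NA outside the domain).
#' @export
sample_trilinear <- function(grid, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  # fractional node coordinates, 0-based
  fx <- (p[, 1] - grid$origin[1]) / grid$spacing[1]
  fy <- (p[, 2] - grid$origin[2]) / grid$spacing[2]
  fz <- (p[, 3] - grid$origin[3]) / grid$spacing[3]
  n <- grid$counts
  ok <- fx >= 0 & fx <= n[1] - 1 & fy >= 0 & fy <= n[2] - 1 &
    fz >= 0 & fz <= n[3] - 1
  ok[is.na(ok)] <- FALSE
  out <- rep(NA_real_, nrow(p))
  if (!any(ok)) return(out)
  i0 <- pmin(floor(fx[ok]), n[1] - 2); tx <- fx[ok] - i0
  j0 <- pmin(floor(fy[ok]), n[2] - 2); ty <- fy[ok] - j0
  k0 <- pmin(floor(fz[ok]), n[3] - 2); tz <- fz[ok] - k0
  v <- grid$values
  idx <- function(di, dj, dk) cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)
  out[ok] <-
    v[idx(0, 0, 0)] * (1 - tx) * (1 - ty) * (1 - tz) +
    v[idx(1, 0, 0)] * tx       * (1 - ty) * (1 - tz) +
    v[idx(0, 1, 0)] * (1 - tx) * ty       * (1 - tz) +
    v[idx(1, 1, 0)] * tx       * ty       * (1 - tz) +
    v[idx(0, 0, 1)] * (1 - tx) * (1 - ty) * tz +
    v[idx(1, 0, 1)] * tx       * (1 - ty) * tz +
    v[idx(0, 1, 1)] * (1 - tx) * ty       * tz +
    v[idx(1, 1, 1)] * tx       * ty       * tz
  out
}

#' Central-difference gradient of a scalar grid
#'
#' Gradient of the trilinear interpolant by central differences with a
#' step of half the local spacing per axis. Points closer than one step to
#' the domain boundary yield a row of \code{NA} (out-of-domain signal).
#'
#' @param grid a [scalar_grid()].
#' @param points a length-3 vector or an n x 3 matrix of world coordinates.
#' @return n x 3 matrix of gradient components (NA rows outside).
#' @export
gradient_at <- function(grid, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  h <- grid$spacing / 2
  g <- matrix(NA_real_, nrow(p), 3)
  for (ax in 1:3) {
    dp <- matrix(0, nrow(p), 3); dp[, ax] <- h[ax]
    g[, ax] <- (sample_trilinear(grid, p + dp) -
                  sample_trilinear(grid, p - dp)) / (2 * h[ax])
  }
  g[!stats::complete.cases(g), ] <- NA_real_
  g
}
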