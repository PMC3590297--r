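# Gaussian atomic density grids. Each atom contributes
#   exp(B * (d^2 / r^2 - 1))
# so an isolated atom's density equals exactly 1 at distance r, making the
# default iso level of 1 reproduce the atom's radius.

#' Molecular-surface parameters
#'
#' @param blobbiness negative Gaussian exponent scale B; more negative
#'   gives tighter, less blobby surfaces.
#' @param iso_level density threshold at which the surface is extracted.
#' @param spacing grid spacing h, Angstrom per cell.
#' @param padding margin added around the atom bounding box, Angstrom.
#' @param cutoff_mult Gaussian truncation radius in units of the atom
#'   radius.
#' @param max_cells guard against accidental huge grids; exceeding it is
#'   an error advising a larger spacing.
#' @return list of class \code{"surface_params"}.
#' @export
surface_params <- function(blobbiness = -2.0, iso_level = 1.0, spacing = 0.5,
                           padding = 3.0, cutoff_mult = 3.0,
                           max_cells = 1.5e7) {
  stopifnot(blobbiness < 0, iso_level > 0, spacing > 0, padding >= 0,
            cutoff_mult > 1)
  structure(list(blobbiness = blobbiness, iso_level = iso_level,
                 spacing = spacing, padding = padding,
                 cutoff_mult = cutoff_mult, max_cells = max_cells),
            class = "surface_params")
}

#' Compute a Gaussian atomic density grid
#'
#' Sums per-atom Gaussians \code{exp(B * (d_i^2 / r_i^2 - 1))} on a grid
#' spanning the atom bounding box plus padding. Contributions are
#' truncated beyond \code{cutoff_mult * r_i}, so each atom touches only a
#' local block of cells and the build stays linear in atom count.
#'
#' @param structure a [mol_structure()] with at least one atom.
#' @param radii per-atom radii, Angstrom (see [assign_radii()]).
#' @param params a [surface_params()].
#' @return A [scalar_grid()].
#' @export
compute_density_grid <- function(structure, radii = NULL,
                                 params = surface_params()) {
  stopifnot(inherits(structure, "mol_structure"),
            inherits(params, "surface_params"))
  n_atoms <- nrow(structure$atoms)
  if (n_atoms == 0L) stop("cannot build a density grid for an empty structure")
  if (is.null(radii)) radii <- assign_radii(structure, scheme = "vdw")
  radii <- as.numeric(radii)
  stopifnot(length(radii) == n_atoms, all(radii > 0))

  xyz <- atom_coords(structure)
  h <- params$spacing
  lo <- apply(xyz, 2, min) - params$padding
  hi <- apply(xyz, 2, max) + params$padding
  counts <- pmax(2L, as.integer(ceiling((hi - lo) / h)) + 1L)
  if (prod(counts) > params$max_cells)
    stop(sprintf(paste0("density grid would need %.3g cells ",
                        "(limit %.3g): increase the grid spacing"),
                 prod(counts), params$max_cells))
  vals <- array(0, dim = counts)
  axx <- lo[1] + (seq_len(counts[1]) - 1) * h
  axy <- lo[2] + (seq_len(counts[2]) - 1) * h
  axz <- lo[3] + (seq_len(counts[3]) - 1) * h
  B <- params$blobbiness

  for (a in seq_len(n_atoms)) {
    r <- radii[a]
    cut <- params$cutoff_mult * r
    i_rng <- range_idx(axx, xyz[a, 1], cut)
    j_rng <- range_idx(axy, xyz[a, 2], cut)
    k_rng <- range_idx(axz, xyz[a, 3], cut)
    if (is.null(i_rng) || is.null(j_rng) || is.null(k_rng)) next
    dx2 <- (axx[i_rng] - xyz[a, 1])^2
    dy2 <- (axy[j_rng] - xyz[a, 2])^2
    dz2 <- (axz[k_rng] - xyz[a, 3])^2
    d2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
    contrib <- exp(B * (d2 / r^2 - 1))
    contrib[d2 > cut^2] <- 0
    vals[i_rng, j_rng, k_rng] <- vals[i_rng, j_rng, k_rng] + contrib
  }
  scalar_grid(counts, lo, h, vals)
}

range_idx <- function(axis, center, cut) {
  i <- which(axis >= center - cut & axis <= center + cut)
  if (length(i) == 0L) NULL else i
}

#' Build a molecular surface mesh
#'
#' Convenience wrapper: Gaussian density grid followed by marching cubes
#' at the configured iso level.
#'
#' @param structure a [mol_structure()].
#' @param radii per-atom radii (default: van der Waals).
#' @param params a [surface_params()].
#' @return A [triangle_mesh()] with normals.
#' @export
molecular_surface <- function(structure, radii = NULL,
                              params = surface_params()) {
  grid <- compute_density_grid(structure, radii, params)
  marching_cubes(grid, params$iso_level)
}
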