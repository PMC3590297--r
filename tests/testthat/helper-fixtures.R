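# Shared helpers for the test suite: tiny structure builders and
# independent oracles kept deliberately separate from the package
# implementation paths they check.

single_atom_structure <- function(pos = c(0, 0, 0), element = "C") {
  mol_structure(data.frame(
    serial = 1L, name = paste0(element, "1"), element = element,
    alt_loc = "", res_name = "LIG", chain = "A", res_id = 1L, insertion = "",
    x = pos[1], y = pos[2], z = pos[3], occupancy = 1, is_hetero = FALSE,
    stringsAsFactors = FALSE))
}

atoms_structure <- function(xyz, elements = "C") {
  n <- nrow(xyz)
  if (length(elements) == 1L) elements <- rep(elements, n)
  mol_structure(data.frame(
    serial = seq_len(n), name = paste0(elements, seq_len(n)),
    element = elements, alt_loc = "", res_name = "LIG", chain = "A",
    res_id = 1L, insertion = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, is_hetero = FALSE, stringsAsFactors = FALSE))
}

# brute-force all-pairs bond detection: the oracle for the spatial hash
brute_force_bonds <- function(structure, table = element_table(),
                              params = bond_params()) {
  xyz <- atom_coords(structure)
  n <- nrow(xyz)
  rc <- table[ifelse(toupper(structure$atoms$element) %in% rownames(table),
                     toupper(structure$atoms$element), "X"), "covalent"]
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    if (d > params$min_dist && d <= rc[i] + rc[j] + params$tolerance)
      out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2) else out
}

# how many faces share each mesh edge (a closed mesh is all 2s)
edge_share_counts <- function(mesh) {
  f <- mesh$faces
  ek <- c(paste(pmin(f[, 1], f[, 2]), pmax(f[, 1], f[, 2])),
          paste(pmin(f[, 2], f[, 3]), pmax(f[, 2], f[, 3])),
          paste(pmin(f[, 1], f[, 3]), pmax(f[, 1], f[, 3])))
  table(table(ek))
}

mesh_face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  u <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  w <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}

# uniform-field grid phi = a.x + b.y + c.z on an n^3 grid
linear_potential_grid <- function(coef = c(1, 0, 0), n = 17, extent = 16) {
  ax <- seq(-extent / 2, extent / 2, length.out = n)
  h <- ax[2] - ax[1]
  vals <- outer(outer(coef[1] * ax, coef[2] * ax, `+`), coef[3] * ax, `+`)
  scalar_grid(rep(n, 3), rep(-extent / 2, 3), rep(h, 3), vals)
}

# nearest-hit parameter by dense sign-change bracketing plus bisection:
# the independent oracle for analytic ray-quadric intersection
bisect_ray_hit <- function(q, origin, dir, t_max = 50, n_samples = 1e5,
                           tol = 1e-10) {
  ts <- seq(1e-9, t_max, length.out = n_samples)
  pts <- matrix(origin, n_samples, 3, byrow = TRUE) + outer(ts, dir)
  vals <- quadric_value(q, pts)
  ok <- rep(TRUE, n_samples)
  if (q$kind == "hyperboloid") {
    xl <- (pts - matrix(q$frame_origin, n_samples, 3, byrow = TRUE)) %*%
      q$frame_rot[1, ]
    ok <- xl >= q$x_bounds[1] & xl <= q$x_bounds[2]
  }
  sgn <- sign(vals)
  cross <- which(sgn[-1] * sgn[-n_samples] < 0 & ok[-1] & ok[-n_samples])
  if (length(cross) == 0L) return(NULL)
  lo <- ts[cross[1]]; hi <- ts[cross[1] + 1]
  f <- function(t) quadric_value(q, origin + t * dir)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# minimum distance from the hyperboloid profile curve to a sphere surface
# (center on the bond axis at x = cx, radius r): coarse scan refined
# around the best abscissa so the floor is set by the geometry, not the
# sampling density
tangency_residual <- function(gm, cx, r) {
  prof <- function(xs) {
    rho <- sqrt(gm$waist_radius^2 + gm$curvature * (xs - gm$waist_center)^2)
    abs(sqrt((xs - cx)^2 + rho^2) - r)
  }
  span <- gm$x_j_t - gm$x_i_t
  xs <- seq(gm$x_i_t - 0.1 * span, gm$x_j_t + 0.1 * span, length.out = 4000)
  d <- prof(xs)
  x0 <- xs[which.min(d)]
  dx <- xs[2] - xs[1]
  fine <- seq(x0 - 2 * dx, x0 + 2 * dx, length.out = 8000)
  min(prof(fine))
}

# a random pair of spheres with guaranteed external tangency for the
# requested shrink: the centers are separated beyond both radii
random_bond_case <- function() {
  r_i <- runif(1, 0.4, 1.2); r_j <- runif(1, 0.4, 1.2)
  p_i <- rnorm(3, sd = 2)
  dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
  D <- r_i + r_j + runif(1, 0.2, 2)
  list(p_i = p_i, r_i = r_i, p_j = p_i + D * dir, r_j = r_j,
       shrink = runif(1, 0, 0.8), center = p_i + D / 2 * dir)
}

# a ray from a random stand-off point aimed near a target, so most rays
# actually intersect the primitive under test
aimed_ray <- function(target, jitter = 0.6) {
  o <- target + runif(1, 4, 9) * {
    u <- rnorm(3); u / sqrt(sum(u^2))
  }
  d <- target + rnorm(3, sd = jitter) - o
  list(origin = o, dir = d / sqrt(sum(d^2)))
}
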