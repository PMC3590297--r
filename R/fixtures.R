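# Synthetic-data generators: every pipeline stage is testable without any
# download or external tool. All randomized generators are seeded and
# pure given (parameters, seed); analytic point-charge/dipole potentials
# stand in for solver-produced electrostatic grids.

make_atom_df <- function(xyz, element = "C", res_name = "LIG") {
  n <- nrow(xyz)
  data.frame(serial = seq_len(n),
             name = paste0(element, seq_len(n)),
             element = rep(element, n),
             alt_loc = "", res_name = res_name, chain = "A",
             res_id = 1L, insertion = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             occupancy = 1, is_hetero = FALSE,
             stringsAsFactors = FALSE)
}

#' Two-atom fixture
#'
#' Two carbon-like atoms on the x axis at distance d; the requested radii
#' are attached as the \code{"radii"} attribute for use with the uniform
#' radius scheme.
#'
#' @param d interatomic distance, Angstrom (> 0).
#' @param r_i,r_j display radii, Angstrom.
#' @return A [mol_structure()].
#' @export
make_diatomic <- function(d = 1.5, r_i = 0.5, r_j = 0.5) {
  stopifnot(d > 0, r_i > 0, r_j > 0)
  s <- mol_structure(make_atom_df(rbind(c(0, 0, 0), c(d, 0, 0))),
                     source_id = "diatomic")
  attr(s, "radii") <- c(r_i, r_j)
  s
}

#' Collinear chain fixture
#'
#' @param n number of atoms (>= 1).
#' @param spacing distance between neighbors, Angstrom.
#' @return A [mol_structure()] of n carbon-like atoms along x.
#' @export
make_chain <- function(n = 5L, spacing = 1.5) {
  stopifnot(n >= 1, spacing > 0)
  xyz <- cbind((seq_len(n) - 1) * spacing, 0, 0)
  mol_structure(make_atom_df(xyz), source_id = "chain")
}

#' Analytic point-charge potential grid
#'
#' Samples phi(x) = q / |x - x_c| on an n^3 grid spanning
#' [-extent/2, extent/2]^3. The charge sits at the cell center nearest
#' the origin, plus a small epsilon, so no grid node coincides with the
#' singularity. The charge position is attached as attribute
#' \code{"charge_pos"}.
#'
#' @param q charge (arbitrary units).
#' @param n nodes per axis (>= 8).
#' @param extent edge length of the cubic domain, Angstrom.
#' @return A [scalar_grid()].
#' @export
make_point_charge_grid <- function(q = 1, n = 32L, extent = 20) {
  stopifnot(n >= 8, extent > 0)
  h <- extent / (n - 1)
  origin <- rep(-extent / 2, 3)
  # cell center nearest the domain center: a half-integer lattice
  # position, so no grid node ever touches the singularity
  xc <- rep(origin[1] + (floor((n - 1) / 2) + 0.5) * h, 3)
  ax <- origin[1] + (seq_len(n) - 1) * h
  d2 <- outer(outer((ax - xc[1])^2, (ax - xc[2])^2, `+`), (ax - xc[3])^2, `+`)
  g <- scalar_grid(rep(n, 3), origin, rep(h, 3), q / sqrt(d2))
  attr(g, "charge_pos") <- xc
  g
}

#' Analytic dipole potential grid
#'
#' Superposition of +q and -q point potentials separated along x. Both
#' charges sit at cell centers (the requested separation is snapped to a
#' whole number of cells), so no grid node touches a singularity and the
#' sampled grid is exactly antisymmetric under inversion through the
#' dipole midpoint. Charge positions are attached as attribute
#' \code{"charge_pos"} (rows +q, -q).
#'
#' @param q charge magnitude.
#' @param separation distance between the charges, Angstrom (snapped to
#'   the grid).
#' @param n nodes per axis (>= 8).
#' @param extent edge length of the cubic domain, Angstrom.
#' @return A [scalar_grid()].
#' @export
make_dipole_grid <- function(q = 1, separation = 6, n = 32L, extent = 20) {
  stopifnot(n >= 8, extent > 0, separation > 0, separation < extent)
  h <- extent / (n - 1)
  origin <- rep(-extent / 2, 3)
  off <- origin[1] + (floor((n - 1) / 2) + 0.5) * h   # central cell center
  half_cells <- max(1L, round(separation / (2 * h)))
  xp <- c(off + half_cells * h, off, off)
  xm <- c(off - half_cells * h, off, off)
  ax <- origin[1] + (seq_len(n) - 1) * h
  pot <- function(xc) {
    d2 <- outer(outer((ax - xc[1])^2, (ax - xc[2])^2, `+`), (ax - xc[3])^2, `+`)
    1 / sqrt(d2)
  }
  g <- scalar_grid(rep(n, 3), origin, rep(h, 3), q * pot(xp) - q * pot(xm))
  attr(g, "charge_pos") <- rbind(xp, xm)
  g
}

#' Seeded random network fixture
#'
#' A G(n, m) random graph with m = round(n * mean_degree / 2) edges,
#' positions from a seeded uniform 2D scatter, radii proportional to node
#' degree (mimicking connectivity-based sizing) and colors from a seeded
#' palette. Serializable with [write_xgmml()] for parser round trips;
#' identical seeds give identical graphs.
#'
#' @param n_nodes number of nodes (>= 1).
#' @param mean_degree target mean degree.
#' @param seed RNG seed.
#' @return A [network_graph()].
#' @export
make_random_network <- function(n_nodes = 20L, mean_degree = 3, seed = 1L) {
  stopifnot(n_nodes >= 1, mean_degree >= 0)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  set.seed(seed)
  rng <- list(xy = matrix(stats::runif(2 * n_nodes, -10, 10), ncol = 2),
              col = matrix(stats::runif(3 * n_nodes, 0.2, 1), ncol = 3),
              perm = sample.int(max(1L, n_nodes * (n_nodes - 1L) / 2L)))
  m_max <- n_nodes * (n_nodes - 1L) / 2L
  m <- min(m_max, round(n_nodes * mean_degree / 2))
  pairs <- if (m_max > 0) {
    all_pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    all_pairs[rng$perm[seq_len(m)], , drop = FALSE]
  } else matrix(integer(0), ncol = 2)
  ids <- sprintf("n%03d", seq_len(n_nodes))
  deg <- tabulate(c(pairs[, 1], pairs[, 2]), nbins = n_nodes)
  nodes <- data.frame(id = ids, label = paste0("node ", seq_len(n_nodes)),
                      x = rng$xy[, 1], y = rng$xy[, 2],
                      radius = 0.5 + 0.25 * deg,
                      r = rng$col[, 1], g = rng$col[, 2], b = rng$col[, 3],
                      z = 0, stringsAsFactors = FALSE)
  edges <- data.frame(source = ids[pairs[, 1]], target = ids[pairs[, 2]],
                      stringsAsFactors = FALSE)
  network_graph(nodes, edges)
}

#' Procedural lit-sphere textures
#'
#' Deterministic stand-ins for photographed or painted lit spheres:
#' \describe{
#'   \item{gradient}{vertical brightness gradient (every row constant).}
#'   \item{checker}{polar checkerboard over the inscribed disk.}
#'   \item{hemilight}{a Lambert-lit hemisphere baked into the disk
#'     (headlight at +z, so the center pixel is brightest).}
#' }
#'
#' @param kind one of "gradient", "checker", "hemilight".
#' @param size texture edge length in pixels (>= 16).
#' @return A [litsphere_texture()].
#' @export
make_litsphere <- function(kind = c("hemilight", "gradient", "checker"),
                           size = 128L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  stopifnot(size >= 16)
  rowv <- matrix((seq_len(size) - 0.5) / size, size, size)        # v down
  colu <- matrix((seq_len(size) - 0.5) / size, size, size, byrow = TRUE)
  nx <- 2 * colu - 1
  ny <- 1 - 2 * rowv
  rr <- sqrt(nx^2 + ny^2)
  px <- array(0, dim = c(size, size, 3))
  if (kind == "gradient") {
    g <- 1 - rowv
    for (ch in 1:3) px[, , ch] <- g
  } else if (kind == "checker") {
    theta <- atan2(ny, nx)
    cells <- (floor(4 * (rr + 1)) + floor(theta / (pi / 4))) %% 2
    val <- ifelse(rr <= 1, 0.15 + 0.7 * cells, 0)
    for (ch in 1:3) px[, , ch] <- val
    px[, , 1] <- px[, , 1] * 1.0
    px[, , 3] <- px[, , 3] * 0.6
  } else {
    nz2 <- pmax(0, 1 - rr^2)
    lam <- sqrt(nz2)                 # headlight dot product
    val <- ifelse(rr <= 1, 0.08 + 0.92 * lam, 0)
    px[, , 1] <- val
    px[, , 2] <- val * 0.95
    px[, , 3] <- val * 0.85
  }
  litsphere_texture(px)
}
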