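# Classic 256-case marching cubes. The per-configuration triangle table is
# derived constructively at first use rather than transcribed: for every
# corner sign pattern, intersected cube edges are linked into polygons by
# pairing them on each cube face (with the pairing for the ambiguous
# 4-intersection face chosen to isolate the inside corners, a rule that
# depends only on the face's own corner signs and is therefore seen
# identically from both adjacent cells -- making meshes watertight), then
# oriented so triangle normals point toward decreasing field values and
# fan-triangulated.

# Cube corners 1..8 (unit cube), standard marching-cubes numbering.
MC_CORNERS <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# Edges 1..12 as corner index pairs.
MC_EDGES <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1),
                  c(5, 6), c(6, 7), c(7, 8), c(8, 5),
                  c(1, 5), c(2, 6), c(3, 7), c(4, 8))

# Faces: 4 corners in cyclic order; edge k of a face joins corner k and
# corner k+1 (cyclically).
MC_FACES <- list(
  list(corners = c(1, 2, 3, 4), edges = c(1, 2, 3, 4)),
  list(corners = c(5, 6, 7, 8), edges = c(5, 6, 7, 8)),
  list(corners = c(1, 2, 6, 5), edges = c(1, 10, 5, 9)),
  list(corners = c(4, 3, 7, 8), edges = c(3, 11, 7, 12)),
  list(corners = c(1, 4, 8, 5), edges = c(4, 12, 8, 9)),
  list(corners = c(2, 3, 7, 6), edges = c(2, 11, 6, 10)))

.mc_env <- new.env(parent = emptyenv())

# Triangle table: list of 256 integer matrices (rows = triangles, entries
# = edge ids 1..12). Config index = 1 + sum over inside corners of 2^(k-1).
mc_triangle_table <- function() {
  if (!is.null(.mc_env$tri_table)) return(.mc_env$tri_table)
  tab <- vector("list", 256)
  for (cfg in 0:255) {
    inside <- bitwAnd(cfg, 2L^(0:7)) > 0L
    tab[[cfg + 1L]] <- mc_case_triangles(inside)
  }
  .mc_env$tri_table <- tab
  tab
}

mc_case_triangles <- function(inside) {
  cut <- inside[MC_EDGES[, 1]] != inside[MC_EDGES[, 2]]
  if (!any(cut)) return(matrix(integer(0), ncol = 3))
  # segments on faces: pairs of intersected edges that should be joined
  segs <- list()
  for (f in MC_FACES) {
    fc <- inside[f$corners]
    fe_cut <- which(fc != fc[c(2, 3, 4, 1)])  # face-edge slots intersected
    if (length(fe_cut) == 2L) {
      segs[[length(segs) + 1L]] <- f$edges[fe_cut]
    } else if (length(fe_cut) == 4L) {
      # ambiguous face (alternating signs): isolate each inside corner --
      # corner k is flanked by face-edge slots k-1 and k
      for (k in which(fc)) {
        prev <- if (k == 1L) 4L else k - 1L
        segs[[length(segs) + 1L]] <- f$edges[c(prev, k)]
      }
    }
  }
  # walk cycles in the segment graph (every intersected edge has degree 2)
  segm <- do.call(rbind, segs)
  tris <- list()
  visited <- rep(FALSE, nrow(segm))
  repeat {
    s0 <- which(!visited)[1]
    if (is.na(s0)) break
    cyc <- segm[s0, ]
    visited[s0] <- TRUE
    repeat {
      last <- cyc[length(cyc)]
      nxt <- which(!visited & (segm[, 1] == last | segm[, 2] == last))[1]
      if (is.na(nxt)) break
      visited[nxt] <- TRUE
      nb <- setdiff(segm[nxt, ], last)
      if (nb == cyc[1]) break
      cyc <- c(cyc, nb)
    }
    cyc <- mc_orient_cycle(cyc, inside)
    for (k in seq_len(length(cyc) - 2L))
      tris[[length(tris) + 1L]] <- c(cyc[1], cyc[k + 1L], cyc[k + 2L])
  }
  do.call(rbind, tris)
}

# Orient a polygon (cycle of edge ids) so its Newell normal points away
# from the inside (high-value) corners of its own edges.
mc_orient_cycle <- function(cyc, inside) {
  pts <- (MC_CORNERS[MC_EDGES[cyc, 1], , drop = FALSE] +
            MC_CORNERS[MC_EDGES[cyc, 2], , drop = FALSE]) / 2
  m <- nrow(pts)
  nrm <- c(0, 0, 0)
  for (k in seq_len(m)) {
    a <- pts[k, ]; b <- pts[if (k == m) 1L else k + 1L, ]
    nrm <- nrm + cross3(a, b)
  }
  in_corner <- ifelse(inside[MC_EDGES[cyc, 1]], MC_EDGES[cyc, 1],
                      MC_EDGES[cyc, 2])
  to_inside <- colMeans(MC_CORNERS[in_corner, , drop = FALSE]) - colMeans(pts)
  if (sum(nrm * to_inside) > 0) rev(cyc) else cyc
}

# Local edge -> (node offset of the edge's lower corner, axis).
MC_EDGE_NODE <- rbind(
  c(0, 0, 0, 1), c(1, 0, 0, 2), c(0, 1, 0, 1), c(0, 0, 0, 2),
  c(0, 0, 1, 1), c(1, 0, 1, 2), c(0, 1, 1, 1), c(0, 0, 1, 2),
  c(0, 0, 0, 3), c(1, 0, 0, 3), c(1, 1, 0, 3), c(0, 1, 0, 3))

#' Extract an isosurface by marching cubes
#'
#' Classic table-driven marching cubes on a scalar grid. Each surface
#' vertex lies on a grid edge whose endpoint values straddle
#' \code{iso_level}, placed by linear interpolation
#' \code{t = (iso - v_a) / (v_b - v_a)}. Triangles are wound so normals
#' point toward decreasing field values (outward for a density blob);
#' per-vertex normals are the normalized negative field gradient.
#' Vertices are shared between cells, so blobs fully inside the grid give
#' closed meshes. An iso level outside the grid's value range yields an
#' empty mesh.
#'
#' @param grid a [scalar_grid()].
#' @param iso_level the threshold value.
#' @return A [triangle_mesh()] with per-vertex normals.
#' @export
marching_cubes <- function(grid, iso_level) {
  stopifnot(inherits(grid, "scalar_grid"), is.finite(iso_level))
  v <- grid$values
  n <- grid$counts
  if (iso_level >= max(v) || iso_level <= min(v))
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3)))
  inside <- v > iso_level

  ii <- seq_len(n[1] - 1L); jj <- seq_len(n[2] - 1L); kk <- seq_len(n[3] - 1L)
  cfg <- array(0L, dim = n - 1L)
  bits <- list(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(0L, 1L, 0L),
               c(0L, 0L, 1L), c(1L, 0L, 1L), c(1L, 1L, 1L), c(0L, 1L, 1L))
  for (b in seq_along(bits)) {
    o <- bits[[b]]
    cfg <- cfg + (2L^(b - 1L)) * inside[ii + o[1], jj + o[2], kk + o[3]]
  }
  active <- which(cfg > 0L & cfg < 255L)
  if (length(active) == 0L)
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3)))

  tab <- mc_triangle_table()
  nc <- n - 1L
  a0 <- active - 1L
  ci <- a0 %% nc[1]
  cj <- (a0 %/% nc[1]) %% nc[2]
  ck <- a0 %/% (nc[1] * nc[2])

  # global vertex cache: one slot per (grid node, axis)
  nn <- prod(n)
  vert_id <- integer(3L * nn)
  vx <- numeric(0); vy <- numeric(0); vz <- numeric(0)
  n_vert <- 0L
  verts_x <- numeric(512); verts_y <- numeric(512); verts_z <- numeric(512)
  tri_list <- vector("list", length(active))

  ax <- grid_axis(grid, 1); ay <- grid_axis(grid, 2); az <- grid_axis(grid, 3)
  for (t in seq_along(active)) {
    tris <- tab[[cfg[active[t]] + 1L]]
    i <- ci[t]; j <- cj[t]; k <- ck[t]
    eds <- unique(as.vector(tris))
    ids <- integer(12L)
    for (e in eds) {
      en <- MC_EDGE_NODE[e, ]
      node <- (i + en[1]) + n[1] * ((j + en[2]) + n[2] * (k + en[3]))
      slot <- node + nn * (en[4] - 1L) + 1L
      id <- vert_id[slot]
      if (id == 0L) {
        # endpoint node indices (1-based array coords)
        p1 <- c(i + en[1] + 1L, j + en[2] + 1L, k + en[3] + 1L)
        p2 <- p1; p2[en[4]] <- p2[en[4]] + 1L
        va <- v[p1[1], p1[2], p1[3]]; vb <- v[p2[1], p2[2], p2[3]]
        tt <- (iso_level - va) / (vb - va)
        pos <- c(ax[p1[1]], ay[p1[2]], az[p1[3]])
        pos[en[4]] <- pos[en[4]] + tt * grid$spacing[en[4]]
        n_vert <- n_vert + 1L
        if (n_vert > length(verts_x)) {
          verts_x <- c(verts_x, numeric(length(verts_x)))
          verts_y <- c(verts_y, numeric(length(verts_y)))
          verts_z <- c(verts_z, numeric(length(verts_z)))
        }
        verts_x[n_vert] <- pos[1]; verts_y[n_vert] <- pos[2]
        verts_z[n_vert] <- pos[3]
        vert_id[slot] <- n_vert
        id <- n_vert
      }
      ids[e] <- id
    }
    tri_list[[t]] <- matrix(ids[tris], ncol = 3)
  }
  faces <- do.call(rbind, tri_list)
  vertices <- cbind(verts_x[seq_len(n_vert)], verts_y[seq_len(n_vert)],
                    verts_z[seq_len(n_vert)])
  # When a grid node sits exactly on the iso level, edges from several
  # axes interpolate onto that node, leaving coincident vertices and
  # zero-area triangles; weld them and drop the degenerates.
  welded <- mc_weld(vertices, faces, tol = 1e-9 * max(grid$spacing))
  vertices <- welded$vertices; faces <- welded$faces
  if (nrow(faces) == 0L)
    return(triangle_mesh(matrix(numeric(0), ncol = 3),
                         matrix(integer(0), ncol = 3)))
  faces <- mc_fix_winding(grid, vertices, faces)
  normals <- mc_vertex_normals(grid, vertices, faces)
  triangle_mesh(vertices, faces, normals)
}

mc_weld <- function(vertices, faces, tol) {
  key <- paste(round(vertices[, 1] / tol), round(vertices[, 2] / tol),
               round(vertices[, 3] / tol))
  first <- match(key, key)
  newid <- match(first, sort(unique(first)))
  vertices <- vertices[sort(unique(first)), , drop = FALSE]
  faces[] <- newid[faces]
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  list(vertices = vertices, faces = faces[keep, , drop = FALSE])
}

# Enforce the winding convention geometrically: a face's right-hand
# normal must point toward decreasing field values (the outward side of a
# density blob). The per-case table gets this right for near-planar
# polygons; strongly skewed interpolated polygons can flip an individual
# fan triangle, which is corrected here from the gradient at the face
# centroid.
mc_fix_winding <- function(grid, vertices, faces) {
  ctr <- (vertices[faces[, 1], , drop = FALSE] +
            vertices[faces[, 2], , drop = FALSE] +
            vertices[faces[, 3], , drop = FALSE]) / 3
  lo <- grid$origin + grid$spacing * 0.51
  hi <- grid_max_corner(grid) - grid$spacing * 0.51
  ctr <- pmin(pmax(ctr, rep(lo, each = nrow(ctr))),
              rep(hi, each = nrow(ctr)))
  g <- gradient_at(grid, ctr)
  fn <- face_normals(vertices, faces)
  flip <- which(rowSums(fn * g) > 0)   # normal ascends the field: flip
  faces[flip, 2:3] <- faces[flip, 3:2]
  faces
}

# Normals = normalized negative gradient; points too close to the grid
# boundary for central differences are nudged inward before sampling.
mc_vertex_normals <- function(grid, vertices, faces) {
  lo <- grid$origin + grid$spacing * 0.51
  hi <- grid_max_corner(grid) - grid$spacing * 0.51
  pc <- pmin(pmax(vertices, rep(lo, each = nrow(vertices))),
             rep(hi, each = nrow(vertices)))
  g <- -gradient_at(grid, pc)
  len <- row_norms(g)
  bad <- !is.finite(len) | len < 1e-300
  if (any(bad)) {
    # fall back to area-weighted face normals
    fn <- face_normals(vertices, faces)
    acc <- matrix(0, nrow(vertices), 3)
    for (c1 in 1:3) {
      m <- rowsum(fn, faces[, c1], reorder = FALSE)
      acc[as.integer(rownames(m)), ] <- acc[as.integer(rownames(m)), ] + m
    }
    g[bad, ] <- acc[bad, ]
    len <- row_norms(g)
    len[len == 0] <- 1
  }
  g / len
}

face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  u <- b - a; w <- c_ - a
  cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
        u[, 3] * w[, 1] - u[, 1] * w[, 3],
        u[, 1] * w[, 2] - u[, 2] * w[, 1])
}
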