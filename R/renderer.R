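# Headless rendering pipeline. Quadric primitives are ray-cast per pixel
# (the point-sprite idea realized as exact analytic impostors: work is
# limited to each primitive's projected envelope); triangle meshes are
# rasterized with a z-buffer. Buffers: color, depth (camera-space
# distance, Inf = background), camera-space normal, primitive id
# (0 = background) and a cut-cap mask.

#' Camera description
#'
#' Right-handed camera space: x right, y up on screen, view direction -z.
#'
#' @param eye camera position, Angstrom.
#' @param look_at point the camera looks at.
#' @param up approximate up direction (not parallel to the view axis).
#' @param mode "orthographic" or "perspective".
#' @param ortho_half_height half the vertical extent of the orthographic
#'   frame, Angstrom.
#' @param fov_y vertical field of view, degrees (perspective).
#' @param width,height frame size in pixels.
#' @return list of class \code{"camera"}.
#' @export
camera <- function(eye = c(0, 0, 5), look_at = c(0, 0, 0), up = c(0, 1, 0),
                   mode = c("orthographic", "perspective"),
                   ortho_half_height = 2, fov_y = 40,
                   width = 256L, height = 256L) {
  mode <- match.arg(mode)
  eye <- as.numeric(eye); look_at <- as.numeric(look_at); up <- as.numeric(up)
  if (all(eye == look_at)) stop("eye and look_at coincide")
  f <- normalize(look_at - eye)
  if (vnorm(cross3(f, up)) < 1e-9) stop("up is parallel to the view direction")
  stopifnot(width >= 1, height >= 1, ortho_half_height > 0,
            fov_y > 0, fov_y < 180)
  structure(list(eye = eye, look_at = look_at, up = up, mode = mode,
                 ortho_half_height = ortho_half_height, fov_y = fov_y,
                 width = as.integer(width), height = as.integer(height)),
            class = "camera")
}

camera_basis <- function(cam) {
  f <- normalize(cam$look_at - cam$eye)
  r <- normalize(cross3(f, cam$up))
  u <- cross3(r, f)
  list(right = r, up = u, forward = f)
}

camera_half_extent <- function(cam) {
  hh <- if (cam$mode == "orthographic") cam$ortho_half_height
        else tan(cam$fov_y / 2 * pi / 180)
  c(hw = hh * cam$width / cam$height, hh = hh)
}

# screen coords of pixel centers (x right, y up)
pixel_screen_xy <- function(cam, cols, rows) {
  he <- camera_half_extent(cam)
  list(x = ((cols - 0.5) / cam$width - 0.5) * 2 * he["hw"],
       y = (0.5 - (rows - 0.5) / cam$height) * 2 * he["hh"])
}

# world point -> fractional pixel (col, row); perspective divides by depth
world_to_pixel <- function(cam, pts) {
  b <- camera_basis(cam)
  he <- camera_half_extent(cam)
  rel <- sweep(pts, 2, cam$eye)
  sx <- rel %*% b$right
  sy <- rel %*% b$up
  d <- rel %*% b$forward
  if (cam$mode == "perspective") {
    bad <- d <= 1e-9
    d[bad] <- NA
    sx <- sx / d; sy <- sy / d
  }
  list(col = (sx / (2 * he["hw"]) + 0.5) * cam$width + 0.5,
       row = (0.5 - sy / (2 * he["hh"])) * cam$height + 0.5,
       depth = d)
}

#' Render style
#'
#' @param representation "particle_spheres" (sphere impostors only,
#'   processed in chunks), "hyperballs" (spheres + bond hyperboloids) or
#'   "mesh".
#' @param shading "lambert" (headlight) or "litsphere" (matcap lookup).
#' @param litsphere_texture a lit-sphere texture (see [make_litsphere()]).
#' @param litsphere_blend fraction of flat base color blended over the
#'   texture, in [0, 1].
#' @param background RGB in [0, 1].
#' @param chunk_limit maximum particles per chunk for the
#'   particle-spheres representation.
#' @return list of class \code{"render_style"}.
#' @export
render_style <- function(representation = c("hyperballs", "particle_spheres", "mesh"),
                         shading = c("lambert", "litsphere"),
                         litsphere_texture = NULL, litsphere_blend = 0,
                         background = c(0, 0, 0), chunk_limit = 16000L) {
  representation <- match.arg(representation)
  shading <- match.arg(shading)
  stopifnot(chunk_limit >= 1, litsphere_blend >= 0, litsphere_blend <= 1)
  structure(list(representation = representation, shading = shading,
                 litsphere_texture = litsphere_texture,
                 litsphere_blend = litsphere_blend,
                 background = check_rgb(background),
                 chunk_limit = as.integer(chunk_limit)),
            class = "render_style")
}

#' Cut plane
#'
#' Fragments with \code{(p - point) . normal > 0} are discarded; the
#' exposed interior is filled flat with \code{cap_color}.
#'
#' @param point a point on the plane, Angstrom.
#' @param normal plane normal (normalized internally); the kept side
#'   satisfies \code{(p - point) . normal <= 0}.
#' @param cap_color RGB in [0, 1] for the interior fill.
#' @param enabled logical switch.
#' @return list of class \code{"cut_plane"}.
#' @export
cut_plane <- function(point = c(0, 0, 0), normal = c(0, 0, 1),
                      cap_color = c(0.8, 0.2, 0.2), enabled = TRUE) {
  structure(list(point = as.numeric(point), normal = normalize(normal),
                 cap_color = check_rgb(cap_color), enabled = isTRUE(enabled)),
            class = "cut_plane")
}

#' Split items into chunks below a particle limit
#'
#' Contiguous, ordered, non-overlapping half-open 0-based index ranges
#' covering [0, n_items): \code{ceiling(n_items / chunk_limit)} ranges,
#' every length at most \code{chunk_limit} and all lengths within 1 of
#' each other.
#'
#' @param n_items number of items (>= 0).
#' @param chunk_limit maximum items per chunk (>= 1).
#' @return matrix with columns \code{start} and \code{end} (0-based,
#'   half-open); 0 rows when \code{n_items} is 0.
#' @export
chunk_particles <- function(n_items, chunk_limit = 16000L) {
  n_items <- as.integer(n_items); chunk_limit <- as.integer(chunk_limit)
  stopifnot(n_items >= 0, chunk_limit >= 1)
  if (n_items == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  k <- as.integer(ceiling(n_items / chunk_limit))
  sizes <- rep(n_items %/% k, k)
  extra <- n_items %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  ends <- cumsum(sizes)
  cbind(start = c(0L, ends[-k]), end = ends)
}

new_frame_set <- function(cam, style) {
  H <- cam$height; W <- cam$width
  color <- array(rep(style$background, each = H * W), dim = c(H, W, 3))
  structure(list(color = color,
                 albedo = array(0, dim = c(H, W, 3)),
                 depth = matrix(Inf, H, W),
                 normal = array(0, dim = c(H, W, 3)),
                 prim_id = matrix(0L, H, W),
                 cap = matrix(FALSE, H, W),
                 camera = cam, style = style),
            class = "frame_set")
}

#' @export
print.frame_set <- function(x, ...) {
  cov <- mean(x$prim_id > 0)
  cat(sprintf("frame_set %dx%d, %.1f%% covered, %d primitives\n",
              x$camera$width, x$camera$height, 100 * cov, max(x$prim_id)))
  invisible(x)
}

LAMBERT_AMBIENT <- 0.15

#' Render a scene of quadrics and meshes
#'
#' Ray-casts each quadric inside its projected envelope, rasterizes
#' meshes with a z-buffer and barycentric normal interpolation, resolves
#' visibility with a depth test, applies the cut plane, and shades
#' (headlight Lambert, or lit-sphere when the style says so and carries a
#' texture). For the particle-spheres representation the primitive list
#' is processed chunk by chunk under \code{chunk_limit}; chunking does
#' not change the image.
#'
#' @param primitives list of [quadric()] objects.
#' @param meshes list of [triangle_mesh()] objects, or of
#'   \code{list(mesh =, color =)} pairs.
#' @param cam a [camera()].
#' @param style a [render_style()].
#' @param cut a [cut_plane()] or \code{NULL}.
#' @return A \code{frame_set} (color, albedo, depth, normal, prim_id,
#'   cap).
#' @export
render_scene <- function(primitives = list(), meshes = list(), cam = camera(),
                         style = render_style(), cut = NULL) {
  stopifnot(inherits(cam, "camera"), inherits(style, "render_style"))
  if (!is.null(cut)) stopifnot(inherits(cut, "cut_plane"))
  if (!is.null(cut) && !cut$enabled) cut <- NULL
  frames <- new_frame_set(cam, style)
  if (style$representation == "particle_spheres" &&
      any(vapply(primitives, function(q) q$kind, "") != "sphere"))
    stop("particle_spheres representation accepts sphere quadrics only")

  groups <- if (style$representation == "particle_spheres")
    chunk_particles(length(primitives), style$chunk_limit)
  else if (length(primitives)) cbind(start = 0L, end = length(primitives))
  else matrix(integer(0), ncol = 2)

  for (g in seq_len(nrow(groups))) {
    for (p in seq.int(groups[g, 1] + 1L, length.out = groups[g, 2] - groups[g, 1])) {
      frames <- raycast_quadric(frames, primitives[[p]], p, cut)
    }
  }
  next_id <- length(primitives)
  for (m in seq_along(meshes)) {
    entry <- meshes[[m]]
    mesh <- if (inherits(entry, "triangle_mesh")) entry else entry$mesh
    mcol <- if (inherits(entry, "triangle_mesh")) c(0.7, 0.7, 0.7) else entry$color
    frames <- rasterize_mesh(frames, mesh, mcol, next_id + m, cut)
  }
  if (style$shading == "litsphere" && !is.null(style$litsphere_texture))
    frames$color <- litsphere_shade(frames, style$litsphere_texture,
                                    blend = style$litsphere_blend)
  frames
}

# pixel-rect of a world-space AABB (rows lo/hi); NULL when off screen
envelope_pixels <- function(cam, env) {
  corners <- as.matrix(expand.grid(env[, 1], env[, 2], env[, 3]))
  pr <- world_to_pixel(cam, corners)
  if (any(!is.finite(pr$col)) || any(!is.finite(pr$row)))
    return(list(cols = seq_len(cam$width), rows = seq_len(cam$height)))
  c0 <- max(1L, floor(min(pr$col))); c1 <- min(cam$width, ceiling(max(pr$col)))
  r0 <- max(1L, floor(min(pr$row))); r1 <- min(cam$height, ceiling(max(pr$row)))
  if (c0 > c1 || r0 > r1) return(NULL)
  list(cols = seq.int(c0, c1), rows = seq.int(r0, r1))
}

raycast_quadric <- function(frames, q, prim_id, cut) {
  cam <- frames$camera
  rect <- envelope_pixels(cam, q$envelope %||%
                            rbind(cam$eye - 1e9, cam$eye + 1e9))
  if (is.null(rect)) return(frames)
  b <- camera_basis(cam)
  np <- length(rect$cols) * length(rect$rows)
  cols <- rep(rect$cols, each = length(rect$rows))
  rows <- rep(rect$rows, times = length(rect$cols))
  sxy <- pixel_screen_xy(cam, cols, rows)

  if (cam$mode == "orthographic") {
    O <- matrix(cam$eye, np, 3, byrow = TRUE) +
      outer(sxy$x, b$right) + outer(sxy$y, b$up)
    Dm <- matrix(b$forward, np, 3, byrow = TRUE)
  } else {
    O <- matrix(cam$eye, np, 3, byrow = TRUE)
    Dm <- matrix(b$forward, np, 3, byrow = TRUE) +
      outer(sxy$x, b$right) + outer(sxy$y, b$up)
    Dm <- Dm / row_norms(Dm)
  }
  OH <- cbind(O, 1); DH <- cbind(Dm, 0)
  QO <- OH %*% q$Q
  A <- rowSums((DH %*% q$Q) * DH)
  B <- 2 * rowSums(QO * DH)
  C <- rowSums(QO * OH)
  disc <- B^2 - 4 * A * C
  hit <- disc >= 0 & abs(A) > 1e-300
  if (!any(hit)) return(frames)
  sq <- sqrt(pmax(disc, 0))
  qq <- -(B + sign(B + (B == 0)) * sq) / 2
  t1 <- qq / A
  t2 <- ifelse(qq != 0, C / qq, NA_real_)
  tn <- pmin(t1, t2); tf <- pmax(t1, t2)

  eval_root <- function(tv) {
    ok <- hit & is.finite(tv) & tv > 1e-9
    P <- O + Dm * tv
    if (q$kind == "hyperboloid") {
      xl <- (P - matrix(q$frame_origin, np, 3, byrow = TRUE)) %*% q$frame_rot[1, ]
      ok <- ok & xl >= q$x_bounds[1] - 1e-9 & xl <= q$x_bounds[2] + 1e-9
    }
    side <- if (!is.null(cut))
      (P - matrix(cut$point, np, 3, byrow = TRUE)) %*% cut$normal
    else rep(-1, np)
    list(ok = ok, P = P, side = as.numeric(side), t = tv)
  }
  near <- eval_root(tn); far <- eval_root(tf)
  near_keep <- near$ok & near$side <= 0
  far_keep <- far$ok & far$side <= 0
  use_far <- !near_keep & far_keep
  is_cap <- use_far & near$ok & near$side > 0   # looking into the cut interior
  sel <- near_keep | use_far
  if (!any(sel)) return(frames)

  tv <- ifelse(near_keep, near$t, far$t)
  P <- near$P; P[use_far, ] <- far$P[use_far, ]
  # camera-space distance along the view axis (= t for orthographic rays)
  depth <- as.numeric((P - matrix(cam$eye, np, 3, byrow = TRUE)) %*% b$forward)

  idx <- cbind(rows, cols)
  lin <- rows + (cols - 1L) * cam$height
  win <- sel & depth < frames$depth[lin]
  if (!any(win)) return(frames)
  wi <- which(win)

  # world normals: gradient of the quadratic form, toward the ray origin
  G <- 2 * (cbind(P[wi, , drop = FALSE], 1) %*% q$Q)[, 1:3, drop = FALSE]
  G <- G / pmax(row_norms(G), 1e-300)
  flip <- rowSums(G * Dm[wi, , drop = FALSE]) > 0
  G[flip, ] <- -G[flip, ]
  capw <- is_cap[wi]
  if (any(capw)) G[capw, ] <- matrix(cut$normal, sum(capw), 3, byrow = TRUE)
  ncam <- cbind(G %*% b$right, G %*% b$up, -(G %*% b$forward))

  base <- matrix(q$color, length(wi), 3, byrow = TRUE)
  if (any(capw)) base[capw, ] <- matrix(cut$cap_color, sum(capw), 3, byrow = TRUE)
  shade <- LAMBERT_AMBIENT + (1 - LAMBERT_AMBIENT) * pmax(ncam[, 3], 0)
  colr <- base * shade
  colr[capw, ] <- base[capw, , drop = FALSE]   # cap is a flat fill

  frames$depth[lin[wi]] <- depth[wi]
  frames$prim_id[lin[wi]] <- prim_id
  frames$cap[lin[wi]] <- capw
  HW <- cam$height * cam$width
  for (ch in 1:3) {
    frames$color[lin[wi] + (ch - 1L) * HW] <- colr[, ch]
    frames$albedo[lin[wi] + (ch - 1L) * HW] <- base[, ch]
    frames$normal[lin[wi] + (ch - 1L) * HW] <- ncam[, ch]
  }
  frames
}

rasterize_mesh <- function(frames, mesh, color, prim_id, cut) {
  cam <- frames$camera
  if (nrow(mesh$faces) == 0L) return(frames)
  b <- camera_basis(cam)
  pr <- world_to_pixel(cam, mesh$vertices)
  vcol <- pr$col; vrow <- pr$row; vdep <- as.numeric(pr$depth)
  vn <- mesh$normals
  HW <- cam$height * cam$width
  for (f in seq_len(nrow(mesh$faces))) {
    vi <- mesh$faces[f, ]
    if (any(!is.finite(vcol[vi])) || any(!is.finite(vrow[vi]))) next
    x <- vcol[vi]; y <- vrow[vi]
    c0 <- max(1L, floor(min(x))); c1 <- min(cam$width, ceiling(max(x)))
    r0 <- max(1L, floor(min(y))); r1 <- min(cam$height, ceiling(max(y)))
    if (c0 > c1 || r0 > r1) next
    area <- (x[2] - x[1]) * (y[3] - y[1]) - (x[3] - x[1]) * (y[2] - y[1])
    if (abs(area) < 1e-12) next
    cols <- rep(seq.int(c0, c1), each = r1 - r0 + 1L)
    rows <- rep(seq.int(r0, r1), times = c1 - c0 + 1L)
    w1 <- ((x[2] - cols) * (y[3] - rows) - (x[3] - cols) * (y[2] - rows)) / area
    w2 <- ((x[3] - cols) * (y[1] - rows) - (x[1] - cols) * (y[3] - rows)) / area
    w3 <- 1 - w1 - w2
    inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(inside)) next
    ii <- which(inside)
    depth <- w1[ii] * vdep[vi[1]] + w2[ii] * vdep[vi[2]] + w3[ii] * vdep[vi[3]]
    Pw <- outer(w1[ii], mesh$vertices[vi[1], ]) +
      outer(w2[ii], mesh$vertices[vi[2], ]) +
      outer(w3[ii], mesh$vertices[vi[3], ])
    # face normal in world space (front = toward camera)
    e1 <- mesh$vertices[vi[2], ] - mesh$vertices[vi[1], ]
    e2 <- mesh$vertices[vi[3], ] - mesh$vertices[vi[1], ]
    fn <- cross3(e1, e2)
    fn_len <- vnorm(fn)
    if (fn_len == 0) next
    fn <- fn / fn_len
    backfacing <- sum(fn * b$forward) > 0
    capf <- rep(FALSE, length(ii))
    if (!is.null(cut)) {
      side <- (Pw - matrix(cut$point, length(ii), 3, byrow = TRUE)) %*% cut$normal
      keep <- as.numeric(side) <= 0
      if (!any(keep)) next
      ii <- ii[keep]; depth <- depth[keep]; Pw <- Pw[keep, , drop = FALSE]
      capf <- rep(backfacing, length(ii))
    } else if (backfacing) {
      # back faces still render (two-sided shading) without a cut
      capf <- rep(FALSE, length(ii))
    }
    if (is.null(vn)) {
      Nw <- matrix(fn, length(ii), 3, byrow = TRUE)
    } else {
      Nw <- outer(w1[ii], vn[vi[1], ]) + outer(w2[ii], vn[vi[2], ]) +
        outer(w3[ii], vn[vi[3], ])
      Nw <- Nw / pmax(row_norms(Nw), 1e-300)
    }
    flip <- as.numeric(Nw %*% b$forward) > 0
    Nw[flip, ] <- -Nw[flip, ]
    ncam <- cbind(Nw %*% b$right, Nw %*% b$up, -(Nw %*% b$forward))
    lin <- rows[ii] + (cols[ii] - 1L) * cam$height
    win <- depth > 0 & depth < frames$depth[lin]
    if (!any(win)) next
    wv <- which(win)
    base <- matrix(color, length(wv), 3, byrow = TRUE)
    capv <- capf[wv]
    if (any(capv)) base[capv, ] <- matrix(cut$cap_color, sum(capv), 3, byrow = TRUE)
    shade <- LAMBERT_AMBIENT + (1 - LAMBERT_AMBIENT) * pmax(ncam[wv, 3], 0)
    colr <- base * shade
    colr[capv, ] <- base[capv, , drop = FALSE]
    frames$depth[lin[wv]] <- depth[wv]
    frames$prim_id[lin[wv]] <- prim_id
    frames$cap[lin[wv]] <- capv
    for (ch in 1:3) {
      frames$color[lin[wv] + (ch - 1L) * HW] <- colr[, ch]
      frames$albedo[lin[wv] + (ch - 1L) * HW] <- base[, ch]
      frames$normal[lin[wv] + (ch - 1L) * HW] <- ncam[wv, ch]
    }
  }
  frames
}

#' Lit-sphere (matcap) shading of a rendered frame
#'
#' For every covered pixel with camera-space normal (nx, ny, nz) the
#' texture is sampled bilinearly at \code{u = (nx + 1) / 2},
#' \code{v = 1 - (ny + 1) / 2} (v flipped so texture up is screen up) and
#' blended with the pixel's flat base color:
#' \code{(1 - blend) * texture + blend * base}. Cut-cap pixels keep their
#' flat fill; background pixels keep the style background.
#'
#' @param frames a \code{frame_set} from [render_scene()].
#' @param texture a lit-sphere texture ([make_litsphere()] or
#'   [litsphere_texture()]).
#' @param base_color_by_prim optional n x 3 matrix of per-primitive base
#'   colors; default uses the albedo recorded in the frame.
#' @param blend fraction of base color in the result, [0, 1].
#' @return H x W x 3 color array.
#' @export
litsphere_shade <- function(frames, texture, base_color_by_prim = NULL,
                            blend = 0) {
  stopifnot(inherits(frames, "frame_set"),
            inherits(texture, "litsphere_texture"),
            blend >= 0, blend <= 1)
  H <- dim(frames$color)[1]; W <- dim(frames$color)[2]
  out <- frames$color
  covered <- which(frames$prim_id > 0 & !frames$cap)
  if (length(covered) == 0L) return(out)
  HW <- H * W
  nx <- frames$normal[covered]
  ny <- frames$normal[covered + HW]
  u <- (nx + 1) / 2
  v <- 1 - (ny + 1) / 2
  tex <- bilinear_texture(texture$pixels, u, v)
  base <- if (is.null(base_color_by_prim)) {
    cbind(frames$albedo[covered], frames$albedo[covered + HW],
          frames$albedo[covered + 2 * HW])
  } else {
    base_color_by_prim[frames$prim_id[covered], , drop = FALSE]
  }
  mix <- (1 - blend) * tex + blend * base
  for (ch in 1:3) out[covered + (ch - 1L) * HW] <- mix[, ch]
  out
}

# bilinear sample of an S x S x 3 texture at (u, v) in [0, 1]^2
bilinear_texture <- function(pixels, u, v) {
  S1 <- dim(pixels)[1]; S2 <- dim(pixels)[2]
  x <- pmin(pmax(u, 0), 1) * (S2 - 1) + 1   # column (u)
  y <- pmin(pmax(v, 0), 1) * (S1 - 1) + 1   # row (v)
  x0 <- pmin(floor(x), S2 - 1); y0 <- pmin(floor(y), S1 - 1)
  tx <- x - x0; ty <- y - y0
  HW <- S1 * S2
  samp <- function(r, c1, ch) pixels[r + (c1 - 1) * S1 + (ch - 1) * HW]
  out <- matrix(0, length(u), 3)
  for (ch in 1:3) {
    out[, ch] <-
      samp(y0, x0, ch) * (1 - tx) * (1 - ty) +
      samp(y0, x0 + 1, ch) * tx * (1 - ty) +
      samp(y0 + 1, x0, ch) * (1 - tx) * ty +
      samp(y0 + 1, x0 + 1, ch) * tx * ty
  }
  out
}

#' Lit-sphere texture container
#'
#' @param pixels S x S x 3 array of RGB values in [0, 1], S >= 2. The
#'   inscribed disk is the valid region (normals always map inside it).
#' @return Object of class \code{"litsphere_texture"}.
#' @export
litsphere_texture <- function(pixels) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] == dim(pixels)[2], dim(pixels)[1] >= 2,
            all(pixels >= 0), all(pixels <= 1))
  structure(list(pixels = pixels, size = dim(pixels)[1]),
            class = "litsphere_texture")
}

#' Write an RGB image to PNG
#'
#' Values are clamped to [0, 1] and quantized to 8 bits; output bytes are
#' deterministic for a given image.
#'
#' @param image H x W x 3 array in [0, 1] (or a \code{frame_set}, whose
#'   color buffer is written).
#' @param path output file path.
#' @export
write_png <- function(image, path) {
  if (inherits(image, "frame_set")) image <- image$color
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  img <- pmin(pmax(image, 0), 1)
  img <- round(img * 255) / 255
  ok <- tryCatch({png::writePNG(img, target = path); TRUE},
                 error = function(e) stop(sprintf("cannot write PNG '%s': %s",
                                                  path, conditionMessage(e)),
                                          call. = FALSE))
  invisible(path)
}

#' Read an RGB PNG into an H x W x 3 array
#'
#' @param path PNG file path.
#' @return H x W x 3 array in [0, 1] (alpha and gray channels expanded).
#' @export
read_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}
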