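# HyperBalls geometry: atoms as sphere quadrics, bonds as one-sheeted
# hyperboloids of revolution tangent to both atom spheres, with a shrink
# parameter s in [0, 1) that thins the waist from min(r_i, r_j) (s = 0,
# cylinder-like) toward a pinched two-sheet/cone limit (s -> 1). All
# quadrics use the inside-negative sign convention and are intersected by
# analytic ray casting.

#' Sphere or hyperboloid quadric
#'
#' Stores the symmetric 4x4 matrix Q of the surface \{p : p~' Q p~ = 0\}
#' in homogeneous world coordinates (inside negative), plus, for
#' hyperboloids, the rigid world-to-local frame (x along the bond axis)
#' and the local-x clip slab.
#'
#' @param Q symmetric 4x4 matrix.
#' @param kind "sphere" or "hyperboloid".
#' @param color RGB in [0, 1].
#' @param frame_rot 3x3 rotation (rows = local axes) for hyperboloids.
#' @param frame_origin world origin of the local frame.
#' @param x_bounds local-frame clip slab (x_lo, x_hi), Angstrom.
#' @param envelope world-space axis-aligned bounding box, 2 x 3 matrix
#'   (min row, max row) -- the primitive's screen-projection envelope.
#' @return Object of class \code{"quadric"}.
#' @export
quadric <- function(Q, kind = c("sphere", "hyperboloid"), color = c(0.7, 0.7, 0.7),
                    frame_rot = diag(3), frame_origin = c(0, 0, 0),
                    x_bounds = c(-Inf, Inf), envelope = NULL) {
  kind <- match.arg(kind)
  Q <- (Q + t(Q)) / 2
  if (max(abs(Q - t(Q))) > 1e-9) stop("Q must be symmetric")
  if (kind == "hyperboloid" && x_bounds[1] >= x_bounds[2])
    stop("x_bounds must satisfy x_lo < x_hi")
  structure(list(Q = Q, kind = kind, color = check_rgb(color),
                 frame_rot = frame_rot, frame_origin = as.numeric(frame_origin),
                 x_bounds = as.numeric(x_bounds), envelope = envelope),
            class = "quadric")
}

#' Evaluate a quadric at world points
#'
#' @param q a [quadric()].
#' @param points length-3 vector or n x 3 matrix.
#' @return numeric vector of p~' Q p~ values (negative inside).
#' @export
quadric_value <- function(q, points) {
  p <- if (is.matrix(points)) points else matrix(points, ncol = 3)
  ph <- cbind(p, 1)
  rowSums((ph %*% q$Q) * ph)
}

#' Sphere quadric
#'
#' Encodes |p - center|^2 - r^2 = 0; the recorded envelope is the
#' axis-aligned cube of side 2r around the center.
#'
#' @param center sphere center, Angstrom.
#' @param radius sphere radius, Angstrom (> 0).
#' @param color RGB in [0, 1].
#' @return A [quadric()] of kind "sphere".
#' @export
sphere_quadric <- function(center, radius, color = c(0.7, 0.7, 0.7)) {
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  center <- as.numeric(center)
  Q <- diag(c(1, 1, 1, sum(center^2) - radius^2))
  Q[1:3, 4] <- Q[4, 1:3] <- -center
  quadric(Q, "sphere", color,
          envelope = rbind(center - radius, center + radius))
}

#' Bond hyperboloid between two atom spheres
#'
#' In the local frame (x along the bond, origin at the first atom) the
#' surface is the revolution surface rho^2 = a^2 + c (x - x_w)^2 with
#' waist radius a = (1 - shrink) * min(r_i, r_j). The waist abscissa x_w
#' and curvature c are solved by a damped 2-unknown Newton iteration
#' (residual tolerance 1e-10) so the profile is tangent to both sphere
#' cross-sections; the quadric is clipped to the slab between the two
#' tangency abscissae, leaving the spheres to cap their own ends.
#'
#' @param p_i,p_j atom centers, Angstrom.
#' @param r_i,r_j atom radii, Angstrom (> 0).
#' @param shrink shrink factor s in [0, 1).
#' @param color RGB in [0, 1].
#' @return list with elements \code{quadric} (a [quadric()]) and
#'   \code{geometry} (class \code{"bond_geometry"}: shrink, waist_radius,
#'   waist_center, curvature, tangency abscissae x_i_t, x_j_t).
#' @export
bond_hyperboloid <- function(p_i, r_i, p_j, r_j, shrink = 0.4,
                             color = c(0.7, 0.7, 0.7)) {
  p_i <- as.numeric(p_i); p_j <- as.numeric(p_j)
  stopifnot(r_i > 0, r_j > 0, shrink >= 0, shrink < 1)
  D <- vnorm(p_j - p_i)
  if (D == 0) stop("bond endpoints coincide")
  if (D + min(r_i, r_j) <= max(r_i, r_j))
    stop("one sphere is entirely inside the other: no external tangency")
  a <- (1 - shrink) * min(r_i, r_j)

  sol <- solve_tangency(D, r_i, r_j, a)
  c_ <- sol$c; x_w <- sol$x_w
  u <- c_ / (1 + c_)
  x_i_t <- u * x_w
  x_j_t <- u * x_w + (1 - u) * D

  # local frame: x along the bond
  ex <- (p_j - p_i) / D
  ref <- if (abs(ex[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ey <- normalize(cross3(ex, ref))
  ez <- cross3(ex, ey)
  R <- rbind(ex, ey, ez)

  # local quadric: y^2 + z^2 - c (x - x_w)^2 - a^2  (inside negative)
  Ql <- diag(c(-c_, 1, 1, -(a^2 + c_ * x_w^2)))
  Ql[1, 4] <- Ql[4, 1] <- c_ * x_w
  M <- rbind(cbind(R, -R %*% p_i), c(0, 0, 0, 1))
  Qw <- t(M) %*% Ql %*% M

  rmax <- max(r_i, r_j, a)
  env_lo <- pmin(p_i, p_j) - rmax
  env_hi <- pmax(p_i, p_j) + rmax
  geom <- structure(list(shrink = shrink, waist_radius = a, waist_center = x_w,
                         curvature = c_, x_i_t = x_i_t, x_j_t = x_j_t),
                    class = "bond_geometry")
  list(quadric = quadric(Qw, "hyperboloid", color, frame_rot = R,
                         frame_origin = p_i, x_bounds = c(x_i_t, x_j_t),
                         envelope = rbind(env_lo, env_hi)),
       geometry = geom)
}

# Solve tangency of rho^2 = a^2 + c (x - x_w)^2 against both sphere
# cross-sections. With u = c / (1 + c) the residuals are
#   F1 = a^2 + u x_w^2       - r_i^2
#   F2 = a^2 + u (D - x_w)^2 - r_j^2
# A closed-form elimination gives the starting point; Newton in (c, x_w)
# polishes to 1e-10.
solve_tangency <- function(D, r_i, r_j, a, tol = 1e-10, max_iter = 60L) {
  beta <- r_i^2 - a^2
  gamma <- r_j^2 - r_i^2
  # initial guess by elimination: gamma x^2 + 2 D beta x - D^2 beta = 0
  x0 <- if (abs(gamma) < 1e-14) {
    D / 2
  } else if (beta < 1e-14) {
    0          # waist sits on the smaller sphere's center plane (s = 0)
  } else {
    disc <- (D * beta)^2 + gamma * D^2 * beta
    if (disc < 0) stop("no tangent hyperboloid exists for these spheres")
    roots <- (-D * beta + c(1, -1) * sqrt(disc)) / gamma
    inr <- roots[roots > -r_i & roots < D + r_j]
    if (length(inr) == 0) stop("no tangent hyperboloid exists for these spheres")
    inr[which.min(abs(inr - D / 2))]
  }
  u0 <- if (x0 == 0) (r_j^2 - a^2) / D^2 else beta / x0^2
  if (u0 < 0 || u0 >= 1)
    stop("no external tangency: spheres too close for this shrink")
  c0 <- u0 / (1 - u0)

  cc <- c0; xw <- x0
  for (it in seq_len(max_iter)) {
    u <- cc / (1 + cc)
    F1 <- a^2 + u * xw^2 - r_i^2
    F2 <- a^2 + u * (D - xw)^2 - r_j^2
    if (max(abs(c(F1, F2))) < tol) break
    J <- rbind(c(xw^2 / (1 + cc)^2, 2 * u * xw),
               c((D - xw)^2 / (1 + cc)^2, -2 * u * (D - xw)))
    d <- tryCatch(solve(J, -c(F1, F2)), error = function(e) NULL)
    if (is.null(d)) break
    # damping: keep c nonnegative
    lam <- 1
    while (cc + lam * d[1] < 0 && lam > 1e-6) lam <- lam / 2
    cc <- cc + lam * d[1]
    xw <- xw + lam * d[2]
    if (it == max_iter) {
      u <- cc / (1 + cc)
      F1 <- a^2 + u * xw^2 - r_i^2
      F2 <- a^2 + u * (D - xw)^2 - r_j^2
      if (max(abs(c(F1, F2))) >= tol)
        stop(sprintf(paste0("tangency solve did not converge ",
                            "(residuals %.3g, %.3g; D=%g r_i=%g r_j=%g a=%g)"),
                     F1, F2, D, r_i, r_j, a))
    }
  }
  list(c = cc, x_w = xw)
}

#' Intersect a ray with a quadric
#'
#' Substitutes the ray p(t) = origin + t * dir into the quadratic form and
#' solves for t. The nearest root with t > 0 whose point satisfies the
#' clip slab (hyperboloids) wins; when the near root is clipped the far
#' root is considered. The surface normal is the normalized spatial
#' gradient 2 (Q p~), oriented toward the ray origin.
#'
#' @param q a [quadric()].
#' @param origin ray origin, length 3.
#' @param dir unit ray direction, length 3.
#' @return list(t, point, normal) for a hit, or \code{NULL} for a miss.
#' @export
intersect_ray <- function(q, origin, dir) {
  origin <- as.numeric(origin); dir <- as.numeric(dir)
  if (abs(vnorm(dir) - 1) > 1e-9) stop("dir must be a unit vector")
  oh <- c(origin, 1); dh <- c(dir, 0)
  A <- sum(dh * (q$Q %*% dh))
  B <- 2 * sum(oh * (q$Q %*% dh))
  C <- sum(oh * (q$Q %*% oh))
  ts <- solve_quadratic(A, B, C)
  ts <- sort(ts[ts > 1e-9])
  for (t in ts) {
    p <- origin + t * dir
    if (q$kind == "hyperboloid") {
      xl <- sum(q$frame_rot[1, ] * (p - q$frame_origin))
      if (xl < q$x_bounds[1] - 1e-9 || xl > q$x_bounds[2] + 1e-9) next
    }
    g <- 2 * as.numeric(q$Q %*% c(p, 1))[1:3]
    len <- vnorm(g)
    if (len == 0) next
    n <- g / len
    if (sum(n * dir) > 0) n <- -n
    return(list(t = t, point = p, normal = n))
  }
  NULL
}

solve_quadratic <- function(A, B, C) {
  if (abs(A) < 1e-300) {
    if (abs(B) < 1e-300) return(numeric(0))
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  # numerically stable pair of roots
  qq <- -(B + sign(B + (B == 0)) * sqrt(disc)) / 2
  r1 <- qq / A
  r2 <- if (qq != 0) C / qq else -B / A - r1
  c(r1, r2)
}
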