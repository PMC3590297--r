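# Electrostatic field lines: seed selection on a surface, streamline
# advection through the potential gradient (E = -grad phi), arclength
# resampling, and the animated sinusoidal dash mask.

#' Field line container
#'
#' @param points ordered n x 3 matrix of points, Angstrom (n >= 2).
#' @return Object of class \code{"field_line"} with a cumulative
#'   \code{arclengths} table (first entry 0).
#' @export
field_line <- function(points) {
  points <- matrix(as.numeric(points), ncol = 3)
  if (nrow(points) < 2L) stop("a field line needs at least 2 points")
  if (any(!is.finite(points))) stop("field line points must be finite")
  seg <- row_norms(points[-1, , drop = FALSE] -
                     points[-nrow(points), , drop = FALSE])
  if (any(seg <= 0)) stop("field line has coincident consecutive points")
  structure(list(points = points, arclengths = c(0, cumsum(seg))),
            class = "field_line")
}

#' Field line set
#'
#' @param lines list of [field_line()] objects.
#' @param source free-text provenance tag.
#' @return Object of class \code{"field_line_set"}.
#' @export
field_line_set <- function(lines = list(), source = "") {
  stopifnot(all(vapply(lines, inherits, TRUE, "field_line")))
  structure(list(lines = lines, source = source), class = "field_line_set")
}

#' @export
print.field_line_set <- function(x, ...) {
  tot <- sum(vapply(x$lines, function(l) max(l$arclengths), 0))
  cat(sprintf("field_line_set: %d lines, total length %.3g Angstrom\n",
              length(x$lines), tot))
  invisible(x)
}

#' Streamline tracing parameters
#'
#' @param step arclength step h_t, Angstrom; \code{NULL} defaults to a
#'   quarter of the grid's smallest spacing at trace time.
#' @param max_steps cap on integration steps per direction.
#' @param min_grad field magnitude below which tracing stops (field units
#'   per Angstrom).
#' @param max_length cap on the traced arclength per direction, Angstrom.
#' @param both_directions trace along +E and -E and join at the seed.
#' @param max_grad_ratio resolvability guard: tracing stops when the
#'   field magnitude changes by more than this fraction across a single
#'   step, the signature of a source/sink the grid cannot resolve
#'   (interpolated directions are meaningless inside such a region).
#' @return list of class \code{"trace_params"}.
#' @export
trace_params <- function(step = NULL, max_steps = 10000L, min_grad = 1e-6,
                         max_length = 500, both_directions = TRUE,
                         max_grad_ratio = 0.15) {
  stopifnot(is.null(step) || step > 0, max_steps >= 1, min_grad > 0,
            max_length > 0, max_grad_ratio > 0)
  structure(list(step = step, max_steps = as.integer(max_steps),
                 min_grad = min_grad, max_length = max_length,
                 both_directions = isTRUE(both_directions),
                 max_grad_ratio = max_grad_ratio),
            class = "trace_params")
}

#' Dash animation parameters
#'
#' @param wavelength spatial period lambda of the dash pattern, Angstrom.
#' @param duty fraction of each wavelength that is lit, in (0, 1].
#' @param speed dash speed f in cycles per second (the pattern advances
#'   f * lambda Angstrom per second).
#' @param width rendered line width (render units).
#' @param color RGB in [0, 1].
#' @return list of class \code{"dash_params"}.
#' @export
dash_params <- function(wavelength = 5, duty = 0.3, speed = 1, width = 1,
                        color = c(1, 1, 0.2)) {
  stopifnot(wavelength > 0, duty > 0, duty <= 1, width > 0)
  structure(list(wavelength = wavelength, duty = duty, speed = speed,
                 width = width, color = check_rgb(color)),
            class = "dash_params")
}

#' Select field-line seeds on a surface
#'
#' Candidate seeds are the surface vertices whose interpolated potential
#' magnitude reaches \code{phi_min}; they are ranked by |phi| descending
#' and greedily thinned so no two kept seeds lie closer than twice the
#' grid's mean spacing, then truncated to \code{max_lines}.
#'
#' @param surface a [triangle_mesh()] whose vertices lie inside the grid.
#' @param potential a [scalar_grid()] of electrostatic potential.
#' @param phi_min minimum |phi| for a candidate (field units).
#' @param max_lines maximum number of seeds returned.
#' @return m x 3 matrix of seed positions (0 rows when none qualify).
#' @export
select_seeds <- function(surface, potential, phi_min = 0, max_lines = 50L) {
  stopifnot(inherits(surface, "triangle_mesh"),
            inherits(potential, "scalar_grid"), max_lines >= 0)
  v <- surface$vertices
  if (nrow(v) == 0L || max_lines == 0L) return(matrix(numeric(0), ncol = 3))
  phi <- sample_trilinear(potential, v)
  cand <- which(is.finite(phi) & abs(phi) >= phi_min)
  if (length(cand) == 0L) return(matrix(numeric(0), ncol = 3))
  cand <- cand[order(-abs(phi[cand]))]
  min_sep <- 2 * mean(potential$spacing)
  kept <- integer(0)
  for (c1 in cand) {
    if (length(kept) == 0L ||
        min(row_norms(v[kept, , drop = FALSE] -
                        matrix(v[c1, ], length(kept), 3, byrow = TRUE))) >= min_sep)
      kept <- c(kept, c1)
    if (length(kept) >= max_lines) break
  }
  v[kept, , drop = FALSE]
}

#' Trace one electrostatic field line
#'
#' Integrates \code{dx/ds = E_hat(x)} with \code{E = -grad(phi)} and the
#' direction unit-normalized (arclength parameterization), by classical
#' 4th-order Runge-Kutta at fixed step. With \code{both_directions} the
#' line runs through the seed: reversed -E branch, seed, +E branch.
#' Tracing stops on domain exit, field magnitude below \code{min_grad},
#' \code{max_steps}, or \code{max_length}. A seed in a (near-)constant
#' region yields \code{NULL} ("no line"), distinct from an error.
#'
#' @param potential a [scalar_grid()] of potential phi.
#' @param seed length-3 start position inside the grid.
#' @param params a [trace_params()].
#' @return A [field_line()], or \code{NULL} when no line exists at the
#'   seed.
#' @export
trace_field_line <- function(potential, seed, params = trace_params()) {
  stopifnot(inherits(potential, "scalar_grid"), length(seed) == 3)
  h <- params$step %||% (0.25 * min(potential$spacing))
  efield <- function(p) {
    g <- gradient_at(potential, p)
    if (any(!is.finite(g))) return(NULL)
    e <- -as.numeric(g)
    len <- vnorm(e)
    if (len < params$min_grad) return(NULL)
    list(dir = e / len, mag = len)
  }
  ehat <- function(p) {
    e <- efield(p)
    if (is.null(e)) NULL else e$dir
  }
  if (is.null(ehat(seed))) return(NULL)

  march <- function(sign) {
    pts <- matrix(0, params$max_steps, 3)
    x <- as.numeric(seed)
    n_pts <- 0L
    len <- 0
    prev_dir <- NULL
    for (s in seq_len(params$max_steps)) {
      e1 <- efield(x);                    if (is.null(e1)) break
      k1 <- e1$dir
      # critical-point guard: a sharp reversal of the advected direction
      # means the line has reached a source/sink (e.g. a point charge),
      # where the interpolated field is no longer meaningful
      if (!is.null(prev_dir) && sum(k1 * prev_dir) < 0) break
      k2 <- ehat(x + sign * h / 2 * k1);  if (is.null(k2)) break
      k3 <- ehat(x + sign * h / 2 * k2);  if (is.null(k3)) break
      k4 <- ehat(x + sign * h * k3);      if (is.null(k4)) break
      step <- sign * h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (vnorm(step) < 0.05 * h) break   # stagnated (cancelling directions)
      xn <- x + step
      if (any(!is.finite(sample_trilinear(potential, xn)))) break
      e2 <- efield(xn)
      # resolvability guard: |E| changing this fast within one step means
      # the grid cannot resolve the field here (approaching a singularity)
      if (!is.null(e2) &&
          abs(e2$mag - e1$mag) > params$max_grad_ratio * e1$mag) break
      n_pts <- n_pts + 1L
      pts[n_pts, ] <- xn
      len <- len + vnorm(step)
      prev_dir <- k1
      x <- xn
      if (is.null(e2)) break              # left the gradient domain
      if (len >= params$max_length) break
    }
    pts[seq_len(n_pts), , drop = FALSE]
  }

  fwd <- march(+1)
  pts <- if (params$both_directions) {
    bwd <- march(-1)
    rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
          matrix(as.numeric(seed), 1), fwd)
  } else rbind(matrix(as.numeric(seed), 1), fwd)
  if (nrow(pts) < 2L) return(NULL)
  field_line(pts)
}

#' Trace field lines from many seeds
#'
#' @param potential a [scalar_grid()].
#' @param seeds m x 3 matrix of seed positions.
#' @param params a [trace_params()].
#' @return A [field_line_set()] (seeds yielding no line are dropped).
#' @export
trace_field_lines <- function(potential, seeds, params = trace_params()) {
  seeds <- if (is.matrix(seeds)) seeds else matrix(seeds, ncol = 3)
  lines <- list()
  for (s in seq_len(nrow(seeds))) {
    l <- trace_field_line(potential, seeds[s, ], params)
    if (!is.null(l)) lines[[length(lines) + 1L]] <- l
  }
  field_line_set(lines, source = "traced")
}

#' Resample a field line at uniform arclength
#'
#' Piecewise-linear resampling at multiples of \code{step}; both endpoints
#' are preserved and arclengths recomputed. Idempotent for a fixed step.
#'
#' @param line a [field_line()].
#' @param step target spacing, Angstrom.
#' @return A [field_line()].
#' @export
resample_arclength <- function(line, step) {
  stopifnot(inherits(line, "field_line"), step > 0)
  s <- line$arclengths
  total <- s[length(s)]
  targets <- unique(c(seq(0, total, by = step), total))
  targets <- targets[targets <= total + 1e-12]
  px <- stats::approx(s, line$points[, 1], xout = targets)$y
  py <- stats::approx(s, line$points[, 2], xout = targets)$y
  pz <- stats::approx(s, line$points[, 3], xout = targets)$y
  pts <- cbind(px, py, pz)
  # drop duplicates created when total is a multiple of step
  keep <- c(TRUE, row_norms(pts[-1, , drop = FALSE] -
                              pts[-nrow(pts), , drop = FALSE]) > 1e-12)
  field_line(pts[keep, , drop = FALSE])
}

#' Animated dash intensity along a field line
#'
#' A dash pattern of spatial period \code{wavelength} moves along the line
#' at \code{speed * wavelength} Angstrom per second. At arclength d and
#' time t the phase is \code{frac(d / lambda - f * t)}; within the first
#' \code{duty} fraction of each period the intensity is the sinusoidal
#' carrier \code{(1 + sin(2*pi*phase)) / 2}, elsewhere 0.
#'
#' @param line a [field_line()].
#' @param time animation time, seconds.
#' @param params a [dash_params()].
#' @return numeric vector of per-point intensities in [0, 1].
#' @export
dash_intensity <- function(line, time = 0, params = dash_params()) {
  stopifnot(inherits(line, "field_line"))
  phase <- (line$arclengths / params$wavelength - params$speed * time) %% 1
  carrier <- 0.5 * (1 + sin(2 * pi * phase))
  ifelse(phase < params$duty | params$duty >= 1, carrier, 0)
}
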