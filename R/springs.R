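# A simple damped spring network over a structure's bonds: headless
# deformation under user forces, per-atom potential energies and the
# white-to-black energy coloring. Integrator: semi-implicit Euler, the
# standard game-physics choice with bounded energy drift; stable for
# dt < 0.2 * sqrt(m / k).

#' Build a spring system from a bonded structure
#'
#' One spring per bond with the rest length set to the current
#' interatomic distance, so the starting state is an exact equilibrium.
#'
#' @param structure a [mol_structure()] with bonds (run [detect_bonds()]
#'   first).
#' @param stiffness uniform spring constant k (> 0).
#' @param damping velocity damping coefficient gamma (>= 0).
#' @param masses per-atom masses (default 1).
#' @return Object of class \code{"spring_system"} with fields positions,
#'   velocities, masses, springs (i, j, l0, k), damping, pinned,
#'   external_force.
#' @export
build_spring_system <- function(structure, stiffness = 1, damping = 0,
                                masses = NULL) {
  stopifnot(inherits(structure, "mol_structure"), stiffness > 0, damping >= 0)
  if (nrow(structure$bonds) == 0L)
    stop("structure has no bonds; run detect_bonds() first")
  pos <- atom_coords(structure)
  n <- nrow(pos)
  if (is.null(masses)) masses <- rep(1, n)
  stopifnot(length(masses) == n, all(masses > 0))
  i <- structure$bonds[, 1]; j <- structure$bonds[, 2]
  l0 <- row_norms(pos[j, , drop = FALSE] - pos[i, , drop = FALSE])
  if (any(l0 <= 0)) stop("bonded atoms coincide")
  structure(list(positions = pos,
                 velocities = matrix(0, n, 3),
                 masses = as.numeric(masses),
                 springs = data.frame(i = i, j = j, l0 = l0, k = stiffness),
                 damping = damping,
                 pinned = integer(0),
                 external_force = matrix(0, n, 3)),
            class = "spring_system")
}

#' @export
print.spring_system <- function(x, ...) {
  cat(sprintf("spring_system: %d atoms, %d springs, k=%.3g, gamma=%.3g, %d pinned\n",
              nrow(x$positions), nrow(x$springs), x$springs$k[1], x$damping,
              length(x$pinned)))
  invisible(x)
}

spring_forces <- function(system) {
  s <- system$springs
  d <- system$positions[s$j, , drop = FALSE] - system$positions[s$i, , drop = FALSE]
  l <- row_norms(d)
  u <- d / l
  f <- (s$k * (l - s$l0)) * u            # force on atom i, toward j when stretched
  n <- nrow(system$positions)
  F <- matrix(0, n, 3)
  acc <- rowsum(rbind(f, -f), group = c(s$i, s$j))
  F[as.integer(rownames(acc)), ] <- acc
  F + system$external_force - system$damping * system$velocities
}

#' Advance a spring system by one time step
#'
#' Semi-implicit Euler: forces (springs + external - damping) update the
#' velocities first, then positions move with the new velocities. Pinned
#' atoms never move. Stable for \code{dt < 0.2 * sqrt(m / k)}.
#'
#' @param system a [build_spring_system()] result.
#' @param dt time step (> 0).
#' @param v_ceiling instability guard: any speed above it aborts with an
#'   error advising a smaller dt.
#' @return The updated system.
#' @export
step_springs <- function(system, dt, v_ceiling = 1e6) {
  stopifnot(inherits(system, "spring_system"), dt > 0)
  F <- spring_forces(system)
  v <- system$velocities + dt * F / system$masses
  if (length(system$pinned)) v[system$pinned, ] <- 0
  if (any(!is.finite(v)) || max(abs(v)) > v_ceiling)
    stop("spring integration unstable: use a smaller dt")
  system$velocities <- v
  system$positions <- system$positions + dt * v
  system
}

#' Run several spring steps
#'
#' @param system a spring system.
#' @param n_steps number of steps.
#' @param dt time step.
#' @param record_every record positions every this many steps (0 = none).
#' @return list(system, trajectory) where trajectory is a list of
#'   position snapshots (possibly empty).
#' @export
run_springs <- function(system, n_steps, dt, record_every = 0L) {
  traj <- list()
  for (s in seq_len(n_steps)) {
    system <- step_springs(system, dt)
    if (record_every > 0L && s %% record_every == 0L)
      traj[[length(traj) + 1L]] <- system$positions
  }
  list(system = system, trajectory = traj)
}

#' Per-atom spring potential energies
#'
#' Each spring's energy \code{k (l - l0)^2 / 2} is split half to each
#' endpoint; atom energies are the sums of their halves, so the total over
#' atoms equals the total over springs exactly.
#'
#' @param system a spring system.
#' @return numeric vector of per-atom energies (>= 0).
#' @export
atom_energies <- function(system) {
  s <- system$springs
  d <- system$positions[s$j, , drop = FALSE] - system$positions[s$i, , drop = FALSE]
  e <- 0.5 * s$k * (row_norms(d) - s$l0)^2
  out <- rep(0, nrow(system$positions))
  acc <- rowsum(c(e / 2, e / 2), group = c(s$i, s$j))
  out[as.integer(rownames(acc))] <- acc
  out
}

total_energy <- function(system) {
  kin <- 0.5 * sum(system$masses * rowSums(system$velocities^2))
  kin + sum(atom_energies(system))
}

#' White-to-black energy coloring
#'
#' Gray value \code{1 - e / e_ref} clamped to [0, 1]: zero energy is
#' white, the reference energy (frame maximum by default) is black.
#'
#' @param energies per-atom energies (>= 0).
#' @param e_ref reference energy mapped to black; default is the frame
#'   maximum. All-zero energies give all white.
#' @return n x 3 matrix of gray RGB colors in [0, 1].
#' @export
energy_colors <- function(energies, e_ref = NULL) {
  stopifnot(all(energies >= 0))
  if (is.null(e_ref)) e_ref <- max(energies)
  g <- if (e_ref <= 0) rep(1, length(energies))
       else pmin(pmax(1 - energies / e_ref, 0), 1)
  cbind(g, g, g)
}

#' Write a multi-model PDB trajectory
#'
#' Positions snapshots become MODEL/ENDMDL blocks over the structure's
#' atom records.
#'
#' @param structure the [mol_structure()] the snapshots refer to.
#' @param trajectory list of n x 3 position matrices.
#' @return PDB text.
#' @export
write_multimodel_pdb <- function(structure, trajectory) {
  stopifnot(inherits(structure, "mol_structure"), length(trajectory) >= 1)
  a <- structure$atoms
  blocks <- vapply(seq_along(trajectory), function(m) {
    p <- trajectory[[m]]
    recs <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                    ifelse(a$is_hetero, "HETATM", "ATOM"),
                    a$serial, formatC(a$name, width = 4, flag = "-"),
                    a$alt_loc, a$res_name, a$chain, a$res_id, a$insertion,
                    p[, 1], p[, 2], p[, 3], a$occupancy, 0,
                    formatC(a$element, width = 2))
    paste(c(sprintf("MODEL     %4d", m), recs, "ENDMDL"), collapse = "\n")
  }, "")
  paste0(paste(blocks, collapse = "\n"), "\nEND\n")
}
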