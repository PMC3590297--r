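# Spring-network deformation: construction, integration, energies and
# the white-to-black coloring.

two_body <- function(d = 1.5, k = 1, gamma = 0) {
  build_spring_system(detect_bonds(make_diatomic(d)), stiffness = k,
                      damping = gamma)
}

test_that("construction takes rest lengths from the current geometry", {
  sys <- two_body(1.5)
  expect_equal(nrow(sys$springs), 1L)
  expect_equal(sys$springs$l0, 1.5)
  # zero net force at the start
  expect_lt(max(abs(hyperview:::spring_forces(sys))), 1e-12)
  ch <- detect_bonds(make_chain(6, 1.5))
  expect_equal(nrow(build_spring_system(ch)$springs), nrow(ch$bonds))
  expect_error(build_spring_system(make_chain(3, 10)), "detect_bonds")
})

test_that("the rest state is a fixed point of the integrator", {
  sys <- two_body()
  p0 <- sys$positions
  for (i in 1:1000) sys <- step_springs(sys, 0.05)
  expect_lt(max(abs(sys$positions - p0)), 1e-12)
  expect_lt(max(abs(sys$velocities)), 1e-12)
})

test_that("two-body oscillation frequency matches sqrt(k/mu) within 1%", {
  sys <- two_body(1.5, k = 1)
  sys$positions[2, 1] <- 1.7           # stretch by 0.2
  dt <- 0.05 * sqrt(1 / 1)
  omega_true <- sqrt(2)                # mu = 1/2 for unit masses
  n_steps <- round(50 * 2 * pi / omega_true / dt)
  gap <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    sys <- step_springs(sys, dt)
    gap[i] <- sys$positions[2, 1] - sys$positions[1, 1]
  }
  x <- gap - mean(gap)
  crossings <- which(x[-1] * x[-n_steps] < 0)
  period <- 2 * mean(diff(crossings)) * dt
  expect_lt(abs(2 * pi / period - omega_true) / omega_true, 0.01)
})

test_that("damping makes total energy non-increasing", {
  sys <- two_body(1.5, k = 2, gamma = 0.3)
  sys$positions[2, 1] <- 2.0
  e <- numeric(400)
  for (i in 1:400) {
    sys <- step_springs(sys, 0.02)
    e[i] <- hyperview:::total_energy(sys)
  }
  expect_true(all(diff(e) <= 1e-12))
})

test_that("momentum is conserved without damping, pins or external force", {
  set.seed(14)
  s <- detect_bonds(make_chain(8, 1.5))
  sys <- build_spring_system(s, stiffness = 1.5)
  sys$positions <- sys$positions + matrix(rnorm(24, sd = 0.1), ncol = 3)
  for (i in 1:1000) sys <- step_springs(sys, 0.02)
  p <- colSums(sys$masses * sys$velocities)
  expect_lt(max(abs(p)), 1e-9)
})

test_that("energy shows no secular drift over 10^4 conservative steps", {
  # semi-implicit Euler conserves a shadow energy: the true energy
  # oscillates within an O(dt * omega) band but must not drift, so the
  # time-averaged energy at the start and at the end agree
  sys <- two_body(1.5, k = 1)
  sys$positions[2, 1] <- 1.8
  dt <- 0.05 * sqrt(1 / 1)
  e <- numeric(10000)
  for (i in 1:10000) {
    sys <- step_springs(sys, dt)
    e[i] <- hyperview:::total_energy(sys)
  }
  head_mean <- mean(e[1:500])
  tail_mean <- mean(e[9501:10000])
  expect_lt(abs(tail_mean - head_mean) / head_mean, 0.01)
  # and the instantaneous energy stays inside a modest band throughout
  expect_lt(diff(range(e)) / mean(e), 0.1)
})

test_that("pinned atoms never move and instability is detected", {
  sys <- two_body(1.5, k = 1)
  sys$pinned <- 1L
  sys$external_force[2, ] <- c(5, 0, 0)
  for (i in 1:50) sys <- step_springs(sys, 0.02)
  expect_equal(unname(sys$positions[1, ]), c(0, 0, 0))
  expect_gt(sys$positions[2, 1], 1.5)
  wild <- two_body(1.5, k = 1e6)
  wild$positions[2, 1] <- 3
  expect_error({for (i in 1:100) wild <- step_springs(wild, 1)},
               "smaller dt")
})

test_that("per-atom energies split springs half-and-half", {
  sys <- two_body(1.5, k = 2)
  expect_equal(atom_energies(sys), c(0, 0))
  delta <- 0.3
  sys$positions[2, 1] <- 1.5 + delta
  e <- atom_energies(sys)
  expect_equal(e, rep(0.25 * 2 * delta^2, 2), tolerance = 1e-12)
  # totals match exactly on a larger system
  set.seed(19)
  s <- detect_bonds(make_chain(7, 1.5))
  big <- build_spring_system(s, stiffness = 1.3)
  big$positions <- big$positions + matrix(rnorm(21, sd = 0.2), ncol = 3)
  sp <- big$springs
  d <- big$positions[sp$j, ] - big$positions[sp$i, ]
  per_spring <- 0.5 * sp$k * (sqrt(rowSums(d^2)) - sp$l0)^2
  expect_equal(sum(atom_energies(big)), sum(per_spring))
})

test_that("energy colors run white to black and are monotone", {
  expect_equal(energy_colors(c(0, 0, 0)), cbind(c(1, 1, 1), 1, 1),
               ignore_attr = TRUE)
  cols <- energy_colors(c(0, 1, 4, 2))
  expect_equal(cols[1, ], c(1, 1, 1), ignore_attr = TRUE)   # rest is white
  expect_equal(cols[3, ], c(0, 0, 0), ignore_attr = TRUE)   # max is black
  e <- c(0.3, 2.2, 1.1, 0.7, 3.0)
  g <- energy_colors(e)[, 1]
  expect_true(all(diff(g[order(e)]) <= 0))
  # fixed reference scale
  expect_equal(energy_colors(c(1, 2), e_ref = 4)[, 1], c(0.75, 0.5))
})

test_that("mode-targeted excitation recovers the stiffness within 5%", {
  set.seed(27)
  k_true <- runif(1, 0.5, 3)
  n <- 6
  s <- detect_bonds(make_chain(n, 1.5))
  sys <- build_spring_system(s, stiffness = k_true)
  # longitudinal modes of the path graph: Laplacian eigenpairs
  L <- matrix(0, n, n)
  for (b in seq_len(nrow(s$bonds))) {
    i <- s$bonds[b, 1]; j <- s$bonds[b, 2]
    L[i, i] <- L[i, i] + 1; L[j, j] <- L[j, j] + 1
    L[i, j] <- L[i, j] - 1; L[j, i] <- L[j, i] - 1
  }
  eig <- eigen(L, symmetric = TRUE)
  lambda <- eig$values[n - 1]            # slowest non-rigid mode
  mode <- eig$vectors[, n - 1]
  sys$positions[, 1] <- sys$positions[, 1] + 0.05 * mode
  omega_true <- sqrt(k_true * lambda)    # unit masses
  dt <- 0.02 * sqrt(1 / k_true)
  n_steps <- round(30 * 2 * pi / omega_true / dt)
  obs <- numeric(n_steps)
  for (i in seq_len(n_steps)) {
    sys <- step_springs(sys, dt)
    obs[i] <- sum(sys$positions[, 1] * mode)
  }
  x <- obs - mean(obs)
  crossings <- which(x[-1] * x[-n_steps] < 0)
  omega_obs <- pi / (mean(diff(crossings)) * dt)
  k_hat <- omega_obs^2 / lambda
  expect_lt(abs(k_hat - k_true) / k_true, 0.05)
})

test_that("trajectories export as parseable multi-model PDB", {
  s <- detect_bonds(make_diatomic(1.5))
  sys <- build_spring_system(s)
  sys$external_force[2, ] <- c(1, 0, 0)
  res <- run_springs(sys, 40, 0.05, record_every = 10)
  expect_length(res$trajectory, 4L)
  txt <- write_multimodel_pdb(s, res$trajectory)
  first <- parse_pdb(txt)
  expect_equal(nrow(first$atoms), 2L)
  all_models <- parse_pdb(txt, pdb_policy(first_model_only = FALSE))
  expect_equal(nrow(all_models$atoms), 8L)
})
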