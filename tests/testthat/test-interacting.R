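test_that("Hertzian force: zero beyond contact, pair-antisymmetric, matches -eps dV_R/dr", {
  expect_equal(hertzianPairForce(c(2.5, 0), c(0, 0), r_c = 1, epsilon = 10),
               c(0, 0))
  f1 <- hertzianPairForce(c(1.2, 0.3), c(0, 0), 1, 10)
  f2 <- hertzianPairForce(c(0, 0), c(1.2, 0.3), 1, 10)
  expect_equal(f1, -f2)
  # finite-difference gate on the transcribed potential
  VR <- function(r, rc = 1) ifelse(r < 2 * rc, (1 - r / (2 * rc))^2.5, 0)
  h <- 1e-7
  for (r in c(0.5, 1.1, 1.9)) {
    mag_fd <- -10 * (VR(r + h) - VR(r - h)) / (2 * h)
    f <- hertzianPairForce(c(r, 0), c(0, 0), 1, 10)
    expect_equal(f[1], mag_fd, tolerance = 1e-6)
    expect_equal(f[2], 0)
    expect_gt(f[1], 0)    # repulsive
  }
})

test_that("alignment torque: zero for aligned pairs and out of range, -J sin(dphi) inside", {
  expect_equal(alignmentTorque(1.2, 1.2, 0.5, J = 2, r_A = 1), 0)
  expect_equal(alignmentTorque(0, pi / 3, 2.1, J = 2, r_A = 1), 0)
  expect_equal(alignmentTorque(pi / 2, 0, 0.5, J = 2, r_A = 1), -2)
  expect_equal(alignmentTorque(0, pi / 2, 0.5, J = 2, r_A = 1), 2)
})

test_that("two distant noiseless particles travel independent straight lines", {
  p <- potentialParams(1.1)
  base <- simConfig(p, v0 = 1, Gamma = 1, Dr = 0, dt = 2e-3,
                    n_steps = 2500L, n_particles = 1L, save_every = 100L,
                    seed = 2L)
  ic <- interactingConfig(base, N = 2L, packing_fraction = 0.002,
                          r_c = 1, r_A = 1, epsilon = 10, J = 0)
  st <- simulateInteracting(ic)
  # orientation relaxes to an axis under Gamma V'; zero noise, no neighbours
  # within range: headings must be constant multiples of the initial relaxers
  # after the angular relaxation transient the heading is frozen on an axis
  late <- st$phi[st$times > 3, ]
  expect_equal(late[nrow(late), ], late[1, ], tolerance = 1e-6)
  expect_equal(foldAngle(late[1, ]), c(0, 0), tolerance = 1e-5)
})

test_that("interacting runs are reproducible from the seed", {
  p <- potentialParams(1.1)
  base <- simConfig(p, dt = 4e-3, n_steps = 400L, n_particles = 1L,
                    save_every = 100L, seed = 7L)
  ic <- interactingConfig(base, N = 40L, packing_fraction = 0.4,
                          epsilon = 25, J = 0.14)
  a <- simulateInteracting(ic)
  b <- simulateInteracting(ic)
  expect_identical(a$phi, b$phi)
  expect_identical(a$x, b$x)
})

test_that("with interactions off, per-particle statistics match the solitary integrator", {
  p <- potentialParams(1.1)
  # same angular dynamics; interactions disabled via J = 0 and zero-measure
  # packing so no pair ever comes within range
  base <- simConfig(p, dt = 2e-3, n_steps = 5000L, n_particles = 1L,
                    save_every = 25L, seed = 19L)
  ic <- interactingConfig(base, N = 60L, packing_fraction = 1e-4,
                          r_c = 0.05, r_A = 0.05, epsilon = 1, J = 0)
  st <- simulateInteracting(ic)
  sol <- simulateSolitary(simConfig(p, dt = 2e-3, n_steps = 5000L,
                                    n_particles = 60L, save_every = 25L,
                                    seed = 23L))
  # compare stationary angular statistics (different initial conditions:
  # uniform vs minima, so discard a transient)
  vbar_i <- mean(potentialValue(st$phi[st$times > 2, ], p))
  vbar_s <- mean(potentialValue(sol$phi[sol$times > 2, ], p))
  expect_lt(abs(vbar_i - vbar_s), 0.2 * max(vbar_i, vbar_s))
})

test_that("polar order: printed atan2 convention and limits", {
  po <- polarOrder(rep(pi, 50))
  expect_equal(po$S_P, 1)
  expect_equal(po$theta_P, pi)
  po2 <- polarOrder(rep(pi / 2, 8))
  expect_equal(po2$theta_P, pi / 2, tolerance = 1e-12)
  set.seed(5)
  expect_lt(polarOrder(runif(2e4, 0, 2 * pi))$S_P, 0.03)
  # matrix form
  m <- polarOrder(matrix(c(0, 0, pi / 2, pi / 2), 2, 2))
  expect_equal(dim(m), c(2L, 2L))
})

test_that("mean-field potential: bare at J = 0; alignment deepens the barrier without moving the minimum", {
  p <- potentialParams(1.1)
  grid <- seq(0, 2 * pi, length.out = 257)
  mf0 <- meanFieldPotential(grid, pi, p, Gamma = 1, J = 0)
  expect_equal(mf0$U, potentialValue(grid, p))
  expect_equal(mf0$dU, 0, tolerance = 1e-4)
  mf <- meanFieldPotential(grid, pi, p, Gamma = 1, J = 0.14, n_neighbors = 8)
  expect_gt(mf$dU, 0)
  expect_equal(mf$phi_min, pi, tolerance = 0.01)
  # tilted collective direction: minimum stays on the axis for |dtheta| < pi/4
  # the minimum shifts only slightly within the same well (by about
  # J n sin(pi/8) / (Gamma k)), never toward the next axis
  mft <- meanFieldPotential(grid, pi + pi / 8, p, Gamma = 1, J = 0.14,
                            n_neighbors = 8)
  expect_lt(abs(mft$phi_min - pi), pi / 8)
})

test_that("density heterogeneity metric is ~1 for uniform random positions", {
  p <- potentialParams(1.1)
  base <- simConfig(p, dt = 4e-3, n_steps = 100L, n_particles = 1L,
                    save_every = 100L, seed = 3L)
  ic <- interactingConfig(base, N = 400L, packing_fraction = 0.05,
                          r_c = 0.3, r_A = 0.3, epsilon = 5, J = 0)
  st <- simulateInteracting(ic)
  vmr <- densityHeterogeneity(st, frame = 1L)
  expect_gt(vmr, 0.5); expect_lt(vmr, 2)
})
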