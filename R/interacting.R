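## Many-body run-and-tumble-turn particles with soft Hertzian repulsion and
## range-limited mutual alignment in a periodic box.  The pair potentials
## are V_R = (1 - r/(2 rc))^{5/2} Theta(2 rc - r) (strength epsilon) and
## V_A = -cos(phi_i - phi_j) Theta(2 rA - r) (strength J); the competition
## between the steering potential Gamma V and the alignment J V_A decides
## between an isotropic state with density heterogeneity (MIPS-like) and a
## flocking state locked to one of the four axes.

#' Configuration of an interacting simulation
#'
#' @param base A \code{\link{simConfig}} object carrying the solitary-model
#'   parameters (potential, v0, Gamma, Dr, dt, n_steps, save_every, seed);
#'   its n_particles is ignored in favour of \code{N}.
#' @param N Particle count.
#' @param packing_fraction Area fraction N pi rc^2 / L^2; the box side L is
#'   derived from it.
#' @param r_c Particle radius (length units); repulsion acts below 2 r_c.
#' @param r_A Alignment half-range; alignment acts below 2 r_A (default
#'   r_c, i.e. alignment at contact range).
#' @param epsilon Repulsion strength (> 0).
#' @param J Alignment strength (>= 0, units 1/time; compare with Gamma).
#' @return An object of class \code{"InteractingConfig"}.
#' @export
interactingConfig <- function(base, N = 200L, packing_fraction = 0.5,
                              r_c = 1, r_A = r_c, epsilon = 25, J = 0) {
  if (!inherits(base, "SimConfig"))
    stop("'base' must be created by simConfig()", call. = FALSE)
  if (N < 1) stop("'N' must be >= 1", call. = FALSE)
  if (packing_fraction <= 0 || packing_fraction >= 1)
    stop("'packing_fraction' must be inside (0, 1)", call. = FALSE)
  if (epsilon <= 0) stop("'epsilon' must be positive", call. = FALSE)
  if (J < 0) stop("'J' must be non-negative", call. = FALSE)
  L <- sqrt(N * pi * r_c^2 / packing_fraction)
  if (L <= 4 * max(r_c, r_A))
    stop("box side derived from N and packing_fraction is too small relative to the interaction ranges",
         call. = FALSE)
  structure(list(base = base, N = as.integer(N),
                 packing_fraction = packing_fraction,
                 r_c = r_c, r_A = r_A, epsilon = epsilon, J = J, L = L),
            class = "InteractingConfig")
}

#' @export
print.InteractingConfig <- function(x, ...) {
  cat("Interacting run-and-tumble-turn config\n")
  cat(sprintf("  N = %d  packing = %.3f  L = %.2f  r_c = %g  r_A = %g\n",
              x$N, x$packing_fraction, x$L, x$r_c, x$r_A))
  cat(sprintf("  epsilon = %g  J = %g  (J/Gamma = %.3g)\n",
              x$epsilon, x$J, x$J / x$base$Gamma))
  invisible(x)
}

#' Hertzian pair force
#'
#' Force on particle i from particle j under the soft Hertzian potential
#' epsilon (1 - r/(2 rc))^{5/2}: repulsive along the centre line, zero at
#' and beyond contact distance 2 rc.  Uses the displacement as given (apply
#' the minimum-image convention beforehand for periodic systems).
#'
#' @param ri,rj Length-2 position vectors.
#' @param r_c Particle radius.
#' @param epsilon Repulsion strength.
#' @return Length-2 force vector on i (equal and opposite on j).
#' @export
hertzianPairForce <- function(ri, rj, r_c, epsilon) {
  d <- ri - rj
  r <- sqrt(sum(d^2))
  if (r >= 2 * r_c) return(c(0, 0))
  if (r < 1e-9)
    stop("coincident particles; the simulator resolves these with a seeded kick",
         call. = FALSE)
  ov <- 1 - r / (2 * r_c)
  (epsilon * 5 / (4 * r_c) * ov^1.5) * d / r
}

#' Alignment torque on a particle
#'
#' Angular drift -J d V_A / d phi_i = -J sin(phi_i - phi_j) when the pair
#' distance is below 2 r_A, else zero.
#'
#' @param phi_i,phi_j Orientations of the two particles.
#' @param r_ij Pair distance (minimum image).
#' @param J Alignment strength.
#' @param r_A Alignment half-range.
#' @return Angular drift contribution (1/time).
#' @export
alignmentTorque <- function(phi_i, phi_j, r_ij, J, r_A) {
  ifelse(r_ij < 2 * r_A, -J * sin(phi_i - phi_j), 0)
}

#' Simulate interacting run-and-tumble-turn particles
#'
#' Euler-Maruyama integration of the many-body system in a periodic box
#' with minimum-image pair interactions and a cell-list neighbour search.
#' Particles are initialised at uniformly random positions and orientations
#' (from the same counter-based streams as the dynamics, so runs are fully
#' reproducible from the seed).
#'
#' @param config An \code{\link{interactingConfig}} object.
#' @return A \code{"ParticleStateSeries"}: list with \code{times} and
#'   matrices \code{x}, \code{y}, \code{phi} (time by particle, positions
#'   wrapped into [0, L)), plus \code{config} and the final state.
#' @export
simulateInteracting <- function(config) {
  if (!inherits(config, "InteractingConfig"))
    stop("'config' must be created by interactingConfig()", call. = FALSE)
  b <- config$base
  N <- config$N
  # streams 3-5: initial x, y, phi; stream 2: angular noise (as solitary)
  u <- function(stream) vapply(seq_len(N) - 1L, function(p)
    tt_unif_cpp(b$seed, stream, p, 0, 1L), numeric(1))
  x0 <- config$L * u(3); y0 <- config$L * u(4); phi0 <- 2 * pi * u(5)
  tab <- .tt_grad_table(b$potential)
  res <- tt_interacting_cpp(x0, y0, phi0, config$L, b$v0, b$Gamma, b$Dr,
                            config$J, config$epsilon, config$r_c, config$r_A,
                            b$dt, b$n_steps, b$save_every, b$seed, 2, 0, tab)
  if (res$max_disp > config$r_c)
    stop(sprintf("a particle moved %.3g (> r_c) in one step; reduce dt",
                 res$max_disp), call. = FALSE)
  structure(list(times = b$dt * b$save_every *
                   seq_len(b$n_steps %/% b$save_every),
                 x = res$x, y = res$y, phi = res$phi, config = config,
                 state = list(x = res$x_final, y = res$y_final,
                              phi = res$phi_final,
                              steps_done = b$n_steps)),
            class = "ParticleStateSeries")
}

#' @export
print.ParticleStateSeries <- function(x, ...) {
  cat(sprintf("ParticleStateSeries: %d particles, %d frames, box %.2f, t up to %g\n",
              ncol(x$phi), nrow(x$phi), x$config$L,
              x$times[length(x$times)]))
  invisible(x)
}

#' Polar order parameter
#'
#' M is the ensemble mean of the orientation unit vectors; S_P = |M| in
#' [0, 1] measures global polar order and theta_P = atan2(-M_y, -M_x) + pi
#' is the global orientation in [0, 2 pi).
#'
#' @param phi Vector of orientations (one state), or a matrix (time by
#'   particle) for a time series.
#' @return For a vector: list(S_P, theta_P).  For a matrix: data.frame with
#'   one row per frame.
#' @export
polarOrder <- function(phi) {
  if (is.matrix(phi)) {
    mx <- rowMeans(cos(phi)); my <- rowMeans(sin(phi))
    return(data.frame(S_P = sqrt(mx^2 + my^2),
                      theta_P = atan2(-my, -mx) + pi))
  }
  mx <- mean(cos(phi)); my <- mean(sin(phi))
  list(S_P = sqrt(mx^2 + my^2), theta_P = atan2(-my, -mx) + pi)
}

#' Mean-field total angular potential
#'
#' U_T(phi) = Gamma V(phi) - J n_neighbors cos(phi - theta_P): the steering
#' potential deepened by alignment with the collective orientation.  Reports
#' the increase of the barrier adjacent to the minimum nearest theta_P and
#' the location of the global minimum (which stays on the nearest axis as
#' long as theta_P is within pi/4 of it).
#'
#' @param phi Angle grid on which to evaluate U_T.
#' @param theta_P Collective orientation.
#' @param params A \code{\link{potentialParams}} object.
#' @param Gamma Rotational mobility.
#' @param J Alignment strength.
#' @param n_neighbors Mean number of alignment neighbours.
#' @return List with \code{U} (values on \code{phi}), \code{U_bare}
#'   (Gamma V), \code{phi_min} (global minimiser on a fine grid) and
#'   \code{dU} (barrier increase over the bare barrier Gamma).
#' @export
meanFieldPotential <- function(phi, theta_P, params, Gamma = 1, J = 0,
                               n_neighbors = 1) {
  .tt_check_params(params)
  U <- function(p) Gamma * potentialValue(p, params) -
    J * n_neighbors * cos(p - theta_P)
  grid <- seq(0, 2 * pi, length.out = 4097L)[-4097L]
  Ug <- U(grid)
  phi_min <- grid[which.min(Ug)]
  # barrier adjacent to the minimum nearest theta_P, relative to that minimum
  near_min <- (pi / 2) * round(theta_P / (pi / 2))
  barrier <- max(U(near_min + seq(0, pi / 2, length.out = 513L))) - U(near_min)
  list(U = U(phi), U_bare = Gamma * potentialValue(phi, params),
       phi_min = phi_min, dU = barrier - Gamma)
}

#' Local-density heterogeneity
#'
#' Coarse-grained density on an m x m grid of the periodic box; the
#' variance of block counts divided by the mean is 1 for an ideal uniform
#' (Poisson) gas and grows when the system phase-separates.
#'
#' @param state A \code{"ParticleStateSeries"}.
#' @param frame Frame index (default: last).
#' @param m Blocks per side (default 16; reduced if blocks would be smaller
#'   than a particle diameter).
#' @return Variance-to-mean ratio of block occupation counts.
#' @export
densityHeterogeneity <- function(state, frame = nrow(state$x), m = 16L) {
  L <- state$config$L
  m <- min(m, floor(L / (2 * state$config$r_c)))
  ix <- pmin(floor(state$x[frame, ] / L * m), m - 1)
  iy <- pmin(floor(state$y[frame, ] / L * m), m - 1)
  counts <- tabulate(1 + ix + m * iy, nbins = m * m)
  stats::var(counts) / mean(counts)
}
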