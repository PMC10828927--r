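## Euler-Maruyama integration of the solitary run-and-tumble-turn particle:
##   dr   = v0 (cos phi, sin phi) dt
##   dphi = -Gamma V'(phi, delta) dt + sqrt(2 Dr) dW
## The compiled core consumes counter-based random streams, one per
## particle, so ensembles are reproducible, particle streams do not depend
## on n_particles, and a resumed run is bit-identical to a single long run.

.tt_grad_table_n <- 8192L

# lookup table of V' on [0, pi/2) used by the compiled integrators
.tt_grad_table <- function(params, n = .tt_grad_table_n) {
  potentialGrad(seq(0, pi / 2, length.out = n + 1L)[seq_len(n)], params)
}

#' Configuration of a solitary-particle simulation
#'
#' @param potential A \code{\link{potentialParams}} object.
#' @param v0 Self-propulsion speed (length/time).
#' @param Gamma Rotational mobility (1/time).
#' @param Dr Rotational diffusion coefficient (1/time).  The study regime of
#'   interest has Gamma/Dr = 7.
#' @param dt Integration time step; must satisfy the stiffness guard
#'   dt * Gamma * max|V''| <= 0.1.
#' @param n_steps Number of integration steps.
#' @param n_particles Ensemble size.
#' @param save_every Save cadence in steps.
#' @param seed Integer seed.
#' @param init_phi Either the string \code{"random-minima"} (each particle
#'   starts in a uniformly chosen axis minimum) or a numeric vector of
#'   initial angles (length 1 or n_particles).
#' @return An object of class \code{"SimConfig"}.
#' @export
simConfig <- function(potential = potentialParams(1.1), v0 = 1, Gamma = 1,
                      Dr = Gamma / 7, dt = 1e-3, n_steps = 1000L,
                      n_particles = 1L, save_every = 1L, seed = 1L,
                      init_phi = "random-minima") {
  .tt_check_params(potential)
  if (dt <= 0) stop("'dt' must be positive", call. = FALSE)
  if (n_particles < 1) stop("'n_particles' must be >= 1", call. = FALSE)
  if (n_steps < 1 || save_every < 1 || n_steps %% save_every != 0)
    stop("'n_steps' must be a positive multiple of 'save_every'", call. = FALSE)
  if (Gamma < 0 || Dr < 0) stop("'Gamma' and 'Dr' must be non-negative", call. = FALSE)
  kmax <- max(abs(potentialCurvature(seq(0, pi / 2, length.out = 721),
                                     potential)))
  if (dt * Gamma * kmax > 0.1)
    stop(sprintf(
      "time step too large for the angular stiffness: dt * Gamma * max|V''| = %.3g > 0.1; use dt <= %.3g",
      dt * Gamma * kmax, 0.1 / (Gamma * kmax)), call. = FALSE)
  if (is.character(init_phi)) {
    if (!identical(init_phi, "random-minima"))
      stop("'init_phi' must be \"random-minima\" or a numeric vector", call. = FALSE)
  } else if (!is.numeric(init_phi) ||
             !(length(init_phi) %in% c(1L, n_particles))) {
    stop("numeric 'init_phi' must have length 1 or n_particles", call. = FALSE)
  }
  structure(list(potential = potential, v0 = v0, Gamma = Gamma, Dr = Dr,
                 dt = dt, n_steps = as.integer(n_steps),
                 n_particles = as.integer(n_particles),
                 save_every = as.integer(save_every),
                 seed = as.integer(seed), init_phi = init_phi),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("Solitary run-and-tumble-turn simulation config\n")
  cat(sprintf("  delta = %.3f  v0 = %g  Gamma = %g  Dr = %g  (Gamma/Dr = %.3g)\n",
              x$potential$delta, x$v0, x$Gamma, x$Dr, x$Gamma / x$Dr))
  cat(sprintf("  dt = %g  n_steps = %d  n_particles = %d  save_every = %d  seed = %d\n",
              x$dt, x$n_steps, x$n_particles, x$save_every, x$seed))
  invisible(x)
}

.tt_initial_angles <- function(config) {
  np <- config$n_particles
  if (is.character(config$init_phi)) {
    # one uniform counter-based draw per particle; stream 1 is reserved for
    # initial conditions so the dynamics stream is untouched
    u <- vapply(seq_len(np) - 1L, function(p)
      tt_unif_cpp(config$seed, 1, p, 0, 1L), numeric(1))
    (pi / 2) * floor(4 * u)
  } else {
    rep_len(config$init_phi, np)
  }
}

#' Simulate an ensemble of solitary run-and-tumble-turn particles
#'
#' Explicit Euler-Maruyama integration of the position/orientation Langevin
#' system.  All particles start from the origin; initial orientations follow
#' \code{config$init_phi}.  Angles are stored unwrapped (no modulo), so
#' tangent correlations and turn counting are unambiguous.
#'
#' @param config A \code{\link{simConfig}} object.
#' @return A \code{"TrajectoryEnsemble"}: list with \code{times} (saved
#'   times), \code{x}, \code{y}, \code{phi} (matrices, time by particle),
#'   \code{config}, and the exact final state used by \code{\link{resume}}.
#' @export
simulateSolitary <- function(config) {
  if (!inherits(config, "SimConfig"))
    stop("'config' must be created by simConfig()", call. = FALSE)
  phi0 <- .tt_initial_angles(config)
  tab <- .tt_grad_table(config$potential)
  res <- tt_langevin_cpp(numeric(config$n_particles),
                         numeric(config$n_particles), phi0,
                         config$v0, config$Gamma, config$Dr, config$dt,
                         config$n_steps, config$save_every,
                         config$seed, 2, 0, tab)
  structure(list(times = config$dt * config$save_every *
                   seq_len(config$n_steps %/% config$save_every),
                 x = res$x, y = res$y, phi = res$phi,
                 config = config,
                 state = list(x = res$x_final, y = res$y_final,
                              phi = res$phi_final,
                              steps_done = config$n_steps,
                              phi0 = phi0)),
            class = "TrajectoryEnsemble")
}

#' Continue a simulation
#'
#' Extends an ensemble by \code{extra_steps}; because random variates are a
#' pure function of (seed, particle, step index), the continuation is
#' bit-identical to a single longer run with the same configuration.
#'
#' @param ensemble A \code{"TrajectoryEnsemble"} from \code{\link{simulateSolitary}}.
#' @param extra_steps Number of additional steps (multiple of
#'   \code{save_every}; 0 returns the ensemble unchanged).
#' @return The extended \code{"TrajectoryEnsemble"}.
#' @export
resume <- function(ensemble, extra_steps) {
  if (!inherits(ensemble, "TrajectoryEnsemble"))
    stop("'ensemble' must come from simulateSolitary()", call. = FALSE)
  if (is.null(ensemble$state))
    stop("ensemble carries no final state; cannot resume", call. = FALSE)
  extra_steps <- as.integer(extra_steps)
  if (extra_steps == 0L) return(ensemble)
  cfg <- ensemble$config
  if (extra_steps < 0L || extra_steps %% cfg$save_every != 0L)
    stop("'extra_steps' must be a non-negative multiple of save_every", call. = FALSE)
  tab <- .tt_grad_table(cfg$potential)
  st <- ensemble$state
  res <- tt_langevin_cpp(st$x, st$y, st$phi, cfg$v0, cfg$Gamma, cfg$Dr,
                         cfg$dt, extra_steps, cfg$save_every,
                         cfg$seed, 2, st$steps_done, tab)
  total <- st$steps_done + extra_steps
  cfg$n_steps <- total
  structure(list(times = cfg$dt * cfg$save_every *
                   seq_len(total %/% cfg$save_every),
                 x = rbind(ensemble$x, res$x),
                 y = rbind(ensemble$y, res$y),
                 phi = rbind(ensemble$phi, res$phi),
                 config = cfg,
                 state = list(x = res$x_final, y = res$y_final,
                              phi = res$phi_final, steps_done = total,
                              phi0 = st$phi0)),
            class = "TrajectoryEnsemble")
}

#' @export
print.TrajectoryEnsemble <- function(x, ...) {
  cat(sprintf("TrajectoryEnsemble: %d particles, %d saved frames, t in [%g, %g]\n",
              ncol(x$phi), nrow(x$phi), x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Export an ensemble as a long-format data frame
#'
#' @param ensemble A \code{"TrajectoryEnsemble"}.
#' @return data.frame with columns particle, t, x, y, phi.
#' @export
ensembleAsDataFrame <- function(ensemble) {
  nt <- nrow(ensemble$phi); np <- ncol(ensemble$phi)
  data.frame(particle = rep(seq_len(np), each = nt),
             t = rep(ensemble$times, np),
             x = as.vector(ensemble$x),
             y = as.vector(ensemble$y),
             phi = as.vector(ensemble$phi))
}
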