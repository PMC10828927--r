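## Four-well angular steering potential and the analytic theory built on it.
##
## The potential V(phi, delta) is pi/2-periodic with minima V = 0 on the
## Cartesian axes (phi = 0, pi/2, pi, 3pi/2) and maxima V = 1 on the
## diagonals, so the barrier height is exactly 1 for every delta.  It is
## constructed by Poisson-kernel smoothing of a piecewise-linear profile
## whose half-height crossing sits at phi = d(delta); smoothing a function
## with 1/n^2 Fourier coefficients yields real dilogarithms, so V has the
## compact closed form
##   V ~ sum_k m_k Re Li2(a e^{4 i (phi - phi_k)}),  a = 1 / rho0^5,
## with knees phi_k in {0, +-d, pi/4} and slope jumps m_k.  delta in
## (0, pi/2) narrows the wells (d decreases with delta); rho0 > 1 sets the
## smoothing radius: large rho0 sends a -> 0 and the potential degenerates
## to (1 - cos 4 phi)/2, independent of delta.

# knee geometry: half-crossing position d(delta), clamped away from 0 and
# pi/4 so that both the well and the barrier keep a finite angular size
.tt_knees <- function(delta) {
  d_lo <- 0.13
  d_hi <- pi / 4 - 0.13
  d <- d_lo + (d_hi - d_lo) * (1 - delta / (pi / 2))
  e <- pi / 4 - d
  list(d = d, e = e,
       m  = c(1 / d, 0.5 * (1 / e - 1 / d), 0.5 * (1 / e - 1 / d), -1 / e),
       ph = c(0, d, -d, pi / 4))
}

# Re Li2(a e^{i theta}) for scalar a in (0,1), vectorised over theta
# (any shape; returns a plain vector of length(theta))
.tt_reli2 <- function(a, theta) {
  nmax <- max(24L, ceiling(-36.8 / log(a)))  # a^n / n^2 < 1e-16
  n <- seq_len(nmax)
  drop(outer(as.vector(theta), n, function(th, nn) cos(nn * th)) %*% (a^n / n^2))
}

#' Parameters of the four-well steering potential
#'
#' @param delta Dimensionless well-narrowness parameter, strictly inside
#'   (0, pi/2).  Larger delta gives narrower potential wells.
#' @param rho0 Dimensionless smoothing parameter, > 1 (default 1.2).  It
#'   bounds the sharpness of the potential's features; large values wash out
#'   the delta dependence entirely.
#' @return An object of class \code{"PotentialParams"}.
#' @examples
#' p <- potentialParams(1.1)
#' potentialValue(c(0, pi / 8, pi / 4), p)
#' @export
potentialParams <- function(delta, rho0 = 1.2) {
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) ||
      delta <= 0 || delta >= pi / 2)
    stop("'delta' must be a single number strictly inside (0, pi/2)",
         call. = FALSE)
  if (!is.numeric(rho0) || length(rho0) != 1 || !is.finite(rho0) || rho0 <= 1)
    stop("'rho0' must be a single number > 1", call. = FALSE)
  kn <- .tt_knees(delta)
  a <- rho0^(-5)
  # normalisation: raw profile difference between maximum and minimum
  g0 <- -sum(kn$m * .tt_reli2(a, 4 * (0 - kn$ph))) / (4 * pi)
  gq <- -sum(kn$m * .tt_reli2(a, 4 * (pi / 4 - kn$ph))) / (4 * pi)
  obj <- structure(list(delta = delta, rho0 = rho0, a = a, knees = kn,
                        g_min = g0, g_norm = gq - g0),
                   class = "PotentialParams")
  # runtime validity: the flank between minimum and maximum must be monotone
  # so that the half-height crossing is unique on each side
  flank <- potentialValue(seq(0, pi / 4, length.out = 257), obj)
  if (any(diff(flank) < -1e-12))
    stop("internal error: potential flank is not monotone for these parameters",
         call. = FALSE)
  obj
}

#' @export
print.PotentialParams <- function(x, ...) {
  cat("Four-well steering potential\n")
  cat(sprintf("  delta = %.4f  rho0 = %.3f\n", x$delta, x$rho0))
  cat(sprintf("  well width W = %.4f rad; curvature at minimum %.3f, at maximum %.3f\n",
              wellWidth(x), potentialCurvature(0, x),
              potentialCurvature(pi / 4, x)))
  invisible(x)
}

.tt_check_params <- function(params) {
  if (!inherits(params, "PotentialParams"))
    stop("'params' must be created by potentialParams()", call. = FALSE)
  params
}

#' Steering potential value
#'
#' Evaluates the dimensionless four-well potential V(phi, delta) in [0, 1];
#' V = 0 at the axis minima and V = 1 at the diagonal maxima.
#'
#' @param phi Angle(s) in radians; any real value (reduced by periodicity).
#' @param params A \code{\link{potentialParams}} object.
#' @return Numeric vector of potential values.
#' @export
potentialValue <- function(phi, params) {
  .tt_check_params(params)
  kn <- params$knees
  s <- 0
  for (j in 1:4)
    s <- s + kn$m[j] * .tt_reli2(params$a, 4 * (phi - kn$ph[j]))
  out <- (-s / (4 * pi) - params$g_min) / params$g_norm
  if (!is.null(dim(phi))) dim(out) <- dim(phi)
  out
}

#' First derivative of the steering potential
#'
#' Closed form dV/dphi; each dilogarithm knee term differentiates to the
#' argument of 1 - a e^{i theta}.
#'
#' @inheritParams potentialValue
#' @return Numeric vector dV/dphi.
#' @export
potentialGrad <- function(phi, params) {
  .tt_check_params(params)
  kn <- params$knees
  a <- params$a
  s <- 0
  for (j in 1:4) {
    th <- 4 * (phi - kn$ph[j])
    s <- s + kn$m[j] * atan2(-a * sin(th), 1 - a * cos(th))
  }
  (-s / pi) / params$g_norm
}

#' Second derivative of the steering potential
#'
#' Closed form d2V/dphi2; positive at minima, negative at maxima.  Each knee
#' contributes a Poisson kernel, which is the smoothed image of the slope
#' jump of the underlying piecewise-linear profile.
#'
#' @inheritParams potentialValue
#' @return Numeric vector d2V/dphi2.
#' @export
potentialCurvature <- function(phi, params) {
  .tt_check_params(params)
  kn <- params$knees
  a <- params$a
  s <- 0
  for (j in 1:4) {
    th <- 4 * (phi - kn$ph[j])
    s <- s + kn$m[j] * (a * a - a * cos(th)) / (1 - 2 * a * cos(th) + a * a)
  }
  (-4 * s / pi) / params$g_norm
}

#' Width of a potential well
#'
#' The angular distance between the two half-height crossings (V = 0.5)
#' bracketing the minimum at phi = 0, found by bisection to 1e-10.
#'
#' @inheritParams potentialValue
#' @return Well width W in radians, inside (0, pi/2).
#' @export
wellWidth <- function(params) {
  .tt_check_params(params)
  f <- function(p) potentialValue(p, params) - 0.5
  eps <- 1e-12
  if (f(eps) > 0 || f(pi / 4 - eps) < 0)
    stop("internal error: half-height crossing not bracketed", call. = FALSE)
  hi <- uniroot(f, c(eps, pi / 4 - eps), tol = 1e-12)$root
  lo <- -uniroot(function(p) f(-p), c(eps, pi / 4 - eps), tol = 1e-12)$root
  hi - lo
}

#' Renormalised effective self-propulsion speed
#'
#' Orientational noise makes the particle wiggle about a potential minimum,
#' reducing the mean speed along the preferred axis to
#' v_eff = v0 exp(-Dr / (2 Gamma k)), where k is the dimensionless curvature
#' of V at the minimum so that Gamma k is the angular relaxation rate of the
#' harmonic well.
#'
#' @param v0 Bare self-propulsion speed (> 0).
#' @param Dr Rotational diffusion coefficient (>= 0, units 1/time).
#' @param k Dimensionless curvature of V at the minimum (> 0).
#' @param Gamma Rotational mobility (> 0, units 1/time).
#' @return Effective speed, 0 < v_eff <= v0.
#' @export
effectiveSpeed <- function(v0, Dr, k, Gamma = 1) {
  if (any(v0 <= 0)) stop("'v0' must be positive", call. = FALSE)
  if (any(Dr < 0)) stop("'Dr' must be non-negative", call. = FALSE)
  if (any(k <= 0)) stop("'k' must be positive (curvature at a minimum)", call. = FALSE)
  if (any(Gamma <= 0)) stop("'Gamma' must be positive", call. = FALSE)
  v0 * exp(-Dr / (2 * Gamma * k))
}

#' Kramers tumble-turn rate and derived scales
#'
#' The thermally-activated rate at which the orientation hops from one well
#' to a given neighbouring well,
#'   lambda = Gamma sqrt(V''(min) |V''(max)|) / (2 pi) * exp(-Gamma dV / Dr)
#' with barrier height dV = 1.  Each well has two neighbours, so the total
#' turn rate is 2 lambda; the natural time and length units of the
#' dynamics are T = 1/(2 lambda) and ell = v0 T.
#'
#' @inheritParams potentialValue
#' @param Gamma Rotational mobility (1/time); Gamma dV is the effective
#'   barrier height seen by the noise.
#' @param Dr Rotational diffusion coefficient (1/time).
#' @param v0 Self-propulsion speed used for the run length and effective
#'   speed (default 1).
#' @return An object of class \code{"Timescales"}: list with elements
#'   \code{lam} (single-neighbour rate), \code{T}, \code{ell}, \code{k}
#'   (curvature at the minimum), \code{k_max} (curvature at the maximum),
#'   \code{v_eff}, \code{z} (= Dr / (Gamma k)), and the inputs.
#' @export
kramersRate <- function(params, Gamma, Dr, v0 = 1) {
  .tt_check_params(params)
  if (!is.numeric(Gamma) || Gamma <= 0) stop("'Gamma' must be positive", call. = FALSE)
  if (!is.numeric(Dr) || Dr <= 0) stop("'Dr' must be positive", call. = FALSE)
  k_min <- potentialCurvature(0, params)
  k_max <- potentialCurvature(pi / 4, params)
  lam <- Gamma * sqrt(k_min * abs(k_max)) / (2 * pi) * exp(-Gamma / Dr)
  T <- 1 / (2 * lam)
  structure(list(lam = lam, T = T, ell = v0 * T,
                 k = k_min, k_max = k_max,
                 v_eff = effectiveSpeed(v0, Dr, k_min, Gamma),
                 z = Dr / (Gamma * k_min),
                 Gamma = Gamma, Dr = Dr, v0 = v0, delta = params$delta),
            class = "Timescales")
}

#' @export
print.Timescales <- function(x, ...) {
  cat("Tumble-turn timescales (Kramers)\n")
  cat(sprintf("  delta = %.3f  Gamma/Dr = %.3f\n", x$delta, x$Gamma / x$Dr))
  cat(sprintf("  lambda = %.4e (per neighbour), total rate %.4e\n",
              x$lam, 2 * x$lam))
  cat(sprintf("  T = %.2f  ell = %.2f  v_eff/v0 = %.5f  z = %.4f\n",
              x$T, x$ell, x$v_eff / x$v0, x$z))
  invisible(x)
}
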