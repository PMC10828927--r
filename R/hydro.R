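## Long-wavelength (hydrodynamic) limit of the spinor master equation.
## Adiabatic elimination of the current j and nematic imbalance chi turns
## the spinor dynamics into a modified diffusion equation for the density,
##   d rho / dt = 1/2 Lap rho + 1/8 Lp^2 rho + 1/32 Lap Lp^2 rho,
## with Lp = dx^2 - dy^2 the anisotropic operator; anisotropy enters only at
## fourth and sixth gradient order, and the sixth-order term stabilises the
## fourth.  All quantities are dimensionless (time in T, length in ell).
## For a Gaussian initial condition of variance sigma^2 >= 1 the evolved
## density, its moments, the angular distribution and the axis/diagonal
## odds all have closed forms (derived with the same q << 1 linearisation
## used to integrate the spectrum term by term); gamma = sigma^2 + t.

#' Spectrum of the anisotropic diffusion operator
#'
#' E(q, theta) = q^2/2 - q^4 cos^2(2 theta)/8 + q^6 cos^2(2 theta)/32.
#' Purely real (no propagating modes), pi/2-periodic in theta, positive for
#' all q, and matching the hydrodynamic branch E1 of the spinor spectrum to
#' O(q^2) for q << 1.
#'
#' @param q Wavenumber modulus (>= 0, units 1/ell), vectorised.
#' @param theta Polar angle of the wavevector, vectorised.
#' @return Real decay rate(s).
#' @export
hydroSpectrum <- function(q, theta) {
  c2 <- cos(2 * theta)^2
  q^2 / 2 - q^4 * c2 / 8 + q^6 * c2 / 32
}

#' Closed-form density of the hydrodynamic theory
#'
#' The time-dependent density evolved from the isotropic Gaussian
#' rho_0 = exp(-r^2/(2 sigma^2)) / (2 pi sigma^2): a Gaussian of variance
#' gamma = sigma^2 + t plus an order-t correction, whose anisotropic part is
#' proportional to cos(4 theta) and decays as 1/t at long times.
#'
#' @param r Radial distance(s) (units ell).
#' @param theta Polar angle(s).
#' @param t Dimensionless time (>= 0).
#' @param sigma Initial Gaussian standard deviation (>= 1).
#' @return Density value(s); integrates to 1 over the plane.
#' @export
closedFormDensity <- function(r, theta, t, sigma = 1) {
  if (sigma < 1) stop("'sigma' must be >= 1 (long-wavelength validity)", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  g <- sigma^2 + t
  x <- r^2 / 2
  e <- exp(-x / g)
  iso <- e / (2 * pi * g) +
    (t / (2 * pi)) * e * (0.5 / g^3 - x / g^4 + 0.25 * x^2 / g^5
                          - 0.75 / g^4 + 2.25 * x / g^5 - 1.125 * x^2 / g^6
                          + 0.125 * x^3 / g^7)
  aniso <- (t / (2 * pi)) * cos(4 * theta) * r^4 * e *
    (1 / (16 * g^5) - 5 / (32 * g^6) + x / (32 * g^7))
  iso + aniso
}

#' Closed-form moments of the hydrodynamic density
#'
#' <r^2> = 2 (sigma^2 + t): plain diffusion with D = 1/2 at all times.
#' <r^4> = 8 (sigma^2 + t)^2 + 4 t: the extra 4 t comes from the
#' anisotropic gradients, so NGP = t / (2 (sigma^2 + t)^2) is positive
#' (whereas agent and master-equation dynamics give NGP < 0) and decays as
#' 1/(2 t).
#'
#' @param t Dimensionless time(s) (>= 0).
#' @param sigma Initial Gaussian standard deviation (>= 1).
#' @return data.frame with columns t, msd, m4, ngp.
#' @export
hydroMoments <- function(t, sigma = 1) {
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  g <- sigma^2 + t
  data.frame(t = t, msd = 2 * g, m4 = 8 * g^2 + 4 * t, ngp = t / (2 * g^2))
}

#' Angular distribution of the hydrodynamic density
#'
#' The radial integral of the closed-form density:
#' rho(theta, t) = 1/(2 pi) + (t / (4 pi)) (1/gamma^2 - 1/gamma^3)
#' cos(4 theta).  For sigma >= 1 and t > 0 the maxima sit on the axes; the
#' anisotropic term decays as 1/t.
#'
#' @param theta Polar angle(s).
#' @param t Dimensionless time (>= 0).
#' @param sigma Initial Gaussian standard deviation (>= 1).
#' @return Density over angle; integrates to 1 over [0, 2 pi).
#' @export
angularDensity <- function(theta, t, sigma = 1) {
  if (sigma < 1) stop("'sigma' must be >= 1", call. = FALSE)
  g <- sigma^2 + t
  1 / (2 * pi) + (t / (4 * pi)) * (1 / g^2 - 1 / g^3) * cos(4 * theta)
}

#' Axis versus diagonal odds
#'
#' P_A is the probability of lying angularly closer to a Cartesian axis
#' than to a diagonal (four times the integral of the angular distribution
#' over [-pi/8, pi/8]); P_D = 1 - P_A.  In closed form
#' P_A = 1/2 + (t / (2 pi)) (1/gamma^2 - 1/gamma^3) >= 1/2 for sigma >= 1.
#'
#' @param t Dimensionless time(s) (>= 0), vectorised.
#' @param sigma Initial Gaussian standard deviation (>= 1).
#' @return data.frame with columns t, P_A, P_D, ratio (= P_A / P_D).
#' @export
axisOdds <- function(t, sigma = 1) {
  if (sigma < 1) stop("'sigma' must be >= 1", call. = FALSE)
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  g <- sigma^2 + t
  pa <- 0.5 + (t / (2 * pi)) * (1 / g^2 - 1 / g^3)
  data.frame(t = t, P_A = pa, P_D = 1 - pa, ratio = pa / (1 - pa))
}

# golden-section maximisation on [lo, hi]
.tt_golden_max <- function(f, lo, hi, tol = 1e-4) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    }
  }
  xm <- (a + b) / 2
  list(t = xm, value = f(xm))
}

#' Time of maximal axis/diagonal anisotropy
#'
#' Golden-section maximisation of the odds ratio P_A / P_D over a time
#' interval (tolerance 1e-4).  For sigma = 1 the maximum is at t = 2.
#'
#' @param sigma Initial Gaussian standard deviation (>= 1).
#' @param interval Search interval in dimensionless time.
#' @return List with \code{t} (arg max) and \code{ratio}.
#' @export
maxAxisOdds <- function(sigma = 1, interval = c(0.1, 20)) {
  res <- .tt_golden_max(function(t) axisOdds(t, sigma)$ratio,
                        interval[1], interval[2])
  list(t = res$t, ratio = res$value)
}

#' Evolve a density under the hydrodynamic operator
#'
#' Spectral application of exp(-E(q, theta) t) on a periodic grid.  The
#' long-wavelength theory has no support at short wavelengths, so the
#' initial condition must carry negligible spectral power beyond the
#' stabilised band: the fraction of |rho_hat|^2 at q > 5 must be below
#' 1e-6 (an isotropic Gaussian with sigma >= 1 satisfies this by a wide
#' margin).
#'
#' @param density n x n matrix (first index x), non-negative, any mass.
#' @param box_size Box side length (units ell).
#' @param t Dimensionless time (>= 0).
#' @return The evolved density matrix; mass is conserved exactly.
#' @export
evolveHydroDensity <- function(density, box_size, t) {
  if (t < 0) stop("'t' must be non-negative", call. = FALSE)
  n <- nrow(density)
  stopifnot(ncol(density) == n)
  qv <- 2 * pi / box_size * c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  qx <- matrix(qv, n, n)
  qy <- matrix(qv, n, n, byrow = TRUE)
  q <- sqrt(qx^2 + qy^2)
  th <- atan2(qy, qx)
  fr <- fft(density)
  pw <- Mod(fr)^2
  hi <- sum(pw[q > 5]) / sum(pw)
  if (hi > 1e-6)
    stop(sprintf("initial density has short-wavelength content (power fraction %.2g at q > 5); the long-wavelength theory does not apply", hi),
         call. = FALSE)
  Re(fft(fr * exp(-hydroSpectrum(q, th) * t), inverse = TRUE)) / n^2
}
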