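## Ensemble statistics of run-and-tumble-turn trajectories: displacement
## moments and the non-Gaussian parameter, tangent-tangent correlation and
## turn-rate estimation, folded angular distributions, squarishness, and the
## effective parallel speed.

#' Displacement moments and non-Gaussian parameter
#'
#' Per saved time, averages r^2 and r^4 over particles (displacement from
#' the origin, where all trajectories start) and computes the 2-D
#' non-Gaussian parameter NGP = <r^4> / (2 <r^2>^2) - 1, which is -0.5 for
#' purely ballistic motion and 0 for Gaussian (diffusive) displacements.
#'
#' @param ensemble A \code{"TrajectoryEnsemble"}.
#' @param units Optional \code{"Timescales"} object; when supplied, rescaled
#'   columns t/T and moments in units of the run length ell are attached.
#' @return A \code{"MomentSeries"} data frame with columns \code{t},
#'   \code{msd}, \code{m4}, \code{ngp} (and \code{t_scaled},
#'   \code{msd_scaled}, \code{m4_scaled} when units are given).
#' @export
displacementMoments <- function(ensemble, units = NULL) {
  r2 <- ensemble$x^2 + ensemble$y^2
  msd <- rowMeans(r2)
  m4 <- rowMeans(r2^2)
  out <- data.frame(t = ensemble$times, msd = msd, m4 = m4,
                    ngp = m4 / (2 * msd^2) - 1)
  if (ncol(r2) == 1L)
    attr(out, "note") <- "single particle: NGP is high-variance"
  if (!is.null(units)) {
    stopifnot(inherits(units, "Timescales"))
    out$t_scaled <- out$t / units$T
    out$msd_scaled <- out$msd / units$ell^2
    out$m4_scaled <- out$m4 / units$ell^4
    attr(out, "units") <- units
  }
  class(out) <- c("MomentSeries", "data.frame")
  out
}

#' Tangent-tangent correlation function
#'
#' C(tau) = <cos(phi(t) - phi(t + tau))>, averaged over particles and time
#' origins in the stationary segment.  For an ideal four-state turner with
#' per-neighbour rate lambda, C(tau) = exp(-2 lambda tau).
#'
#' @param ensemble A \code{"TrajectoryEnsemble"}.
#' @param max_lag Maximum lag in saved frames.
#' @param discard Initial time to drop as transient (same units as
#'   \code{ensemble$times}); default 0.
#' @param lag_by Stride between evaluated lags in frames (default 1).
#' @return data.frame with columns \code{tau} (time units) and \code{C}.
#' @export
tangentCorrelation <- function(ensemble, max_lag, discard = 0, lag_by = 1L) {
  keep <- ensemble$times > discard
  phi <- ensemble$phi[keep, , drop = FALSE]
  nt <- nrow(phi)
  max_lag <- min(as.integer(max_lag), nt - 2L)
  lags <- seq(0L, max_lag, by = as.integer(lag_by))
  dt_frame <- ensemble$times[2] - ensemble$times[1]
  C <- vapply(lags, function(L) {
    if (L == 0L) return(1)
    mean(cos(phi[seq_len(nt - L), , drop = FALSE] -
             phi[seq_len(nt - L) + L, , drop = FALSE]))
  }, numeric(1))
  data.frame(tau = lags * dt_frame, C = C)
}

#' Estimate the tumble-turn rate from a tangent correlation
#'
#' Least-squares fit of log C(tau) on the window where C > 0.1, excluding
#' lags shorter than \code{fit_start} (the fast intra-well decorrelation).
#' The fitted decay rate is the total turn rate 2 lambda; the returned
#' estimate is the per-neighbour rate lambda.
#'
#' @param lags Numeric vector of lags (time units).
#' @param C Correlation values at \code{lags}.
#' @param fit_start Shortest lag entering the fit; use a few angular
#'   relaxation times 1/(Gamma k) to skip the intra-well transient.
#' @return Estimated per-neighbour turn rate lambda.
#' @export
estimateTurnRate <- function(lags, C, fit_start = 0) {
  sel <- lags >= fit_start & C > 0.1
  if (sum(sel) < 3)
    stop("correlation decays below 0.1 within 3 usable lags; enlarge max_lag or sampling density",
         call. = FALSE)
  fit <- stats::lm(log(C[sel]) ~ lags[sel])
  -unname(stats::coef(fit)[2]) / 2
}

#' Fold an angle into the first zone around the nearest axis
#'
#' Subtracts the nearest multiple of pi/2, mapping any angle into
#' [-pi/4, pi/4) (half-open: +pi/4 folds to -pi/4).
#'
#' @param phi Angle(s) in radians.
#' @return Folded angle(s) in [-pi/4, pi/4).
#' @export
foldAngle <- function(phi) {
  f <- phi - (pi / 2) * floor(phi / (pi / 2) + 0.5)
  f[f >= pi / 4 - 1e-15] <- -pi / 4  # guard the boundary convention
  f
}

#' Squarishness of a set of orientations
#'
#' The four-fold orientational order parameter S = |<exp(4 i phi)>|: 1 for
#' axis-locked motion, 0 for isotropic orientations.
#'
#' @param angles Numeric vector or matrix of angles (NA allowed; dropped).
#' @return S in [0, 1].
#' @export
squarishness <- function(angles) {
  a <- angles[!is.na(angles)]
  if (length(a) == 0) stop("no angles supplied", call. = FALSE)
  Mod(mean(exp(4i * a)))
}

#' Coarse-grain trajectory angles by a circular running mean
#'
#' Centered running mean of the orientation unit vectors over a time window
#' (then the argument is taken), per trajectory.  Vector averaging is used
#' so trajectories that wrap do not corrupt the mean.  Frames whose window
#' sticks out of the trajectory are NA.
#'
#' @param ensemble A \code{"TrajectoryEnsemble"}.
#' @param window Averaging window in time units; the natural choice is the
#'   tumble-turn time T.  A window below one frame returns the instantaneous
#'   angles.
#' @return Matrix (time by particle) of coarse-grained angles, NA-padded.
#' @export
coarseGrainAngles <- function(ensemble, window) {
  dt_frame <- ensemble$times[2] - ensemble$times[1]
  k <- max(1L, round(window / dt_frame))
  if (k > nrow(ensemble$phi))
    stop("window longer than the trajectory", call. = FALSE)
  if (k == 1L) return(ensemble$phi)
  w <- rep(1 / k, k)
  cx <- stats::filter(cos(ensemble$phi), w, sides = 2)
  sx <- stats::filter(sin(ensemble$phi), w, sides = 2)
  out <- atan2(as.matrix(sx), as.matrix(cx))
  dimnames(out) <- NULL
  out
}

#' Mean speed along the instantaneous preferred axis
#'
#' <v_par> = v0 <cos(fold(phi))>: the component of the velocity parallel to
#' the axis the particle is currently locked to.  Equals the renormalised
#' effective speed of \code{\link{effectiveSpeed}} in the harmonic-well
#' regime.
#'
#' @param ensemble A \code{"TrajectoryEnsemble"}.
#' @param discard Initial transient time to drop (default 0).
#' @return Mean parallel speed (same units as v0).
#' @export
parallelSpeed <- function(ensemble, discard = 0) {
  keep <- ensemble$times > discard
  ensemble$config$v0 * mean(cos(foldAngle(ensemble$phi[keep, , drop = FALSE])))
}

#' Histogram of folded polarization angles
#'
#' Normalised density of the instantaneous orientation folded into
#' [-pi/4, pi/4), with the standard deviation of the folded angles.
#'
#' @param ensemble A \code{"TrajectoryEnsemble"}.
#' @param bins Number of histogram bins (default 61).
#' @param discard Initial transient time to drop (default 0).
#' @return List with \code{mids}, \code{density} (integrates to 1 over the
#'   fold interval) and \code{sd}.
#' @export
angularHistogram <- function(ensemble, bins = 61L, discard = 0) {
  keep <- ensemble$times > discard
  f <- foldAngle(as.vector(ensemble$phi[keep, , drop = FALSE]))
  h <- hist(f, breaks = seq(-pi / 4, pi / 4, length.out = bins + 1L),
            plot = FALSE)
  list(mids = h$mids, density = h$density, sd = stats::sd(f))
}
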