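## Independent oracles used by the tests.  These deliberately avoid the
## package's own implementation paths: brute-force quadrature, direct
## Monte-Carlo of the ideal four-state turner, and hand-built ensembles.

# Mean-first-passage-time tumble-turn rate by double quadrature.
# For dphi = -Gamma V' dt + sqrt(2 Dr) dW the MFPT from the well bottom at 0
# to absorbers at the two adjacent barrier tops +-pi/4 (reflecting symmetry
# at 0) is tau = (1/Dr) int_0^{pi/4} dy e^{G V(y)} int_0^y e^{-G V(z)} dz
# with G = Gamma/Dr.  Each top is committed with probability 1/2, and there
# are two exits, so the per-neighbour rate is lambda = 1 / (4 tau).
mfpt_rate <- function(params, Gamma, Dr, n = 2001L) {
  G <- Gamma / Dr
  y <- seq(0, pi / 4, length.out = n)
  h <- y[2] - y[1]
  vin <- exp(-G * potentialValue(y, params))
  vout <- exp(G * potentialValue(y, params))
  inner <- (cumsum(vin) - vin / 2 - vin[1] / 2) * h  # trapezoid cumulative
  tau <- sum((vout * inner)[-1] + (vout * inner)[-n]) / 2 * h / Dr
  1 / (4 * tau)
}

# Ideal four-state Poisson turner: piecewise-constant angles, +-pi/2 turns
# at total rate `rate`; returns an object mimicking a TrajectoryEnsemble.
poisson_turner_ensemble <- function(n_particles, t_end, dt_frame, rate,
                                    v0 = 1, seed = 1) {
  set.seed(seed)
  times <- seq(dt_frame, t_end, by = dt_frame)
  nt <- length(times)
  phi <- matrix(0, nt, n_particles)
  x <- matrix(0, nt, n_particles)
  y <- matrix(0, nt, n_particles)
  for (p in seq_len(n_particles)) {
    tt <- cumsum(rexp(ceiling(3 * rate * t_end) + 20, rate))
    tt <- tt[tt < t_end]
    sgn <- sample(c(-1, 1), length(tt), replace = TRUE)
    ph0 <- sample(0:3, 1) * pi / 2
    brk <- c(0, tt, t_end)
    ang <- ph0 + c(0, cumsum(sgn)) * pi / 2
    idx <- findInterval(times, tt) + 1L
    phi[, p] <- ang[idx]
    # integrate the velocity exactly over the piecewise-constant angles
    segx <- diff(brk) * v0 * cos(ang)
    segy <- diff(brk) * v0 * sin(ang)
    cx <- c(0, cumsum(segx)); cy <- c(0, cumsum(segy))
    x[, p] <- cx[idx] + (times - brk[idx]) * v0 * cos(ang[idx])
    y[, p] <- cy[idx] + (times - brk[idx]) * v0 * sin(ang[idx])
  }
  structure(list(times = times, x = x, y = y, phi = phi,
                 config = list(v0 = v0, dt = dt_frame, save_every = 1L)),
            class = "TrajectoryEnsemble")
}

# build a TrajectoryEnsemble-shaped object from raw matrices
synthetic_ensemble <- function(times, x, y, phi, v0 = 1) {
  structure(list(times = times, x = x, y = y, phi = phi,
                 config = list(v0 = v0)),
            class = "TrajectoryEnsemble")
}

# study-condition potentials used across tests
tt_test_deltas <- c(0.9, 1.1, 1.3)
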