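test_that("NGP is exactly -0.5 for any deterministic-speed non-turning ensemble", {
  # four particles leaving the origin along different axes at fixed speed
  times <- seq(0.1, 10, by = 0.1)
  ang <- c(0, pi / 2, pi, 3 * pi / 2, pi / 2, 0)
  x <- outer(times, cos(ang)); y <- outer(times, sin(ang))
  ens <- synthetic_ensemble(times, x, y, matrix(rep(ang, each = length(times)),
                                                ncol = length(ang)))
  mom <- displacementMoments(ens)
  expect_equal(mom$ngp, rep(-0.5, nrow(mom)), tolerance = 1e-12)
})

test_that("NGP vanishes for isotropic Gaussian displacements", {
  set.seed(4)
  n <- 1e4
  x <- matrix(rnorm(n, sd = 2), 1); y <- matrix(rnorm(n, sd = 2), 1)
  ens <- synthetic_ensemble(1, x, y, 0 * x)
  ngp <- displacementMoments(ens)$ngp
  expect_lt(abs(ngp), 3 / sqrt(n))
})

test_that("four-state Poisson walk: NGP rises from -0.5 toward 0 beyond the turn time", {
  ens <- poisson_turner_ensemble(4000, t_end = 12, dt_frame = 0.25,
                                 rate = 1, seed = 7)
  mom <- displacementMoments(ens)
  expect_lt(abs(mom$ngp[1] + 0.5), 0.02)      # ballistic at t << T
  late <- mom$ngp[mom$t >= 1]
  # monotone rise within Monte-Carlo tolerance
  expect_true(all(diff(late) > -0.02))
  expect_gt(late[length(late)], -0.2)
})

test_that("tangent correlation of an ideal four-state turner decays at the total rate 2 lambda", {
  lam <- 0.5   # per-neighbour rate; total 1
  ens <- poisson_turner_ensemble(400, t_end = 30, dt_frame = 0.05,
                                 rate = 2 * lam, seed = 11)
  tc <- tangentCorrelation(ens, max_lag = 80)
  expect_equal(tc$C[1], 1)
  lam_est <- estimateTurnRate(tc$tau, tc$C)
  expect_lt(abs(lam_est - lam) / lam, 0.05)
})

test_that("turn-rate estimate is invariant under subsampling", {
  ens <- poisson_turner_ensemble(400, t_end = 30, dt_frame = 0.05,
                                 rate = 1, seed = 13)
  tc1 <- tangentCorrelation(ens, max_lag = 120)
  sub <- synthetic_ensemble(ens$times[seq(4, length(ens$times), by = 4)],
                            ens$x[seq(4, nrow(ens$x), by = 4), ],
                            ens$y[seq(4, nrow(ens$y), by = 4), ],
                            ens$phi[seq(4, nrow(ens$phi), by = 4), ])
  tc4 <- tangentCorrelation(sub, max_lag = 30)
  l1 <- estimateTurnRate(tc1$tau, tc1$C)
  l4 <- estimateTurnRate(tc4$tau, tc4$C)
  expect_lt(abs(l1 - l4) / l1, 0.1)
})

test_that("a frozen ensemble never decorrelates", {
  phi <- matrix(pi / 2, 200, 3)
  ens <- synthetic_ensemble(seq_len(200) * 0.1, 0 * phi, 0 * phi, phi)
  tc <- tangentCorrelation(ens, max_lag = 50)
  expect_equal(tc$C, rep(1, nrow(tc)))
})

test_that("angle folding maps into [-pi/4, pi/4) with the half-open boundary", {
  expect_equal(foldAngle(pi / 2 + 0.1), 0.1)
  expect_equal(foldAngle(-0.2), -0.2)
  expect_equal(foldAngle(pi / 4), -pi / 4)
  r <- seq(-20, 20, length.out = 817)
  f <- foldAngle(r)
  expect_true(all(f >= -pi / 4 & f < pi / 4))
  expect_equal(sin(4 * f), sin(4 * r), tolerance = 1e-9)
})

test_that("squarishness: 1 for a delta ensemble, ~0 for uniform angles", {
  expect_equal(squarishness(rep(pi / 2, 100)), 1)
  set.seed(8)
  u <- runif(1e4, 0, 2 * pi)
  expect_lt(squarishness(u), 3 / sqrt(1e4))
  expect_error(squarishness(NA_real_), "no angles")
})

test_that("coarse-graining: identity for tiny windows and for constant trajectories", {
  phi <- matrix(rep(c(0.3, 1.9), each = 100), 100, 2)
  ens <- synthetic_ensemble(seq_len(100) * 0.5, 0 * phi, 0 * phi, phi)
  expect_identical(coarseGrainAngles(ens, 0.1), phi)     # window < one frame
  cg <- coarseGrainAngles(ens, 5)
  expect_equal(cg[!is.na(cg)], phi[!is.na(cg)], tolerance = 1e-12)
  expect_error(coarseGrainAngles(ens, 1000), "longer")
})

test_that("coarse-graining averages circularly (wrapping trajectories stay sane)", {
  # angles wrapping through 2 pi: arithmetic averaging would cut through the
  # wrong quadrant; circular averaging must stay near the true direction
  n <- 101
  phi <- matrix(seq(2 * pi - 0.2, 2 * pi + 0.2, length.out = n), n, 1)
  ens <- synthetic_ensemble(seq_len(n) * 0.1, 0 * phi, 0 * phi, phi)
  cg <- coarseGrainAngles(ens, 2)
  mid <- cg[51, 1]
  expect_lt(abs(sin(mid)), 0.05)  # near angle 0 (= 2 pi)
})

test_that("parallel speed: v0 at a frozen minimum, bounded by v0, near v_eff in the locked regime", {
  phi <- matrix(pi, 50, 2)
  ens <- synthetic_ensemble(seq_len(50) * 0.1, 0 * phi, 0 * phi, phi)
  ens$config$v0 <- 1.7
  expect_equal(parallelSpeed(ens), 1.7)
  set.seed(2)
  phi2 <- matrix(rnorm(5000, 0, 0.3), 1000, 5)
  ens2 <- synthetic_ensemble(seq_len(1000) * 0.1, 0 * phi2, 0 * phi2, phi2)
  expect_lte(parallelSpeed(ens2), 1)
})

test_that("angular histogram integrates to one and sharpens with delta", {
  p1 <- potentialParams(0.9); p2 <- potentialParams(1.3)
  mk <- function(p, seed) simulateSolitary(
    simConfig(p, dt = 2e-3, n_steps = 8000L, n_particles = 100L,
              save_every = 20L, seed = seed))
  h1 <- angularHistogram(mk(p1, 41L), discard = 2)
  h2 <- angularHistogram(mk(p2, 42L), discard = 2)
  bw <- h1$mids[2] - h1$mids[1]
  expect_equal(sum(h1$density) * bw, 1, tolerance = 1e-6)
  expect_equal(sum(h2$density) * bw, 1, tolerance = 1e-6)
  expect_gt(h1$sd, h2$sd)   # narrower wells collimate more strongly
})
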