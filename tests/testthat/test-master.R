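test_that("turning matrix: conservation, spectrum {0,1,1,2} at q = 0", {
  H0 <- buildDynamicalMatrix(0, 0)
  expect_equal(colSums(Re(H0)), rep(0, 4), tolerance = 1e-14)  # probability conservation
  ev <- sort(Re(eigen(H0, only.values = TRUE)$values))
  expect_equal(ev, c(0, 1, 1, 2), tolerance = 1e-12)
  # the nematic imbalance chi = (P_r + P_l) - (P_u + P_d) decays at rate 2
  chi <- c(1, 1, -1, -1)
  expect_equal(Re(as.vector(H0 %*% chi)), 2 * chi, tolerance = 1e-14)
})

test_that("spectrum has the lattice four-fold symmetry", {
  for (qq in list(c(0.4, 0.1), c(1.2, -0.7), c(2.5, 2.5))) {
    e1 <- eigen(buildDynamicalMatrix(qq[1], qq[2]), only.values = TRUE)$values
    e2 <- eigen(buildDynamicalMatrix(-qq[2], qq[1]), only.values = TRUE)$values
    expect_equal(sort(Re(e1)), sort(Re(e2)), tolerance = 1e-10)
    expect_equal(sort(Im(e1)), sort(Im(e2)), tolerance = 1e-10)
  }
})

test_that("closed-form eigenvalues match the numeric eigendecomposition everywhere (transcription gate)", {
  for (q in c(0, 0.05, 0.3, 0.7, 0.999, 1.001, 1.7, 3.2))
    for (th in c(0, 0.13, pi / 8, pi / 4, 1.2, 2.9)) {
      cf <- spectrumClosedForm(q, th)
      ev <- eigen(buildDynamicalMatrix(q * cos(th), q * sin(th)),
                  only.values = TRUE)$values
      err <- 0
      for (e in cf) {
        i <- which.min(Mod(ev - e)); err <- max(err, Mod(ev[i] - e))
        ev <- ev[-i]
      }
      expect_lt(err, 1e-10)
    }
})

test_that("hydrodynamic branch: E1 -> q^2/2 (D = 1/2) at small q; two counter-propagating modes on the axis at large q", {
  for (th in c(0, 0.4, pi / 4)) {
    q <- 1e-3
    expect_equal(Re(spectrumClosedForm(q, th)[1]), q^2 / 2, tolerance = 1e-4)
  }
  ev <- spectrumClosedForm(2.5, 0)
  n_imag <- sum(abs(Im(ev)) > 1e-9)
  expect_equal(n_imag, 2)
  expect_equal(sort(Im(ev))[1], -sort(Im(ev))[4], tolerance = 1e-12)
})

test_that("eigenmode weights: equipartition at q -> 0, direction-locking on the axis, pairing on the diagonal", {
  em0 <- eigenmodes(1e-4, 0.3)
  hyd <- which.min(Re(em0$values))
  expect_equal(em0$weights[, hyd], rep(0.25, 4), tolerance = 1e-3)
  # theta = 0, large q: the two propagating (complex) modes identify with
  # the right- and left-moving components; the degenerate non-propagating
  # pair carries no horizontal weight asymptotically
  em <- eigenmodes(3, 0)
  prop <- which(abs(Im(em$values)) > 1e-9)
  expect_length(prop, 2)
  expect_true(all(apply(em$weights[1:2, prop, drop = FALSE], 2, max) > 0.85))
  expect_equal(sort(apply(em$weights[, prop], 2, which.max)), 1:2)
  still <- setdiff(1:4, prop)
  expect_true(all(colSums(em$weights[3:4, still, drop = FALSE]) > 0.85))
  # theta = pi/4: weights pair (right with up; left with down)
  emd <- eigenmodes(2, pi / 4)
  expect_equal(emd$weights[1, ], emd$weights[3, ], tolerance = 1e-8)
  expect_equal(emd$weights[2, ], emd$weights[4, ], tolerance = 1e-8)
})

test_that("uniform spinor is stationary; mass is conserved; evolution is an exact semigroup", {
  n <- 64L
  u <- array(1 / (4 * n^2), c(n, n, 4))
  f <- spinorField(u, box_size = 40)
  g <- evolveSpinor(f, 3)
  expect_equal(g$components, u, tolerance = 1e-13)
  f0 <- gaussianSpinorField(40, 256L, 0.5)
  f1 <- evolveSpinor(f0, 1.7)
  expect_equal(sum(f1$components), sum(f0$components), tolerance = 1e-12)
  f2a <- evolveSpinor(f1, 2.3)
  f2b <- evolveSpinor(f0, 4.0)
  expect_lt(max(abs(f2a$components - f2b$components)), 1e-10)
})

test_that("wrap-around guard names the required box size", {
  f0 <- gaussianSpinorField(20, 64L, 0.5)
  expect_error(evolveSpinor(f0, 20), "box_size")
})

test_that("localized start: early-time peaks travel along the axes at unit speed, late-time maximum sits at the center", {
  f0 <- gaussianSpinorField(56, 384L, 0.5)
  fe <- evolveSpinor(f0, 1.5)
  rho <- spinorDensity(fe)
  n <- fe$n_grid
  xs <- (seq_len(n) - 1) * fe$box_size / n - fe$box_size / 2
  # peak along the +x axis near x = t
  mid <- which.min(abs(xs))
  ix <- which.max(rho[, mid])
  expect_lt(abs(abs(xs[ix]) - 1.5), 0.5)
  expect_gt(abs(xs[ix]), 0.9)
  # four-fold symmetry of the density
  expect_equal(rho, t(rho), tolerance = 1e-10)         # x <-> y mirror pair
  fl <- evolveSpinor(f0, 8)
  rhol <- spinorDensity(fl)
  expect_equal(which.max(rhol[, mid]), mid)            # maximum back at center
  # long-time angular isotropy: squarishness of the mass distribution decays
  thg <- atan2(rep(xs, each = n), rep(xs, n))
  S_early <- Mod(sum(rho * exp(4i * matrix(thg, n, n))))
  S_late <- Mod(sum(rhol * exp(4i * matrix(thg, n, n))))
  expect_lt(S_late, S_early / 3)
})

test_that("density moments match a direct Monte-Carlo of the four-state Poisson walk", {
  f0 <- gaussianSpinorField(64, 448L, 0.5)
  fields <- lapply(c(0.5, 2, 10), function(t) evolveSpinor(f0, t))
  mom <- spinorMoments(fields)
  nmc <- 2e5
  ens <- poisson_turner_ensemble(2000, t_end = 10, dt_frame = 0.5,
                                 rate = 1, seed = 17)
  # Monte-Carlo moments at matching times, plus the initial Gaussian spread
  for (i in seq_len(3)) {
    t <- c(0.5, 2, 10)[i]
    r2 <- ens$x[ens$times == t, ]^2 + ens$y[ens$times == t, ]^2
    mc_msd <- mean(r2) + 2 * 0.25        # add the sigma = 0.5 initial variance
    se <- stats::sd(r2) / sqrt(length(r2))
    expect_lt(abs(mom$msd[i] - mc_msd), 3 * se + 0.01,
              label = sprintf("msd at t=%g (grid %.4f vs MC %.4f)", t,
                              mom$msd[i], mc_msd))
  }
  # NGP: the sigma = 0.5 initial Gaussian keeps NGP near 0 at t -> 0; the
  # ballistic peaks drive it negative by t ~ 2; diffusion restores Gaussian
  expect_lt(mom$ngp[2], -0.2)
  expect_gt(mom$ngp[3], mom$ngp[2])
  expect_gt(mom$ngp[3], -0.15)
})

test_that("negative-density policy: clipping is counted, real negatives abort", {
  f0 <- gaussianSpinorField(40, 256L, 0.5)
  f1 <- evolveSpinor(f0, 2)
  expect_true(is.numeric(attr(f1, "clipped")) || is.integer(attr(f1, "clipped")))
  expect_gte(min(f1$components), 0)
  expect_error(spinorField(array(-1e-6, c(8, 8, 4)), 10), "negative")
})
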