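## Four-direction spinor master equation in the natural units T (tumble-turn
## time) and ell (run length): four probability densities P_right, P_left,
## P_up, P_down advect along their directions at unit speed and exchange
## probability with their two perpendicular components at rate 1/2 each
## (total turn rate 1; direct reversals are forbidden).  In Fourier space
## each wavevector evolves under a 4x4 dynamical matrix H_D(q); the
## evolution operator exp(-H_D t) is applied exactly per mode, so the only
## discretisation error is the spatial grid.

.tt_component_names <- c("right", "left", "up", "down")

#' Construct a spinor field on a periodic grid
#'
#' @param components Numeric array n x n x 4 of directional densities in the
#'   order right, left, up, down.  First index is x, second is y.
#' @param box_size Box side length in units of the run length ell.
#' @param t Dimensionless time (units of T) the field refers to.
#' @return An object of class \code{"SpinorField"}.
#' @export
spinorField <- function(components, box_size, t = 0) {
  if (length(dim(components)) != 3 || dim(components)[3] != 4 ||
      dim(components)[1] != dim(components)[2])
    stop("'components' must be an n x n x 4 array", call. = FALSE)
  if (box_size <= 0) stop("'box_size' must be positive", call. = FALSE)
  if (min(components) < -1e-10)
    stop("negative densities in 'components'", call. = FALSE)
  structure(list(components = components, box_size = box_size,
                 n_grid = dim(components)[1], t = t),
            class = "SpinorField")
}

#' Localized isotropic initial spinor field
#'
#' An isotropic Gaussian of standard deviation \code{sigma}, centered in the
#' box and split equally among the four direction components; total mass 1
#' on the grid.
#'
#' @param box_size Box side length (units of ell).
#' @param n_grid Grid points per side.
#' @param sigma Gaussian standard deviation (units of ell, default 0.5).
#' @return A \code{"SpinorField"} at t = 0.
#' @export
gaussianSpinorField <- function(box_size = 80, n_grid = 1024L, sigma = 0.5) {
  xs <- (seq_len(n_grid) - 1) * box_size / n_grid - box_size / 2
  g <- exp(-outer(xs^2, xs^2, "+") / (2 * sigma^2))
  g <- g / sum(g)
  spinorField(array(rep(g / 4, 4), dim = c(n_grid, n_grid, 4)), box_size, 0)
}

#' Total density of a spinor field
#'
#' @param field A \code{"SpinorField"}.
#' @return n x n matrix rho = P_right + P_left + P_up + P_down.
#' @export
spinorDensity <- function(field) {
  field$components[, , 1] + field$components[, , 2] +
    field$components[, , 3] + field$components[, , 4]
}

#' @export
print.SpinorField <- function(x, ...) {
  cat(sprintf("SpinorField: %d x %d grid, box %g ell, t = %g T, mass %.6f\n",
              x$n_grid, x$n_grid, x$box_size, x$t, sum(x$components)))
  invisible(x)
}

#' Dynamical matrix of the spinor master equation
#'
#' H_D(q) for dimensionless wavevector (qx, qy): advection i q . e_c on the
#' diagonal plus the turning matrix in which every component loses at total
#' rate 1 and gains at rate 1/2 from each of its two perpendicular
#' components.  The evolution is dP/dt = -H_D P per Fourier mode.
#'
#' @param qx,qy Wavevector components (units 1/ell).
#' @return 4 x 4 complex matrix (component order right, left, up, down).
#' @export
buildDynamicalMatrix <- function(qx, qy) {
  turn <- matrix(c(1, 0, -0.5, -0.5,
                   0, 1, -0.5, -0.5,
                   -0.5, -0.5, 1, 0,
                   -0.5, -0.5, 0, 1), 4, 4, byrow = TRUE)
  turn + diag(1i * c(qx, -qx, qy, -qy))
}

#' Closed-form spectrum of the dynamical matrix
#'
#' The four eigenvalues of H_D in polar form (q, theta):
#'   E = 1 +- sqrt(mu2_pm),
#'   mu2_pm = [(1 - q^2) +- sqrt((1 - q^2)^2 - q^4 sin^2(2 theta))] / 2.
#' E1 = 1 - sqrt(mu2_+) is the hydrodynamic branch: it goes to zero as
#' q^2 / 2 for q << 1.  Principal complex square roots are used.
#'
#' @param q Wavenumber modulus (>= 0, units 1/ell).
#' @param theta Polar angle of the wavevector.
#' @return Complex vector (E1, E2, E3, E4) = (1 - sp, 1 - sm, 1 + sm, 1 + sp).
#' @export
spectrumClosedForm <- function(q, theta) {
  a <- q * cos(theta); b <- q * sin(theta)
  r1 <- 1 - q^2
  disc <- sqrt(as.complex(r1^2 - 4 * a^2 * b^2))
  sp <- sqrt((r1 + disc) / 2)
  sm <- sqrt((r1 - disc) / 2)
  c(1 - sp, 1 - sm, 1 + sm, 1 + sp)
}

#' Eigenmodes of the dynamical matrix
#'
#' Numeric eigendecomposition of H_D(q) with a deterministic basis: within
#' any (numerically) degenerate eigenvalue cluster the basis is fixed by
#' projecting the current-like combinations j_x = (1,-1,0,0)/sqrt(2) and
#' j_y = (0,0,1,-1)/sqrt(2) (then the density and nematic combinations)
#' onto the cluster's eigenspace and orthonormalising, which makes the
#' reported weights reproducible.  On an axis the degenerate pair resolves
#' into the transverse current mode and its orthogonal complement.
#'
#' @param q Wavenumber modulus.
#' @param theta Polar angle.
#' @return List with \code{values} (complex, ordered by real part),
#'   \code{vectors} (4 x 4, columns normalised) and \code{weights}
#'   (|component|^2 per mode, columns sum to 1).
#' @export
eigenmodes <- function(q, theta) {
  H <- buildDynamicalMatrix(q * cos(theta), q * sin(theta))
  ev <- eigen(H)
  ord <- order(Re(ev$values), Im(ev$values))
  vals <- ev$values[ord]
  vecs <- ev$vectors[, ord, drop = FALSE]
  # deterministic basis inside degenerate clusters
  ref <- cbind(c(1, -1, 0, 0) / sqrt(2), c(0, 0, 1, -1) / sqrt(2),
               c(1, 1, 1, 1) / 2, c(1, 1, -1, -1) / 2, diag(4))
  i <- 1
  while (i <= 4) {
    j <- i
    while (j < 4 && abs(vals[j + 1] - vals[i]) < 1e-8) j <- j + 1
    if (j > i) {
      B <- vecs[, i:j, drop = FALSE]           # basis of the eigenspace
      P <- B %*% solve(crossprod(Conj(B), B), t(Conj(B)))  # projector
      new <- matrix(0 + 0i, 4, 0)
      for (r in seq_len(ncol(ref))) {
        w <- P %*% ref[, r]
        if (ncol(new) > 0)
          w <- w - new %*% crossprod(Conj(new), w)
        nw <- sqrt(Re(crossprod(Conj(w), w)))
        if (nw > 1e-8) new <- cbind(new, w / as.numeric(nw))
        if (ncol(new) == j - i + 1) break
      }
      vecs[, i:j] <- new
    }
    i <- j + 1
  }
  vecs <- sweep(vecs, 2, sqrt(colSums(Mod(vecs)^2)), "/")
  list(values = vals, vectors = vecs, weights = Mod(vecs)^2)
}

# apply H_D to a list of four complex mode arrays (vectorised over modes)
.tt_H_apply <- function(v, ia, ib) {
  s12 <- 0.5 * (v[[1]] + v[[2]])
  s34 <- 0.5 * (v[[3]] + v[[4]])
  list((1 + ia) * v[[1]] - s34,
       (1 - ia) * v[[2]] - s34,
       (1 + ib) * v[[3]] - s12,
       (1 - ib) * v[[4]] - s12)
}

# subset a list-of-arrays by a logical/integer index
.tt_sub <- function(v, idx) lapply(v, function(z) z[idx])

# exp(-H t) v for the index set idx given its distinct eigenvalue nodes
# (list of complex vectors over idx); grouped spectral projector formula,
# valid because H is semisimple away from exceptional points
.tt_lagrange_apply <- function(v, ia, ib, nodes, t) {
  d <- length(nodes)
  out <- lapply(1:4, function(j) 0 * v[[1]])
  for (g in seq_len(d)) {
    w <- v
    denom <- 1 + 0i
    for (h in seq_len(d)) {
      if (h == g) next
      Hw <- .tt_H_apply(w, ia, ib)
      w <- lapply(1:4, function(j) Hw[[j]] - nodes[[h]] * w[[j]])
      denom <- denom * (nodes[[g]] - nodes[[h]])
    }
    fac <- exp(-nodes[[g]] * t) / denom
    for (j in 1:4) out[[j]] <- out[[j]] + fac * w[[j]]
  }
  out
}

#' Evolve a spinor field exactly in time
#'
#' Fourier transforms each component, applies exp(-H_D(q) t) exactly per
#' mode (no time-stepping error), and transforms back.  The evolution is an
#' exact linear semigroup: evolve(evolve(f, t1), t2) equals
#' evolve(f, t1 + t2) to rounding accuracy.
#'
#' @param field A \code{"SpinorField"}.
#' @param t Dimensionless time increment (units of T, >= 0).
#' @return The evolved \code{"SpinorField"} at time field$t + t.
#' @details The box must satisfy box_size >= 2 (t_final + 6 sqrt(t_final))
#'   so that no appreciable probability wraps around the periodic boundary.
#'   Spectral ringing can leave negligible negative densities; values in
#'   (-1e-10, 0) are clipped to zero and counted in the attribute
#'   \code{"clipped"}, anything more negative aborts.
#' @export
evolveSpinor <- function(field, t) {
  stopifnot(inherits(field, "SpinorField"))
  if (t < 0) stop("'t' must be non-negative", call. = FALSE)
  if (t == 0) return(field)
  tf <- field$t + t
  need <- 2 * (tf + 6 * sqrt(tf))
  if (field$box_size < need)
    stop(sprintf("box_size %.3g too small for evolution to t = %.3g; need >= %.3g to avoid wrap-around",
                 field$box_size, tf, need), call. = FALSE)
  n <- field$n_grid
  L <- field$box_size
  qv <- 2 * pi / L * c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  ia <- 1i * matrix(qv, n, n)         # qx varies along rows (first index)
  ib <- 1i * matrix(qv, n, n, byrow = TRUE)
  v <- lapply(1:4, function(j) fft(field$components[, , j]))

  a2 <- Re(ia)^2 + Im(ia)^2; b2 <- Re(ib)^2 + Im(ib)^2  # = qx^2, qy^2
  q2 <- a2 + b2
  r1 <- 1 - q2
  disc <- sqrt(as.complex(r1^2 - 4 * a2 * b2))
  sp <- sqrt((r1 + disc) / 2)
  sm <- sqrt((r1 - disc) / 2)

  tol <- 1e-9
  zp <- Mod(sp) < tol                # E = 1 double (semisimple)
  zm <- Mod(sm) < tol
  # exceptional (non-semisimple) modes: coalescing distinct branches, or
  # both branches vanishing (q = 1 exactly on an axis); handled by expm
  ep <- ((Mod(sp - sm) < tol | Mod(sp + sm) < tol) & !zp & !zm) | (zp & zm)
  out <- lapply(1:4, function(j) array(0i, dim(v[[1]])))

  classes <- list(
    generic = which(!zp & !zm & !ep),
    axisA   = which(zm & !zp & !ep), # nodes {1 - sp, 1, 1 + sp}
    axisB   = which(zp & !zm & !ep)) # nodes {1 - sm, 1, 1 + sm}
  for (nm in names(classes)) {
    idx <- classes[[nm]]
    if (length(idx) == 0) next
    vi <- .tt_sub(v, idx)
    iai <- ia[idx]; ibi <- ib[idx]
    nodes <- switch(nm,
      generic = list(1 - sp[idx], 1 - sm[idx], 1 + sm[idx], 1 + sp[idx]),
      axisA   = list(1 - sp[idx], rep(1 + 0i, length(idx)), 1 + sp[idx]),
      axisB   = list(1 - sm[idx], rep(1 + 0i, length(idx)), 1 + sm[idx]))
    res <- .tt_lagrange_apply(vi, iai, ibi, nodes, t)
    for (j in 1:4) out[[j]][idx] <- res[[j]]
  }
  if (any(ep)) {                      # rare exceptional points: direct expm
    for (m in which(ep)) {
      H <- buildDynamicalMatrix(Im(ia[m]), Im(ib[m]))
      vec <- c(v[[1]][m], v[[2]][m], v[[3]][m], v[[4]][m])
      ev <- .tt_expm_apply(-H * t, vec)
      for (j in 1:4) out[[j]][m] <- ev[j]
    }
  }

  comp <- array(0, dim = c(n, n, 4))
  clipped <- 0L
  for (j in 1:4) {
    re <- Re(fft(out[[j]], inverse = TRUE)) / n^2
    neg <- re < 0
    if (any(neg)) {
      if (min(re) < -1e-10)
        stop(sprintf("negative density %.3g below ringing tolerance; increase grid resolution",
                     min(re)), call. = FALSE)
      clipped <- clipped + sum(neg)
      re[neg] <- 0
    }
    comp[, , j] <- re
  }
  f <- spinorField(comp, L, tf)
  attr(f, "clipped") <- clipped
  f
}

# exp(A) %*% x for a small matrix by scaling and squaring with Taylor
.tt_expm_apply <- function(A, x) {
  nrmA <- max(abs(A))
  s <- max(0L, ceiling(log2(max(nrmA, 1e-300))) + 1L)
  B <- A / 2^s
  E <- diag(1 + 0i, nrow(A))
  term <- diag(1 + 0i, nrow(A))
  for (k in 1:16) {
    term <- term %*% B / k
    E <- E + term
  }
  for (k in seq_len(s)) E <- E %*% E
  as.vector(E %*% x)
}

#' Displacement moments of the density of evolved spinor fields
#'
#' Grid quadrature of <r^2>, <r^4> and the non-Gaussian parameter of the
#' total density rho, measured from the box center (where localized initial
#' conditions are placed).
#'
#' @param fields A list of \code{"SpinorField"} objects sharing one grid
#'   (e.g. successive outputs of \code{\link{evolveSpinor}}).
#' @return A \code{"MomentSeries"} data frame with columns t, msd, m4, ngp.
#' @export
spinorMoments <- function(fields) {
  if (inherits(fields, "SpinorField")) fields <- list(fields)
  stopifnot(all(vapply(fields, inherits, logical(1), "SpinorField")))
  out <- do.call(rbind, lapply(fields, function(f) {
    n <- f$n_grid
    xs <- (seq_len(n) - 1) * f$box_size / n - f$box_size / 2
    r2 <- outer(xs^2, xs^2, "+")
    rho <- spinorDensity(f)
    mass <- sum(rho)
    if (abs(mass - 1) > 1e-6)
      stop("field is not normalised; spinorMoments expects total mass 1",
           call. = FALSE)
    msd <- sum(rho * r2) / mass
    m4 <- sum(rho * r2^2) / mass
    data.frame(t = f$t, msd = msd, m4 = m4, ngp = m4 / (2 * msd^2) - 1)
  }))
  class(out) <- c("MomentSeries", "data.frame")
  out
}
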