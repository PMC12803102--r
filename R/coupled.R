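#' Integrate a coupled Markov / non-Markov linear system
#'
#' Propagates dP/dt = M P + B1 x, dx/dt = B2 P + C x. For systems with
#' n + l <= 500 the propagation uses matrix-exponential stepping on the
#' assembled A (exact to machine precision on the grid); larger systems
#' fall back to adaptive ODE integration. Probability conservation
#' 1'P(t) = 1 is guaranteed by the zero column sums of [M B1]; the maximum
#' residual is reported. Linear coupling can transiently drive components
#' of P negative; this is reported via the trajectory, not clamped.
#'
#' @param sys a \linkS4class{CoupledLinearSystem}.
#' @param P0 initial probability vector (sums to 1, componentwise >= 0).
#' @param x0 initial input vector (length l).
#' @param tGrid uniform output time grid starting at 0.
#' @param rtol,atol tolerances for the adaptive fallback.
#' @return a \linkS4class{CoupledTrajectory}.
#' @export
integrateCoupled <- function(sys, P0, x0, tGrid, rtol = 1e-10, atol = 1e-12) {
  n <- sys@n; l <- sys@l
  stopifnot(length(P0) == n, length(x0) == l)
  if (abs(sum(P0) - 1) > 1e-8) stop("P0 must sum to 1")
  if (any(P0 < -1e-12)) stop("P0 must be componentwise nonnegative")
  nT <- length(tGrid)
  Z <- matrix(0, nT, n + l)
  z <- c(P0, x0)
  Z[1, ] <- z
  if (n + l <= 500 && nT >= 2 &&
      max(abs(diff(diff(tGrid)))) < 1e-9 * max(diff(tGrid))) {
    h <- tGrid[2] - tGrid[1]
    E <- as.matrix(Matrix::expm(Matrix::Matrix(sys@A * h)))
    for (k in 2:nT) {
      z <- E %*% z
      Z[k, ] <- z
    }
  } else {
    f <- function(t, y, parms) list(as.numeric(sys@A %*% y))
    out <- deSolve::ode(y = z, times = tGrid, func = f, parms = NULL,
                        method = "lsoda", rtol = rtol, atol = atol)
    if (attr(out, "istate")[1] < 0)
      stop("coupled integration failed (lsoda istate ",
           attr(out, "istate")[1], ")")
    Z <- unname(out[, -1, drop = FALSE])
  }
  P <- Z[, seq_len(n), drop = FALSE]
  x <- Z[, n + seq_len(l), drop = FALSE]
  new("CoupledTrajectory", time = as.numeric(tGrid), P = P, x = x,
      conservationResidual = max(abs(rowSums(P) - 1)))
}

## exp(s * C) for the small l x l input block
.expC <- function(C, s) {
  if (nrow(C) == 1) return(matrix(exp(s * C[1, 1]), 1, 1))
  as.matrix(Matrix::expm(Matrix::Matrix(C * s)))
}

#' Integral (convolution) solution for the input variable
#'
#' Evaluates the closed-form solution
#' \deqn{x(t) = e^{tC} x(0) + e^{tC} \int_0^t e^{-sC} B_2 P(s)\, ds}
#' (the integral-controller view of the coupling) by high-order quadrature
#' of the tabulated probability path, as an independent cross-check of the
#' ODE-integrated x(t).
#'
#' @param Ppath matrix (time x n) of probabilities on \code{tGrid}.
#' @param C l x l input dynamics.
#' @param B2 l x n readout coupling.
#' @param x0 initial input vector.
#' @param tGrid the (uniform) grid the path is tabulated on.
#' @return matrix (time x l) of input values.
#' @export
xIntegralSolution <- function(Ppath, C, B2, x0, tGrid) {
  if (nrow(Ppath) != length(tGrid))
    stop("probability path and time grid lengths differ")
  nT <- length(tGrid)
  l <- nrow(B2)
  h <- tGrid[2] - tGrid[1]
  if (max(abs(diff(tGrid) - h)) > 1e-9 * h)
    stop("integral solution requires a uniform grid")
  # The formula is evaluated stepwise (mathematically identical via the
  # semigroup property), because the literal form multiplies quadrature
  # residue by e^{tC}, which diverges for the unstable C of a design:
  #   x(t_k) = e^{hC} x(t_{k-1}) + int_{t_{k-1}}^{t_k} e^{(t_k-s)C} B2 P(s) ds
  # with the per-step integral from 4th-order (cubic-interpolant)
  # Newton-Cotes over the nodes t_{k-2}..t_{k+1}, trapezoid at the ends.
  f <- t(B2 %*% t(Ppath))            # nT x l readouts B2 P(s)
  E <- lapply(-2:3, function(j) .expC(C, j * h))
  names(E) <- as.character(-2:3)
  ker <- function(j) E[[as.character(j)]]
  E1 <- ker(1)
  x <- matrix(0, nT, l)
  x[1, ] <- x0
  if (nT < 4) stop("integral solution needs at least 4 grid points")
  for (k in 2:nT) {
    if (k == 2) {
      # one-sided cubic rule over nodes k-1 .. k+2
      inc <- h / 24 * (9 * (ker(1) %*% f[k - 1, ]) + 19 * f[k, ] -
                         5 * (ker(-1) %*% f[k + 1, ]) +
                         ker(-2) %*% f[k + 2, ])
    } else if (k == nT) {
      # mirrored one-sided cubic rule over nodes k-3 .. k
      inc <- h / 24 * (ker(3) %*% f[k - 3, ] - 5 * (ker(2) %*% f[k - 2, ]) +
                         19 * (ker(1) %*% f[k - 1, ]) + 9 * f[k, ])
    } else {
      # centered cubic rule over nodes k-2 .. k+1
      inc <- h / 24 * (-(ker(2) %*% f[k - 2, ]) +
                         13 * (ker(1) %*% f[k - 1, ]) + 13 * f[k, ] -
                         ker(-1) %*% f[k + 1, ])
    }
    x[k, ] <- E1 %*% x[k - 1, ] + as.numeric(inc)
  }
  x
}

#' Integrate a coupled system with cubic saturation of the input
#'
#' Augments the input equation to \eqn{\dot x = B_2 P + C x - \kappa x^3}
#' (elementwise cube). For a real-mode design tuned slightly into the
#' growing-oscillatory regime, the cubic term saturates the growth and the
#' long-run oscillation amplitude becomes independent of the initial
#' amplitude: a limit cycle, with stability contributed by the
#' non-Markovian part. With \code{kappa = 0} this reduces exactly to
#' \code{\link{integrateCoupled}}.
#'
#' @param sys a \linkS4class{CoupledLinearSystem} (real-mode design, l = 1).
#' @param P0,x0 initial conditions as in \code{\link{integrateCoupled}}.
#' @param kappa nonnegative cubic saturation coefficient.
#' @param tGrid output time grid.
#' @param rtol,atol integration tolerances.
#' @return a \linkS4class{CoupledTrajectory}.
#' @export
integrateWithCubic <- function(sys, P0, x0, kappa, tGrid,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(integrateCoupled(sys, P0, x0, tGrid))
  n <- sys@n; l <- sys@l
  f <- function(t, y, parms) {
    P <- y[seq_len(n)]
    x <- y[n + seq_len(l)]
    dP <- as.numeric(sys@M %*% P) + as.numeric(sys@B1 %*% x)
    dx <- as.numeric(sys@B2 %*% P) + as.numeric(sys@Cmat %*% x) - kappa * x^3
    list(c(dP, dx))
  }
  out <- deSolve::ode(y = c(P0, x0), times = tGrid, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0)
    stop("cubic-coupled integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  Z <- unname(out[, -1, drop = FALSE])
  P <- Z[, seq_len(n), drop = FALSE]
  x <- Z[, n + seq_len(l), drop = FALSE]
  new("CoupledTrajectory", time = as.numeric(tGrid), P = P, x = x,
      conservationResidual = max(abs(rowSums(P) - 1)))
}
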