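## Coupling design: make the coupled block system
##   A = [[M, B1], [B2, C]]
## acquire a purely imaginary leading eigenvalue pair at a chosen frequency
## by targeting one mode of M in ordered Schur coordinates.

.assembleCoupled <- function(M, B1, B2, C) {
  n <- nrow(M); l <- ncol(B1)
  A <- rbind(cbind(M, B1), cbind(B2, C))
  new("CoupledLinearSystem", M = M, B1 = B1, B2 = B2, Cmat = C, A = A,
      n = as.integer(n), l = as.integer(l))
}

#' Assemble a coupled linear system from its blocks
#'
#' @param M generator block (n x n).
#' @param B1 n x l coupling into the probabilities; columns must sum to 0.
#' @param B2 l x n readout coupling.
#' @param C l x l input dynamics.
#' @return a \linkS4class{CoupledLinearSystem}.
#' @export
coupledLinearSystem <- function(M, B1, B2, C) {
  .assembleCoupled(as.matrix(M), as.matrix(B1), as.matrix(B2), as.matrix(C))
}

## leading eigenvalue: largest real part, ties (within roundoff) broken by
## largest |Im| so a designed oscillatory pair beats exact zero modes
.leadingEigen <- function(ev, tieTol = 1e-9) {
  top <- ev[Re(ev) >= max(Re(ev)) - tieTol]
  top[which.max(abs(Im(top)))]
}

#' Design a coherent oscillation by targeting a real Schur mode
#'
#' Couples a one-dimensional unstable input to the scalar Schur mode at
#' position i (eigenvalue \eqn{\sigma^{(1)} < 0}): sets
#' \eqn{\sigma^{(2)} = -\sigma^{(1)}} (trace zero) and the coupling product
#' \eqn{q^{(1)} q^{(2)} = \sigma^{(1)} \sigma^{(2)} - \omega^{*2}} so that
#' the targeted 2x2 factor has eigenvalues exactly \eqn{\pm i \omega^*}.
#' The product is split antisymmetrically,
#' \eqn{q^{(1)} = -q^{(2)} = \sqrt{-q^{(1)} q^{(2)}}} (negative feedback),
#' and embedded through the mode's Schur vector, whose orthogonality to the
#' all-ones vector makes the B1 column sum exactly zero. The achieved
#' spectrum of the assembled A is verified against the prediction.
#'
#' @param sf a \linkS4class{SchurForm} of the generator.
#' @param modeIndex position in \code{sf@S1} coordinates of the targeted
#'   scalar mode (must have a strictly negative entry).
#' @param targetOmega desired angular frequency (> 0).
#' @param verifyTol tolerance on |Re| of the achieved leading eigenvalue.
#' @return a list with \code{design} (a \linkS4class{DesignResult}) and
#'   \code{system} (the \linkS4class{CoupledLinearSystem}, l = 1).
#' @examples
#' tri <- fixture("trimolecular")
#' G <- buildGenerator(tri$network,
#'        enumerateStates(tri$network, "closed-conserved", totals = 6))
#' sf <- orderedSchur(G)
#' d <- designRealMode(sf, slowestRealMode(sf)$position, targetOmega = 1)
#' d$design
#' @export
designRealMode <- function(sf, modeIndex, targetOmega, verifyTol = 1e-8) {
  modeIndex <- as.integer(modeIndex)
  if (!modeIndex %in% sf@S1)
    stop("mode ", modeIndex, " is not a scalar (1x1) Schur position")
  stopifnot(targetOmega > 0)
  sigma1 <- sf@D1[modeIndex, modeIndex]
  if (sigma1 >= 0)
    stop("targeted scalar mode must be strictly negative (got ",
         signif(sigma1, 4), ")")
  sigma2 <- -sigma1
  product <- sigma1 * sigma2 - targetOmega^2   # always < 0
  q1 <- sqrt(-product)
  q2 <- -q1
  vM <- sf@Q[, modeIndex]
  M <- sf@Q %*% sf@D1 %*% t(sf@Q)
  B1 <- matrix(q1 * vM, ncol = 1)
  B1 <- B1 - mean(B1)  # remove roundoff in the exact zero column sum
  B2 <- matrix(q2 * vM, nrow = 1)
  C <- matrix(sigma2, 1, 1)
  sys <- .assembleCoupled(M, B1, B2, C)
  ev <- eigen(sys@A, only.values = TRUE)$values
  lead <- .leadingEigen(ev)
  # eigenvalues other than the designed pair
  dPair <- order(abs(Re(ev)) + abs(abs(Im(ev)) - targetOmega))[1:2]
  maxOther <- max(Re(ev[-dPair]))
  if (abs(Re(lead)) > verifyTol)
    stop("design verification failed: leading eigenvalue real part ",
         signif(Re(lead), 3), " exceeds tolerance; achieved spectrum ",
         "available via eigen() of the assembled system")
  design <- new("DesignResult", targetKind = "real", targetIndex = modeIndex,
                sigma1 = sigma1, sigma2 = sigma2, q1 = q1, q2 = q2,
                couplingProduct = product, predictedOmega = targetOmega,
                achievedEigenvalues = ev,
                leadingEigenvalue = if (Im(lead) >= 0) lead else Conj(lead),
                maxOtherRealPart = maxOther, system = sys, cubic = NULL)
  list(design = design, system = sys)
}

#' Characteristic cubic of a reduced complex-mode coupling
#'
#' For the 3x3 reduced system
#' \code{[[d_aa, d_ab, q1], [d_ba, d_bb, 0], [q2, 0, s2]]} (a 2x2 Schur
#' block coupled through its first coordinate, the weakly coupled second
#' input dropped), returns the coefficients of
#' \eqn{a\lambda^3 + b\lambda^2 + c\lambda + d = det(\lambda I - A_3)} and
#' its roots. Purely imaginary conjugate roots exist iff bc = ad with
#' b > 0 and c > 0.
#'
#' @param block 2x2 numeric Schur block.
#' @param sigma2 the non-Markov eigenvalue coupled to the first coordinate.
#' @param product the coupling product q1 * q2.
#' @return a \linkS4class{CharacteristicCubic}.
#' @export
characteristicCubic <- function(block, sigma2, product) {
  daa <- block[1, 1]; dab <- block[1, 2]
  dba <- block[2, 1]; dbb <- block[2, 2]
  a <- 1
  b <- -(daa + dbb + sigma2)
  c <- (daa * dbb - dab * dba) + (daa * sigma2 - product) + dbb * sigma2
  d <- -(sigma2 * (daa * dbb - dab * dba) - product * dbb)
  roots <- polyroot(c(d, c, b, a))
  new("CharacteristicCubic", coefficients = c(a = a, b = b, c = c, d = d),
      roots = roots)
}

#' Test the purely-imaginary-pair condition of a cubic
#'
#' @param cubic a \linkS4class{CharacteristicCubic} or numeric (a, b, c, d).
#' @param relTol relative tolerance on bc = ad.
#' @return logical: bc = ad (within tolerance) with b > 0 and c > 0.
#' @export
hasImaginaryPair <- function(cubic, relTol = 1e-9) {
  co <- if (is(cubic, "CharacteristicCubic")) cubic@coefficients else cubic
  a <- co[1]; b <- co[2]; c <- co[3]; d <- co[4]
  scale <- max(abs(c(b * c, a * d, 1)))
  abs(b * c - a * d) <= relTol * scale && b > 0 && c > 0
}

#' Design a coherent oscillation by targeting a complex Schur block
#'
#' Couples a (nominally two-dimensional, one direction weakly coupled and
#' dropped) input to the 2x2 Schur block starting at position j. With the
#' second coupling set to zero the quartic characteristic factor reduces to
#' a cubic whose purely-imaginary-root condition bc = ad (b, c > 0) is
#' solved for the coupling product by bracketing root search (the condition
#' is affine in the product, so the bracket collapses in one step). The
#' solution is embedded through the block's Schur vectors into full
#' (B1, B2, C) with l = 2, the second input direction decoupled and stable,
#' and the assembled spectrum verified to contain a purely imaginary pair.
#'
#' @param sf a \linkS4class{SchurForm}.
#' @param blockIndex starting position (in \code{sf@S2}) of the targeted
#'   2x2 block.
#' @param sigma2 eigenvalue of the coupled input direction. Must satisfy
#'   \code{sigma2 < -tr(block)} for feasibility (b > 0).
#' @param sigmaBeta2 eigenvalue of the decoupled second input direction
#'   (default: stable, \code{-abs(sigma2) - 1}).
#' @param searchRange interval of coupling products searched for the
#'   bc = ad root.
#' @param verifyTol tolerance on |Re| of the achieved oscillatory pair.
#' @return list with \code{design} (\linkS4class{DesignResult}),
#'   \code{system} (l = 2) and \code{cubic}
#'   (\linkS4class{CharacteristicCubic}).
#' @export
designComplexMode <- function(sf, blockIndex, sigma2,
                              sigmaBeta2 = -abs(sigma2) - 1,
                              searchRange = c(-1e4, 1e4),
                              verifyTol = 1e-8) {
  blockIndex <- as.integer(blockIndex)
  if (!blockIndex %in% sf@S2)
    stop("position ", blockIndex, " is not the start of a 2x2 Schur block")
  block <- sf@D1[blockIndex + 0:1, blockIndex + 0:1]
  g <- function(p) {
    co <- characteristicCubic(block, sigma2, p)@coefficients
    co[2] * co[3] - co[1] * co[4]
  }
  lo <- searchRange[1]; hi <- searchRange[2]
  if (g(lo) * g(hi) > 0)
    stop("infeasible design: bc = ad has no root for coupling products in [",
         lo, ", ", hi, "]")
  pStar <- stats::uniroot(g, c(lo, hi), tol = 1e-13)$root
  cubic <- characteristicCubic(block, sigma2, pStar)
  co <- cubic@coefficients
  if (!(co[2] > 0 && co[3] > 0))
    stop("infeasible design: bc = ad root found but b > 0, c > 0 fails ",
         "(b = ", signif(co[2], 4), ", c = ", signif(co[3], 4), ")")
  q1 <- sqrt(abs(pStar)) * sign(pStar)
  q2 <- sqrt(abs(pStar))
  vAlpha <- sf@Q[, blockIndex]
  M <- sf@Q %*% sf@D1 %*% t(sf@Q)
  n <- nrow(M)
  B1 <- cbind(q1 * vAlpha, rep(0, n))
  B1 <- sweep(B1, 2L, colMeans(B1))  # exact zero column sums
  B2 <- rbind(q2 * vAlpha, rep(0, n))
  C <- diag(c(sigma2, sigmaBeta2))
  sys <- .assembleCoupled(M, B1, B2, C)
  ev <- eigen(sys@A, only.values = TRUE)$values
  osc <- ev[abs(Im(ev)) > 1e-8]
  if (!length(osc))
    stop("design verification failed: no oscillatory eigenvalues in A")
  lead <- osc[which.min(abs(Re(osc)))]
  omega <- abs(Im(lead))
  if (abs(Re(lead)) > verifyTol)
    stop("design verification failed: oscillatory pair real part ",
         signif(Re(lead), 3), " exceeds tolerance")
  dPair <- which(abs(Re(ev) - Re(lead)) < 1e-12 &
                 abs(abs(Im(ev)) - omega) < 1e-12)
  maxOther <- max(Re(ev[-dPair]))
  design <- new("DesignResult", targetKind = "complex",
                targetIndex = blockIndex, sigma1 = block,
                sigma2 = c(sigma2, sigmaBeta2), q1 = q1, q2 = q2,
                couplingProduct = pStar, predictedOmega = omega,
                achievedEigenvalues = ev,
                leadingEigenvalue = if (Im(lead) >= 0) lead else Conj(lead),
                maxOtherRealPart = maxOther, system = sys, cubic = cubic)
  list(design = design, system = sys, cubic = cubic)
}

#' Suppress an oscillatory Markov mode by positive coupling
#'
#' Couples an input with a positive coupling product to a 2x2 Schur block;
#' for sufficiently strong coupling the targeted complex pair collapses
#' onto the real axis (the oscillating mode becomes non-oscillatory). The
#' outcome is reported either way, never raised as an error.
#'
#' @param sf a \linkS4class{SchurForm}.
#' @param blockIndex starting position of the targeted 2x2 block.
#' @param product positive coupling product.
#' @param sigma2 eigenvalue of the coupled input (default -1, stable).
#' @return list with \code{system} (\linkS4class{CoupledLinearSystem}),
#'   \code{suppressed} (logical: targeted pair now real),
#'   \code{eigenvalues} and \code{targetEigenvalues}.
#' @export
suppressOscillatoryMode <- function(sf, blockIndex, product, sigma2 = -1) {
  blockIndex <- as.integer(blockIndex)
  if (!blockIndex %in% sf@S2)
    stop("position ", blockIndex, " is not the start of a 2x2 Schur block")
  stopifnot(product > 0)
  block <- sf@D1[blockIndex + 0:1, blockIndex + 0:1]
  q1 <- q2 <- sqrt(product)
  vAlpha <- sf@Q[, blockIndex]
  M <- sf@Q %*% sf@D1 %*% t(sf@Q)
  B1 <- matrix(q1 * vAlpha, ncol = 1)
  B1 <- B1 - mean(B1)
  B2 <- matrix(q2 * vAlpha, nrow = 1)
  C <- matrix(sigma2, 1, 1)
  sys <- .assembleCoupled(M, B1, B2, C)
  ev <- eigen(sys@A, only.values = TRUE)$values
  # roots of the targeted reduced cubic, to identify the targeted pair
  target <- characteristicCubic(block, sigma2, product)@roots
  suppressed <- all(abs(Im(target)) < 1e-8)
  list(system = sys, suppressed = suppressed, eigenvalues = ev,
       targetEigenvalues = target)
}

#' Classify the dynamical regime of a scalar-mode coupling
#'
#' For the 2x2 reduction \code{[[sigma1, q1], [q2, sigma2]]} with trace
#' \eqn{\tau = \sigma^{(1)} + \sigma^{(2)}} and determinant
#' \eqn{\Delta = \sigma^{(1)}\sigma^{(2)} - q^{(1)}q^{(2)}}: the mode is
#' oscillatory iff \eqn{\tau^2 < 4\Delta}, stable iff the largest real part
#' is negative, and coherent on the boundary \eqn{|\tau| \le} tolerance
#' with \eqn{\Delta > 0}.
#'
#' @param sigma1 targeted (negative) Markov eigenvalue.
#' @param sigma2 non-Markov eigenvalue.
#' @param product coupling product q1 * q2.
#' @param tol boundary tolerance on the trace.
#' @return one of \code{"stable-nonoscillatory"},
#'   \code{"decaying-oscillatory"}, \code{"coherent"},
#'   \code{"growing-oscillatory"}, \code{"unstable-nonoscillatory"}.
#' @export
classifyRegime <- function(sigma1, sigma2, product, tol = 1e-10) {
  if (sigma1 >= 0)
    stop("sigma1 must be strictly negative (nonzero Markov eigenvalues are)")
  tau <- sigma1 + sigma2
  delta <- sigma1 * sigma2 - product
  if (tau^2 < 4 * delta) {
    if (abs(tau) <= tol) return("coherent")
    if (tau < 0) return("decaying-oscillatory")
    return("growing-oscillatory")
  }
  lamMax <- (tau + sqrt(max(tau^2 - 4 * delta, 0))) / 2
  if (lamMax < -tol) "stable-nonoscillatory" else "unstable-nonoscillatory"
}

#' Regime phase diagram over (sigma2, coupling product)
#'
#' Classifies every grid cell and reports the frequency
#' \eqn{\omega = \sqrt{\Delta}} where the cell is oscillatory (exact on the
#' coherent boundary, where the pair is purely imaginary).
#'
#' @param sigma1 targeted (negative) Markov eigenvalue.
#' @param sigma2Grid,productGrid numeric grids spanning both signs.
#' @return data.frame with columns \code{sigma2}, \code{product},
#'   \code{regime}, \code{omega}; attribute \code{"nOpenRegions"} counts
#'   the distinct open-region labels (coherent boundary excluded).
#' @export
phaseDiagram <- function(sigma1, sigma2Grid, productGrid) {
  grid <- expand.grid(sigma2 = sigma2Grid, product = productGrid,
                      KEEP.OUT.ATTRS = FALSE)
  regime <- character(nrow(grid))
  omega <- rep(NA_real_, nrow(grid))
  for (r in seq_len(nrow(grid))) {
    regime[r] <- classifyRegime(sigma1, grid$sigma2[r], grid$product[r])
    delta <- sigma1 * grid$sigma2[r] - grid$product[r]
    if (regime[r] %in% c("decaying-oscillatory", "coherent",
                         "growing-oscillatory"))
      omega[r] <- sqrt(delta)
  }
  out <- data.frame(grid, regime = regime, omega = omega)
  attr(out, "nOpenRegions") <- length(setdiff(unique(regime), "coherent"))
  out
}

#' Square-root scaling of the frequency near the coherent boundary
#'
#' On the zero-trace line (\eqn{\sigma^{(2)} = -\sigma^{(1)}}), the
#' coherent frequency at coupling products offset by \eqn{\epsilon} below
#' the critical product \eqn{\sigma^{(1)}\sigma^{(2)}} is
#' \eqn{\omega = \sqrt{\epsilon}}; the fitted log-log slope of
#' \eqn{\omega} versus \eqn{\epsilon} measures the 1/2 scaling exponent.
#'
#' @param sigma1 targeted (negative) Markov eigenvalue.
#' @param offsets positive offsets from the critical coupling product
#'   (at least 3 distinct values, ideally spanning >= 2 decades).
#' @return list with \code{slope}, \code{residual} (fit residual norm) and
#'   the \code{omega} values.
#' @export
scalingExponent <- function(sigma1, offsets) {
  stopifnot(sigma1 < 0)
  offsets <- as.numeric(offsets)
  if (length(unique(offsets)) < 3 || any(offsets <= 0))
    stop("insufficient data: need >= 3 distinct positive offsets")
  sigma2 <- -sigma1
  critical <- sigma1 * sigma2
  omega <- vapply(offsets, function(eps)
    sqrt(sigma1 * sigma2 - (critical - eps)), numeric(1))
  fit <- stats::lm(log(omega) ~ log(offsets))
  list(slope = unname(stats::coef(fit)[2]),
       residual = sqrt(sum(stats::resid(fit)^2)), omega = omega)
}
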