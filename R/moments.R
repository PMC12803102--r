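## Moment hierarchy of the chemical master equation:
##   d<n^m>/dt = sum_j < a_j(n) * [ (n + S_j)^m - n^m ] >
## expanded exactly into raw moments, then closed at order q by setting all
## central moments of order > q to zero (order 1 recovers the classical
## rate equations).

#' All moment multi-indices up to a given order
#'
#' @param N number of species.
#' @param maxOrder largest total order |m|.
#' @return integer matrix of multi-indices (rows), ordered by total order
#'   then lexicographically.
#' @keywords internal
.multiIndices <- function(N, maxOrder) {
  out <- list()
  for (o in seq_len(maxOrder)) {
    grid <- .enumerateConserved(N, list(seq_len(N)), o)
    # descending lexicographic within each order: first-order block then
    # lists the means in species order
    out[[o]] <- grid[rev(seq_len(nrow(grid))), , drop = FALSE]
  }
  do.call(rbind, out)
}

.momentLabel <- function(idx) paste0("m", paste(idx, collapse = "_"))

#' Derive the exact moment equations of a mass-action network
#'
#' Computes, for every raw moment \eqn{\langle n^m \rangle} with
#' \eqn{1 \le |m| \le q}, its exact time derivative as a linear combination
#' of raw moments, by symbolic polynomial expansion of
#' \eqn{\sum_j a_j(n) [(n+S_j)^m - n^m]}. For mass action the derivative of
#' an order-|m| moment involves raw moments up to order
#' \eqn{|m| + d_{max}} where \eqn{d_{max}} is the maximum propensity degree
#' minus one (at most 2 up to trimolecular reactions).
#'
#' @param net a \linkS4class{ReactionNetwork} (polynomial propensities).
#' @param q truncation order, 1 <= q <= 5.
#' @return a \linkS4class{MomentSystem} with closure \code{"none"}.
#' @examples
#' decay <- reactionNetwork("A", matrix(1), matrix(0), rates = 2)
#' ms <- deriveMoments(decay, q = 1)   # d<n>/dt = -2 <n>
#' @export
deriveMoments <- function(net, q) {
  stopifnot(q >= 1, q <= 5)
  N <- length(net@speciesNames)
  S <- netStoich(net)
  aPolys <- lapply(seq_len(nReactions(net)), .propensityPoly, net = net)
  tracked <- .multiIndices(N, q)
  rhs <- vector("list", nrow(tracked))
  for (r in seq_len(nrow(tracked))) {
    m <- tracked[r, ]
    mono <- list(expo = matrix(as.integer(m), 1, N), coef = 1)
    acc <- .polyZero(N)
    for (j in seq_len(nReactions(net))) {
      jump <- .polyAdd(.polyShift(mono, S[, j]), .polyScale(mono, -1))
      acc <- .polyAdd(acc, .polyMul(aPolys[[j]], jump))
    }
    rhs[[r]] <- list(coef = acc$coef, idx = acc$expo)
  }
  new("MomentSystem", order = as.integer(q), indices = tracked, rhs = rhs,
      closure = "none", network = net)
}

## Closure expansion: a raw moment of order |m| > q, with all central
## moments of order > q set to zero, equals
##   sum over sub-multi-indices i <= m with |i| <= q of
##     K_i * mu^(m-i) * <n^i>
## where the means mu are themselves tracked first moments. Returns a term
## list: each term has a coefficient and an integer vector of tracked
## positions whose product (of current values) is the term's factor.
.rawClosureTerms <- function(m, q, trackedKeys, N) {
  subIdx <- as.matrix(expand.grid(lapply(m, function(e) 0:e),
                                  KEEP.OUT.ATTRS = FALSE))
  coefs <- numeric(0)
  posList <- list()
  meanPos <- match(vapply(seq_len(N), function(k) {
    e <- integer(N); e[k] <- 1L; paste(e, collapse = ",")
  }, character(1)), trackedKeys)
  for (jr in seq_len(nrow(subIdx))) {
    j <- subIdx[jr, ]
    oj <- sum(j)
    if (oj > q || oj == 1) next   # central moment zero (closure / exact)
    cmj <- prod(choose(m, j))
    innerIdx <- as.matrix(expand.grid(lapply(j, function(e) 0:e),
                                      KEEP.OUT.ATTRS = FALSE))
    for (ir in seq_len(nrow(innerIdx))) {
      i <- innerIdx[ir, ]
      coef <- cmj * prod(choose(j, i)) * (-1)^(sum(j) - sum(i))
      # mean exponent vector: (m - j) + (j - i) = m - i
      meanExp <- m - i
      pos <- rep(meanPos, times = meanExp)
      if (sum(i) > 0)
        pos <- c(pos, match(paste(i, collapse = ","), trackedKeys))
      coefs <- c(coefs, coef)
      posList[[length(posList) + 1L]] <- as.integer(pos)
    }
  }
  list(coef = coefs, pos = posList)
}

#' Close a moment system by central-moment neglect
#'
#' Sets every central moment of order above q to zero, so that the higher
#' raw moments appearing in the exact derivatives are re-expressed through
#' tracked moments (order <= q) and the system becomes self-contained.
#' Order q = 1 reduces to the classical rate equations (all covariances
#' vanish; propensities are evaluated at the means).
#'
#' @param ms a \linkS4class{MomentSystem} from \code{\link{deriveMoments}}.
#' @param scheme closure scheme; only \code{"central-moment-neglect"}.
#' @return a list of class \code{"ClosedMomentSystem"} with elements
#'   \code{order}, \code{indices}, \code{labels}, \code{terms} (compiled
#'   polynomial evaluation structure) and \code{rhs} (a function of a named
#'   moment vector returning the derivatives).
#' @export
closeSystem <- function(ms, scheme = "central-moment-neglect") {
  scheme <- match.arg(scheme, "central-moment-neglect")
  q <- ms@order
  N <- ncol(ms@indices)
  trackedKeys <- apply(ms@indices, 1L, paste, collapse = ",")
  cache <- new.env(parent = emptyenv())
  compileRaw <- function(idx) {
    o <- sum(idx)
    if (o == 0) return(list(coef = 1, pos = list(integer(0))))
    if (o <= q) {
      p <- match(paste(idx, collapse = ","), trackedKeys)
      return(list(coef = 1, pos = list(p)))
    }
    key <- paste(idx, collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    res <- .rawClosureTerms(idx, q, trackedKeys, N)
    cache[[key]] <- res
    res
  }
  terms <- vector("list", length(ms@rhs))
  for (r in seq_along(ms@rhs)) {
    tab <- ms@rhs[[r]]
    coefs <- numeric(0)
    posList <- list()
    for (t in seq_along(tab$coef)) {
      sub <- compileRaw(tab$idx[t, ])
      coefs <- c(coefs, tab$coef[t] * sub$coef)
      posList <- c(posList, sub$pos)
    }
    terms[[r]] <- list(coef = coefs, pos = posList)
  }
  labels <- apply(ms@indices, 1L, .momentLabel)
  rhsFun <- function(y) {
    vapply(terms, function(tt) {
      s <- 0
      for (t in seq_along(tt$coef)) s <- s + tt$coef[t] * prod(y[tt$pos[[t]]])
      s
    }, numeric(1))
  }
  structure(list(order = q, indices = ms@indices, labels = labels,
                 terms = terms, rhs = rhsFun, network = ms@network,
                 scheme = scheme),
            class = "ClosedMomentSystem")
}

#' @export
print.ClosedMomentSystem <- function(x, ...) {
  cat(sprintf(
    "ClosedMomentSystem: order %d, %d tracked moments (%s closure)\n",
    x$order, nrow(x$indices), x$scheme))
  invisible(x)
}

#' Initial raw moments for a deterministic start
#'
#' All central moments zero: \eqn{\langle n^m \rangle = n_0^m}.
#'
#' @param closed a ClosedMomentSystem (or MomentSystem).
#' @param n0 deterministic initial copy numbers.
#' @return named numeric vector of initial tracked moments.
#' @export
deterministicInitialMoments <- function(closed, n0) {
  idx <- if (is(closed, "MomentSystem")) closed@indices else closed$indices
  y <- apply(idx, 1L, function(m) prod(n0^m))
  names(y) <- apply(idx, 1L, .momentLabel)
  y
}

#' Integrate a closed moment system
#'
#' Stiff-capable adaptive integration (lsoda) of the closed moment ODEs.
#'
#' @param closed a ClosedMomentSystem from \code{\link{closeSystem}}.
#' @param initMoments named initial moment vector (see
#'   \code{\link{deterministicInitialMoments}}).
#' @param tGrid output times.
#' @param rtol,atol integration tolerances.
#' @return matrix (time x tracked moments) with a leading \code{time}
#'   column, as returned by \code{deSolve::ode}.
#' @export
integrateMoments <- function(closed, initMoments, tGrid,
                             rtol = 1e-8, atol = 1e-10, maxsteps = 50000) {
  f <- function(t, y, parms) list(closed$rhs(y))
  out <- deSolve::ode(y = initMoments, times = tGrid, func = f, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = maxsteps)
  if (attr(out, "istate")[1] < 0)
    stop("moment integration failed (lsoda istate ",
         attr(out, "istate")[1], ")")
  out
}

#' Leading oscillatory mode of a closed moment system
#'
#' Locates a fixed point of the closed moment ODEs by damped Newton
#' iteration from a given start (for instance the time average of an
#' integrated trajectory), then reads the frequency and decay rate off the
#' leading complex-conjugate eigenvalue pair of the numerically evaluated
#' Jacobian: \eqn{\omega = |Im \lambda|}, \eqn{\gamma = -Re \lambda}.
#'
#' @param closed a ClosedMomentSystem.
#' @param start numeric starting point for the fixed-point search.
#' @param maxIter,tol Newton iteration controls.
#' @return a list with \code{omega} (NA when no complex pair exists),
#'   \code{gamma}, \code{hasComplexPair}, \code{fixedPoint} and
#'   \code{eigenvalues}.
#' @export
linearizedMode <- function(closed, start, maxIter = 200, tol = 1e-10) {
  f <- closed$rhs
  y <- as.numeric(start)
  conv <- FALSE
  for (it in seq_len(maxIter)) {
    fy <- f(y)
    if (sqrt(sum(fy^2)) < tol) { conv <- TRUE; break }
    J <- pracma::jacobian(f, y)
    step <- tryCatch(solve(J, fy), error = function(e)
      pracma::pinv(J) %*% fy)
    lam <- 1
    repeat {
      y2 <- y - lam * as.numeric(step)
      if (sqrt(sum(f(y2)^2)) < sqrt(sum(fy^2)) || lam < 1e-6) break
      lam <- lam / 2
    }
    y <- y2
  }
  if (!conv && sqrt(sum(f(y)^2)) > 1e-6)
    stop("fixed-point search did not converge (residual ",
         signif(sqrt(sum(f(y)^2)), 3), ")")
  J <- pracma::jacobian(f, y)
  ev <- eigen(J, only.values = TRUE)$values
  cx <- ev[abs(Im(ev)) > 1e-8]
  if (length(cx)) {
    lead <- cx[which.max(Re(cx))]
    list(omega = abs(Im(lead)), gamma = -Re(lead), hasComplexPair = TRUE,
         fixedPoint = y, eigenvalues = ev)
  } else {
    nz <- ev[Mod(ev) > 1e-8]
    gam <- if (length(nz)) -max(Re(nz)) else NA_real_
    list(omega = NA_real_, gamma = gam, hasComplexPair = FALSE,
         fixedPoint = y, eigenvalues = ev)
  }
}
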