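#' Ordered real Schur form of a generator with the zero mode last
#'
#' Computes an orthogonal Q and quasi-upper-triangular D1 with
#' M = Q D1 Q', arranging the probability-conservation zero eigenvalue in
#' the final diagonal position. Because the all-ones vector is a left null
#' vector of any generator, its orthogonal complement is an invariant
#' subspace of M; the decomposition is obtained by Schur-factorizing the
#' restriction of M to that complement and appending the normalized ones
#' direction as the last Schur vector. Consequently every Schur vector
#' except the last is orthogonal to the all-ones vector, so couplings built
#' from those vectors conserve probability automatically.
#'
#' @param G a \linkS4class{GeneratorMatrix} or plain generator matrix.
#' @param blockTol subdiagonal magnitude above which a 2x2 block is
#'   recognized.
#' @return a \linkS4class{SchurForm}.
#' @examples
#' M <- matrix(c(-1, 1, 1, -1), 2)
#' sf <- orderedSchur(M)
#' sf@D1   # diag(-2, 0), zero mode last
#' @export
orderedSchur <- function(G, blockTol = 1e-9) {
  M <- if (is(G, "GeneratorMatrix")) as.matrix(G@M) else as.matrix(G)
  n <- nrow(M)
  if (max(abs(colSums(M))) > 1e-8)
    stop("matrix is not a generator: column sums are not zero")
  if (n == 1) {
    return(new("SchurForm", Q = matrix(1, 1, 1), D1 = matrix(0, 1, 1),
               S1 = integer(0), S2 = integer(0),
               blocks = data.frame(position = integer(0), size = integer(0)),
               zeroModePosition = 1L))
  }
  # orthonormal basis with the ones direction first, complement after
  qr1 <- qr(matrix(1, n, 1))
  Qfull <- qr.Q(qr1, complete = TRUE)
  ones <- Qfull[, 1]
  if (sum(ones) < 0) ones <- -ones
  Q1 <- Qfull[, -1, drop = FALSE]
  M1 <- crossprod(Q1, M %*% Q1)
  sch <- Matrix::Schur(M1)
  Qt <- as.matrix(sch$Q)
  Tt <- as.matrix(sch$T)
  Qlead <- Q1 %*% Qt
  Q <- cbind(Qlead, ones)
  v <- crossprod(Qlead, M %*% ones)
  dnn <- as.numeric(crossprod(ones, M %*% ones))
  D1 <- rbind(cbind(Tt, v), c(rep(0, n - 1), dnn))
  dimnames(D1) <- NULL
  # block inventory of the leading (n-1) x (n-1) quasi-triangular part
  S1 <- integer(0); S2 <- integer(0)
  pos <- integer(0); size <- integer(0)
  i <- 1L
  while (i <= n - 1L) {
    if (i < n - 1L && abs(D1[i + 1L, i]) > blockTol) {
      S2 <- c(S2, i); pos <- c(pos, i); size <- c(size, 2L)
      i <- i + 2L
    } else {
      S1 <- c(S1, i); pos <- c(pos, i); size <- c(size, 1L)
      i <- i + 1L
    }
  }
  pos <- c(pos, n); size <- c(size, 1L)
  new("SchurForm", Q = Q, D1 = D1, S1 = S1, S2 = S2,
      blocks = data.frame(position = pos, size = size),
      zeroModePosition = as.integer(n))
}

#' Scalar Schur eigenvalues of a generator
#'
#' Convenience accessor: the 1x1 diagonal entries of the ordered Schur form
#' (the real eigenvalues of M), excluding the conservation zero mode.
#'
#' @param sf a \linkS4class{SchurForm}.
#' @param zeroTol entries with magnitude below this are reported but can be
#'   excluded by the caller as residual zero modes (absorbing states).
#' @return data.frame with columns \code{position} and \code{sigma1}.
#' @export
scalarModes <- function(sf, zeroTol = 1e-8) {
  data.frame(position = sf@S1,
             sigma1 = sf@D1[cbind(sf@S1, sf@S1)],
             isZeroMode = abs(sf@D1[cbind(sf@S1, sf@S1)]) <= zeroTol)
}

#' Slowest decaying real (scalar) mode of a Schur form
#'
#' The scalar diagonal entry with the largest strictly negative value (the
#' slowest direct-decay relaxation mode), skipping residual zero modes from
#' absorbing states.
#'
#' @param sf a \linkS4class{SchurForm}.
#' @param zeroTol magnitude below which a scalar entry counts as zero.
#' @return list with \code{position} and \code{sigma1}.
#' @export
slowestRealMode <- function(sf, zeroTol = 1e-8) {
  sm <- scalarModes(sf, zeroTol)
  sm <- sm[!sm$isZeroMode & sm$sigma1 < 0, ]
  if (!nrow(sm)) stop("no strictly negative scalar mode found")
  best <- sm[which.max(sm$sigma1), ]
  list(position = best$position, sigma1 = best$sigma1)
}
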