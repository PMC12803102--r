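#' Assemble the master-equation generator matrix
#'
#' Builds the n x n transition-rate matrix M over an enumerated state space:
#' for each reaction j and source state n with target n + S_j inside the
#' space, M[target, source] += a_j(n); the diagonal is minus the column's
#' off-diagonal sum. On a truncated box, jumps leaving the box are dropped
#' from both the flux and the escape rate (reflecting truncation), which
#' keeps M a proper generator.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param space a \linkS4class{StateSpace} enumerated for \code{net}.
#' @return a \linkS4class{GeneratorMatrix} (sparse).
#' @examples
#' tri <- fixture("trimolecular")$network
#' space <- enumerateStates(tri, "closed-conserved", totals = 4)
#' G <- buildGenerator(tri, space)
#' max(abs(Matrix::colSums(rateMatrix(G))))  # 0 within 1e-12
#' @export
buildGenerator <- function(net, space) {
  sts <- space@states
  nS <- nrow(sts)
  S <- netStoich(net)
  A <- propensityMatrix(net, sts)
  keys <- .stateKeys(sts)
  ii <- jj <- integer(0)
  xx <- numeric(0)
  escape <- numeric(nS)
  for (j in seq_len(nReactions(net))) {
    tgt <- sweep(sts, 2L, S[, j], "+")
    ok <- rowSums(tgt < 0) == 0
    idx <- rep(NA_integer_, nS)
    idx[ok] <- match(.stateKeys(tgt[ok, , drop = FALSE]), keys)
    live <- which(!is.na(idx) & A[, j] > 0)
    if (length(live)) {
      ii <- c(ii, idx[live])
      jj <- c(jj, live)
      xx <- c(xx, A[live, j])
      escape[live] <- escape[live] + A[live, j]
    }
  }
  M <- Matrix::sparseMatrix(i = c(ii, seq_len(nS)), j = c(jj, seq_len(nS)),
                            x = c(xx, -escape), dims = c(nS, nS))
  new("GeneratorMatrix", M = M, space = space, network = net)
}

#' Spectral summary of a generator matrix
#'
#' Computes the full eigenvalue spectrum (sorted by descending real part,
#' ties by ascending |imaginary part|), the multiplicity of the zero
#' eigenvalue, and a basis of the stationary null space. By the structure of
#' a generator (zero column sums, nonnegative off-diagonals), every
#' eigenvalue must have nonpositive real part; a violation beyond tolerance
#' is flagged as an internal-consistency failure.
#'
#' @param G a \linkS4class{GeneratorMatrix} or a plain generator matrix.
#' @param tol magnitude below which an eigenvalue is counted as zero
#'   (default 1e-10, eigensolver noise at double precision).
#' @return a \linkS4class{SpectralSummary}.
#' @export
spectralSummary <- function(G, tol = 1e-10) {
  M <- if (is(G, "GeneratorMatrix")) as.matrix(G@M) else as.matrix(G)
  eig <- eigen(M)
  ev <- as.complex(eig$values)
  ord <- order(-Re(ev), abs(Im(ev)))
  ev <- ev[ord]
  if (max(Re(ev)) > 1e-8)
    stop("internal consistency failure: generator eigenvalue with positive ",
         "real part ", max(Re(ev)))
  zero <- which(Mod(ev) <= tol)
  vecs <- eig$vectors[, ord, drop = FALSE][, zero, drop = FALSE]
  null <- Re(vecs)
  # normalize stationary vectors to unit probability mass where possible
  for (k in seq_len(ncol(null))) {
    s <- sum(null[, k])
    if (abs(s) > tol) null[, k] <- null[, k] / s
  }
  new("SpectralSummary", eigenvalues = ev,
      zeroMultiplicity = length(zero), nullVectors = null, tol = tol)
}

#' Absorbing states of a generator
#'
#' States with zero total propensity (all-zero columns of M).
#'
#' @param G a \linkS4class{GeneratorMatrix}.
#' @return integer indices of absorbing states.
#' @export
absorbingStates <- function(G) {
  cs <- Matrix::colSums(abs(G@M))
  which(cs == 0)
}

#' Export a generator matrix as TSV
#'
#' Dense tab-separated export with state labels ("a,b,c" copy-number keys)
#' as header row and first column.
#'
#' @param G a \linkS4class{GeneratorMatrix}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
exportGenerator <- function(G, path) {
  M <- as.matrix(G@M)
  labels <- .stateKeys(G@space@states)
  df <- data.frame(state = labels, as.data.frame(M), check.names = FALSE)
  colnames(df) <- c("state", labels)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
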