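## Internal multivariate polynomial arithmetic over copy-number variables.
## A polynomial in N variables is a list(expo = integer matrix (terms x N),
## coef = numeric). Exact expansion of propensities and moment jumps only
## needs add/multiply/shift, so no general CAS is required.

.polyZero <- function(N) list(expo = matrix(0L, 0, N), coef = numeric(0))

.polyConst <- function(value, N) {
  if (value == 0) return(.polyZero(N))
  list(expo = matrix(0L, 1, N), coef = value)
}

.polyVar <- function(i, N) {
  e <- matrix(0L, 1, N)
  e[1, i] <- 1L
  list(expo = e, coef = 1)
}

.polySimplify <- function(p) {
  if (!nrow(p$expo)) return(p)
  keys <- apply(p$expo, 1L, paste, collapse = ",")
  coef <- rowsum(p$coef, keys, reorder = FALSE)[, 1]
  keep <- which(coef != 0)
  if (!length(keep)) return(.polyZero(ncol(p$expo)))
  ukeys <- rownames(rowsum(p$coef, keys, reorder = FALSE))[keep]
  first <- match(ukeys, keys)
  list(expo = p$expo[first, , drop = FALSE], coef = unname(coef[keep]))
}

.polyAdd <- function(p, q) {
  .polySimplify(list(expo = rbind(p$expo, q$expo), coef = c(p$coef, q$coef)))
}

.polyScale <- function(p, s) {
  if (s == 0) return(.polyZero(ncol(p$expo)))
  list(expo = p$expo, coef = p$coef * s)
}

.polyMul <- function(p, q) {
  np <- nrow(p$expo); nq <- nrow(q$expo)
  if (!np || !nq) return(.polyZero(ncol(p$expo)))
  ip <- rep(seq_len(np), each = nq)
  iq <- rep(seq_len(nq), times = np)
  .polySimplify(list(expo = p$expo[ip, , drop = FALSE] +
                       q$expo[iq, , drop = FALSE],
                     coef = p$coef[ip] * q$coef[iq]))
}

.polyPow <- function(p, k) {
  N <- ncol(p$expo)
  out <- .polyConst(1, N)
  while (k > 0) {
    out <- .polyMul(out, p)
    k <- k - 1
  }
  out
}

## n_i (n_i - 1) ... (n_i - s + 1): combinatorial mass-action factor.
.fallingFactorialPoly <- function(i, s, N) {
  out <- .polyConst(1, N)
  for (k in seq_len(s) - 1L) {
    out <- .polyMul(out, .polyAdd(.polyVar(i, N), .polyConst(-k, N)))
  }
  out
}

## Substitute n -> n + shift (integer vector), expanding binomially.
.polyShift <- function(p, shift) {
  N <- ncol(p$expo)
  out <- .polyZero(N)
  for (t in seq_len(nrow(p$expo))) {
    term <- .polyConst(p$coef[t], N)
    for (i in seq_len(N)) {
      e <- p$expo[t, i]
      if (e > 0)

        term <- .polyMul(term, .polyPow(
          .polyAdd(.polyVar(i, N), .polyConst(shift[i], N)), e))
    }
    out <- .polyAdd(out, term)
  }
  out
}

## Evaluate at a numeric point (vector of length N).
.polyEval <- function(p, x) {
  if (!nrow(p$expo)) return(0)
  sum(p$coef * apply(p$expo, 1L, function(e) prod(x^e)))
}

## Propensity of reaction j as a polynomial in the copy numbers.
.propensityPoly <- function(net, j) {
  N <- length(net@speciesNames)
  out <- .polyConst(net@rateConstants[j] *
                      net@systemSize^net@omegaExponents[j], N)
  for (i in seq_len(N)) {
    s <- net@reactantStoich[i, j]
    if (s > 0) out <- .polyMul(out, .fallingFactorialPoly(i, s, N))
  }
  out
}
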