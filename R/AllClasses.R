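#' @import methods
#' @importFrom Matrix Matrix colSums Diagonal Schur expm sparseMatrix
NULL

#' Mass-action reaction network
#'
#' Holds a chemical reaction network with N species and R mass-action
#' reactions. Each reaction j converts a reactant multiset (column j of
#' \code{reactantStoich}) into a product multiset (column j of
#' \code{productStoich}) with rate constant \eqn{c_j} and a declared
#' system-size scaling exponent \eqn{w_j}, so that the propensity in state n
#' is \eqn{a_j(n) = c_j \Omega^{w_j} \prod_i n_i (n_i - 1) \cdots
#' (n_i - s_{ij} + 1)} (combinatorial mass action).
#'
#' @slot speciesNames character vector of species identifiers.
#' @slot reactantStoich integer matrix (N x R) of reactant stoichiometries.
#' @slot productStoich integer matrix (N x R) of product stoichiometries.
#' @slot rateConstants nonnegative numeric vector of length R.
#' @slot omegaExponents numeric vector of length R; the power of the system
#'   size entering each propensity.
#' @slot systemSize positive numeric scalar (the system size Omega).
#' @slot conservation list of character vectors; each is a group of species
#'   whose total copy number every reaction conserves (may be empty).
#' @exportClass ReactionNetwork
setClass("ReactionNetwork",
  representation(
    speciesNames = "character",
    reactantStoich = "matrix",
    productStoich = "matrix",
    rateConstants = "numeric",
    omegaExponents = "numeric",
    systemSize = "numeric",
    conservation = "list"
  )
)

setValidity("ReactionNetwork", function(object) {
  msg <- character()
  N <- length(object@speciesNames)
  R <- ncol(object@reactantStoich)
  if (R < 1) msg <- c(msg, "network must contain at least one reaction")
  if (nrow(object@reactantStoich) != N || nrow(object@productStoich) != N)
    msg <- c(msg, "stoichiometry matrices must have one row per species")
  if (!identical(dim(object@reactantStoich), dim(object@productStoich)))
    msg <- c(msg, "reactant and product stoichiometry dimensions differ")
  if (any(object@reactantStoich < 0) || any(object@productStoich < 0))
    msg <- c(msg, "stoichiometric coefficients must be nonnegative")
  if (length(object@rateConstants) != R)
    msg <- c(msg, "need one rate constant per reaction")
  if (any(object@rateConstants < 0))
    msg <- c(msg, "rate constants must be nonnegative")
  if (length(object@omegaExponents) != R)
    msg <- c(msg, "need one system-size exponent per reaction")
  if (length(object@systemSize) != 1 || object@systemSize <= 0)
    msg <- c(msg, "system size must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' Enumerated copy-number state space
#'
#' An ordered (lexicographic) enumeration of the copy-number states over
#' which a master-equation generator is assembled. Either a closed,
#' conservation-constrained enumeration or a truncated box.
#'
#' @slot states integer matrix, one row per state, one column per species.
#' @slot kind either \code{"closed-conserved"} or \code{"truncated-box"}.
#' @slot bounds integer per-species upper bounds (truncated-box) or empty.
#' @slot totals named list of conserved totals (closed-conserved) or empty.
#' @slot speciesNames character vector matching the parent network.
#' @exportClass StateSpace
setClass("StateSpace",
  representation(
    states = "matrix",
    kind = "character",
    bounds = "integer",
    totals = "list",
    speciesNames = "character"
  )
)

setValidity("StateSpace", function(object) {
  msg <- character()
  if (!object@kind %in% c("closed-conserved", "truncated-box"))
    msg <- c(msg, "kind must be 'closed-conserved' or 'truncated-box'")
  if (any(object@states < 0)) msg <- c(msg, "states must be nonnegative")
  keys <- apply(object@states, 1L, paste, collapse = ",")
  if (anyDuplicated(keys)) msg <- c(msg, "duplicate states")
  if (length(msg)) msg else TRUE
})

#' Master-equation generator matrix
#'
#' The n x n transition-rate matrix M of the chemical master equation over an
#' enumerated state space: \code{M[beta, alpha]} is the rate of jumping from
#' state alpha to state beta, diagonals are minus the total escape rate, and
#' every column sums to zero (probability conservation).
#'
#' @slot M sparse numeric matrix (Matrix package).
#' @slot space the \linkS4class{StateSpace} the matrix is indexed by.
#' @slot network the \linkS4class{ReactionNetwork} it was built from.
#' @exportClass GeneratorMatrix
setClass("GeneratorMatrix",
  representation(M = "ANY", space = "StateSpace", network = "ReactionNetwork")
)

setValidity("GeneratorMatrix", function(object) {
  msg <- character()
  M <- object@M
  if (nrow(M) != ncol(M)) msg <- c(msg, "M must be square")
  if (nrow(M) != nrow(object@space@states))
    msg <- c(msg, "M dimension must match state-space size")
  cs <- Matrix::colSums(M)
  if (max(abs(cs)) > 1e-12)
    msg <- c(msg, "columns of a generator must sum to zero (within 1e-12)")
  d <- Matrix::diag(M)
  if (any(d > 1e-12)) msg <- c(msg, "diagonal entries must be <= 0")
  offmin <- min(M - Matrix::Diagonal(nrow(M), d))
  if (offmin < -1e-12) msg <- c(msg, "off-diagonal entries must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Spectral summary of a generator
#'
#' @slot eigenvalues complex vector sorted by descending real part (ties by
#'   ascending absolute imaginary part).
#' @slot zeroMultiplicity number of eigenvalues with modulus below tolerance.
#' @slot nullVectors matrix whose columns span the stationary (null) space.
#' @slot tol tolerance used to call an eigenvalue zero.
#' @exportClass SpectralSummary
setClass("SpectralSummary",
  representation(
    eigenvalues = "complex",
    zeroMultiplicity = "integer",
    nullVectors = "matrix",
    tol = "numeric"
  )
)

#' Ensemble of stochastic simulation trajectories
#'
#' Seeded Gillespie realisations sampled onto a common uniform time grid.
#'
#' @slot timeGrid increasing numeric vector of sampling times.
#' @slot counts integer array with dimensions (trajectory, time, species).
#' @slot seeds per-trajectory RNG seeds derived from the base seed.
#' @slot baseSeed the base seed the ensemble was generated from.
#' @slot speciesNames character vector of species identifiers.
#' @slot network the simulated \linkS4class{ReactionNetwork}.
#' @slot absorptionTimes per-trajectory time of entering a zero-propensity
#'   state (Inf if never observed).
#' @exportClass TrajectoryEnsemble
setClass("TrajectoryEnsemble",
  representation(
    timeGrid = "numeric",
    counts = "array",
    seeds = "integer",
    baseSeed = "integer",
    speciesNames = "character",
    network = "ReactionNetwork",
    absorptionTimes = "numeric"
  )
)

setValidity("TrajectoryEnsemble", function(object) {
  msg <- character()
  if (length(dim(object@counts)) != 3)
    msg <- c(msg, "counts must be a (trajectory, time, species) array")
  if (dim(object@counts)[2] != length(object@timeGrid))
    msg <- c(msg, "time dimension must match the grid")
  if (any(diff(object@timeGrid) <= 0))
    msg <- c(msg, "time grid must be strictly increasing")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Moment-equation system for a mass-action network
#'
#' The exact time-derivatives of all raw moments \eqn{\langle n^m \rangle}
#' with \eqn{1 \le |m| \le q}, each expanded as a linear combination of raw
#' moments (of order up to \eqn{|m| + d_{max}}), before or after closure.
#'
#' @slot order the moment order q at which the hierarchy is truncated.
#' @slot indices integer matrix of tracked multi-indices (rows).
#' @slot rhs list (one per tracked moment) of term tables: each has a
#'   numeric \code{coef} vector and an integer matrix \code{idx} of raw
#'   moment multi-indices.
#' @slot closure \code{"none"} or \code{"central-moment-neglect"}.
#' @slot network the originating \linkS4class{ReactionNetwork}.
#' @exportClass MomentSystem
setClass("MomentSystem",
  representation(
    order = "integer",
    indices = "matrix",
    rhs = "list",
    closure = "character",
    network = "ReactionNetwork"
  )
)

#' Real Schur form of a generator with the zero mode ordered last
#'
#' Orthogonal Q and quasi-upper-triangular D1 with M = Q D1 Q'. The
#' probability-conservation (zero) eigenvalue occupies the final diagonal
#' position, so every other Schur vector is orthogonal to the all-ones
#' vector; couplings built from those vectors automatically conserve
#' probability.
#'
#' @slot Q orthogonal matrix of Schur vectors.
#' @slot D1 quasi-upper-triangular matrix (1x1 and 2x2 diagonal blocks).
#' @slot S1 integer positions of scalar (1x1) diagonal entries.
#' @slot S2 integer starting positions of 2x2 diagonal blocks.
#' @slot blocks data.frame inventory (position, size, eigenvalue parts).
#' @slot zeroModePosition index of the conservation zero mode (always n).
#' @exportClass SchurForm
setClass("SchurForm",
  representation(
    Q = "matrix",
    D1 = "matrix",
    S1 = "integer",
    S2 = "integer",
    blocks = "data.frame",
    zeroModePosition = "integer"
  )
)

#' Coupled Markov / non-Markov linear system
#'
#' The block system dP/dt = M P + B1 x, dx/dt = B2 P + C x assembled into
#' A = [[M, B1], [B2, C]]. Probability conservation requires every column of
#' B1 to sum to zero.
#'
#' @slot M n x n generator block.
#' @slot B1 n x l coupling into the probability dynamics (zero column sums).
#' @slot B2 l x n coupling reading out the probabilities.
#' @slot C l x l dynamics of the non-Markovian input.
#' @slot A the assembled (n+l) x (n+l) matrix.
#' @slot n,l block dimensions.
#' @exportClass CoupledLinearSystem
setClass("CoupledLinearSystem",
  representation(
    M = "matrix", B1 = "matrix", B2 = "matrix", Cmat = "matrix",
    A = "matrix", n = "integer", l = "integer"
  )
)

setValidity("CoupledLinearSystem", function(object) {
  msg <- character()
  n <- object@n; l <- object@l
  if (!identical(dim(object@M), c(n, n))) msg <- c(msg, "M must be n x n")
  if (!identical(dim(object@B1), c(n, l))) msg <- c(msg, "B1 must be n x l")
  if (!identical(dim(object@B2), c(l, n))) msg <- c(msg, "B2 must be l x n")
  if (!identical(dim(object@Cmat), c(l, l))) msg <- c(msg, "C must be l x l")
  if (!identical(dim(object@A), c(n + l, n + l)))
    msg <- c(msg, "A must be (n+l) x (n+l)")
  if (max(abs(colSums(object@B1))) > 1e-12)
    msg <- c(msg, "columns of B1 must sum to zero (probability conservation)")
  if (max(abs(object@A[seq_len(n), seq_len(n)] - object@M)) > 0)
    msg <- c(msg, "top-left block of A must equal M")
  if (length(msg)) msg else TRUE
})

#' Result of a coherent-oscillation coupling design
#'
#' @slot targetKind "real" or "complex".
#' @slot targetIndex Schur position of the targeted mode (scalar entry or
#'   start of the 2x2 block).
#' @slot sigma1 targeted Markov eigenvalue (real designs) or the 2x2 Schur
#'   block (complex designs).
#' @slot sigma2 designed non-Markov eigenvalue(s).
#' @slot q1,q2 the chosen coupling split.
#' @slot couplingProduct the product q1 * q2.
#' @slot predictedOmega designed angular frequency.
#' @slot achievedEigenvalues full spectrum of the assembled A.
#' @slot leadingEigenvalue the achieved oscillatory eigenvalue (positive
#'   imaginary part member of the pair).
#' @slot maxOtherRealPart largest real part among non-targeted eigenvalues.
#' @slot system the assembled \linkS4class{CoupledLinearSystem}.
#' @slot cubic the \linkS4class{CharacteristicCubic} (complex designs) or NULL.
#' @exportClass DesignResult
setClass("DesignResult",
  representation(
    targetKind = "character",
    targetIndex = "integer",
    sigma1 = "ANY",
    sigma2 = "numeric",
    q1 = "numeric",
    q2 = "numeric",
    couplingProduct = "numeric",
    predictedOmega = "numeric",
    achievedEigenvalues = "complex",
    leadingEigenvalue = "complex",
    maxOtherRealPart = "numeric",
    system = "CoupledLinearSystem",
    cubic = "ANY"
  )
)

#' Characteristic cubic of the reduced complex-mode coupling
#'
#' Coefficients (a, b, c, d) of a*lambda^3 + b*lambda^2 + c*lambda + d = 0
#' arising from coupling a 2x2 Schur block to a one-dimensional input with
#' the weakly coupled direction dropped. A purely imaginary conjugate root
#' pair exists iff b*c = a*d with b > 0 and c > 0.
#'
#' @slot coefficients numeric vector (a, b, c, d).
#' @slot roots complex roots of the cubic.
#' @exportClass CharacteristicCubic
setClass("CharacteristicCubic",
  representation(coefficients = "numeric", roots = "complex")
)

#' Damped-sinusoid fit of a signal
#'
#' Parameters of the least-squares fit
#' \eqn{A_0 e^{-\gamma t} \cos(\omega t + \phi) + c}.
#'
#' @slot amplitude fitted amplitude A0 (>= 0).
#' @slot decayRate fitted decay rate gamma (may be negative: growth).
#' @slot omega fitted angular frequency.
#' @slot phase fitted phase.
#' @slot offset fitted constant offset.
#' @slot residualNorm Euclidean norm of the fit residual.
#' @slot converged logical convergence flag (non-convergence is flagged,
#'   never thrown).
#' @exportClass OscillationFit
setClass("OscillationFit",
  representation(
    amplitude = "numeric", decayRate = "numeric", omega = "numeric",
    phase = "numeric", offset = "numeric", residualNorm = "numeric",
    converged = "logical"
  )
)

#' Normalized autocorrelation curve
#'
#' @slot lags nonnegative lag times.
#' @slot values autocorrelation values in [-1, 1]; exactly 1 at lag zero.
#' @slot mode "per-trajectory" (average of individual-trajectory ACFs) or
#'   "ensemble" (ACF of the ensemble-mean signal).
#' @slot meta estimator metadata.
#' @exportClass AutocorrelationCurve
setClass("AutocorrelationCurve",
  representation(lags = "numeric", values = "numeric", mode = "character",
                 meta = "list")
)

setValidity("AutocorrelationCurve", function(object) {
  msg <- character()
  if (length(object@lags) != length(object@values))
    msg <- c(msg, "lags and values must have equal length")
  if (abs(object@values[1] - 1) > 1e-12)
    msg <- c(msg, "autocorrelation at lag zero must equal 1")
  if (any(abs(object@values) > 1 + 1e-9))
    msg <- c(msg, "autocorrelation values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Integrated trajectory of a coupled linear system
#'
#' @slot time the integration grid.
#' @slot P matrix of probability paths (time x n). Linear coupling can drive
#'   components transiently negative; this is reported, not clamped.
#' @slot x matrix of non-Markovian input paths (time x l).
#' @slot conservationResidual max over time of |1'P(t) - 1|.
#' @exportClass CoupledTrajectory
setClass("CoupledTrajectory",
  representation(time = "numeric", P = "matrix", x = "matrix",
                 conservationResidual = "numeric")
)

## ---- show methods -------------------------------------------------------

setMethod("show", "ReactionNetwork", function(object) {
  cat(sprintf("ReactionNetwork: %d species, %d reactions (Omega = %g)\n",
              length(object@speciesNames), ncol(object@reactantStoich),
              object@systemSize))
  cat("  species:", paste(object@speciesNames, collapse = ", "), "\n")
  S <- object@productStoich - object@reactantStoich
  for (j in seq_len(ncol(S))) {
    lhs <- .sideLabel(object@reactantStoich[, j], object@speciesNames)
    rhs <- .sideLabel(object@productStoich[, j], object@speciesNames)
    cat(sprintf("  [%d] %s -> %s   rate %g, Omega^%g\n", j, lhs, rhs,
                object@rateConstants[j], object@omegaExponents[j]))
  }
  invisible(object)
})

.sideLabel <- function(stoich, names) {
  nz <- which(stoich > 0)
  if (!length(nz)) return("0")
  paste(ifelse(stoich[nz] > 1, paste0(stoich[nz], " "), ""), names[nz],
        sep = "", collapse = " + ")
}

setMethod("show", "StateSpace", function(object) {
  cat(sprintf("StateSpace (%s): %d states over %d species\n", object@kind,
              nrow(object@states), ncol(object@states)))
  invisible(object)
})

setMethod("show", "GeneratorMatrix", function(object) {
  cat(sprintf("GeneratorMatrix: %d x %d over %s state space\n",
              nrow(object@M), ncol(object@M), object@space@kind))
  cat(sprintf("  max |column sum| = %.3g\n",
              max(abs(Matrix::colSums(object@M)))))
  invisible(object)
})

setMethod("show", "SpectralSummary", function(object) {
  cat(sprintf("SpectralSummary: %d eigenvalues, zero multiplicity %d\n",
              length(object@eigenvalues), object@zeroMultiplicity))
  cat(sprintf("  slowest nonzero real part: %.6g\n",
              .slowestNonzeroRe(object)))
  invisible(object)
})

.slowestNonzeroRe <- function(object) {
  ev <- object@eigenvalues
  nz <- ev[Mod(ev) > object@tol]
  if (!length(nz)) return(NA_real_)
  max(Re(nz))
}

setMethod("show", "TrajectoryEnsemble", function(object) {
  d <- dim(object@counts)
  cat(sprintf(
    "TrajectoryEnsemble: %d trajectories x %d times x %d species (seed %d)\n",
    d[1], d[2], d[3], object@baseSeed))
  invisible(object)
})

setMethod("show", "SchurForm", function(object) {
  cat(sprintf(
    "SchurForm: n = %d, %d scalar modes, %d complex blocks, zero mode last\n",
    nrow(object@Q), length(object@S1), length(object@S2)))
  invisible(object)
})

setMethod("show", "CoupledLinearSystem", function(object) {
  cat(sprintf("CoupledLinearSystem: n = %d Markov states + l = %d inputs\n",
              object@n, object@l))
  invisible(object)
})

setMethod("show", "DesignResult", function(object) {
  cat(sprintf("DesignResult (%s mode, Schur position %d)\n",
              object@targetKind, object@targetIndex))
  cat(sprintf("  sigma2 = %s, coupling product = %.6g\n",
              paste(signif(object@sigma2, 6), collapse = ", "),
              object@couplingProduct))
  cat(sprintf("  predicted omega = %.6g; achieved %.3g %+.6gi\n",
              object@predictedOmega, Re(object@leadingEigenvalue),
              Im(object@leadingEigenvalue)))
  cat(sprintf("  max other Re(lambda) = %.3g\n", object@maxOtherRealPart))
  invisible(object)
})

setMethod("show", "OscillationFit", function(object) {
  cat(sprintf(
    "OscillationFit: A0 = %.6g, gamma = %.6g, omega = %.6g (converged: %s)\n",
    object@amplitude, object@decayRate, object@omega, object@converged))
  invisible(object)
})

setMethod("show", "CoupledTrajectory", function(object) {
  cat(sprintf(
    "CoupledTrajectory: %d times, n = %d, l = %d; conservation residual %.3g\n",
    length(object@time), ncol(object@P), ncol(object@x),
    object@conservationResidual))
  invisible(object)
})
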