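## Generics and simple accessors.

#' Species names of an object
#' @param x a ReactionNetwork, StateSpace or TrajectoryEnsemble.
#' @return character vector of species identifiers.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@speciesNames)

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "StateSpace", function(x) x@speciesNames)

#' @rdname speciesNames
#' @export
setMethod("speciesNames", "TrajectoryEnsemble", function(x) x@speciesNames)

#' Net stoichiometric matrix S = products - reactants
#' @param x a ReactionNetwork.
#' @return integer matrix (species x reactions).
#' @export
setGeneric("netStoich", function(x) standardGeneric("netStoich"))

#' @rdname netStoich
#' @export
setMethod("netStoich", "ReactionNetwork",
          function(x) x@productStoich - x@reactantStoich)

#' Number of reactions in a network
#' @param x a ReactionNetwork.
#' @export
setGeneric("nReactions", function(x) standardGeneric("nReactions"))

#' @rdname nReactions
#' @export
setMethod("nReactions", "ReactionNetwork", function(x) ncol(x@reactantStoich))

#' Number of enumerated states
#' @param x a StateSpace or GeneratorMatrix.
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname nStates
#' @export
setMethod("nStates", "StateSpace", function(x) nrow(x@states))

#' @rdname nStates
#' @export
setMethod("nStates", "GeneratorMatrix", function(x) nrow(x@M))

#' State matrix of an enumeration
#' @param x a StateSpace or GeneratorMatrix.
#' @return integer matrix, one row per state.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname states
#' @export
setMethod("states", "StateSpace", function(x) x@states)

#' @rdname states
#' @export
setMethod("states", "GeneratorMatrix", function(x) x@space@states)

#' Underlying transition-rate matrix
#' @param x a GeneratorMatrix or CoupledLinearSystem.
#' @return numeric matrix (sparse for GeneratorMatrix).
#' @export
setGeneric("rateMatrix", function(x) standardGeneric("rateMatrix"))

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "GeneratorMatrix", function(x) x@M)

#' @rdname rateMatrix
#' @export
setMethod("rateMatrix", "CoupledLinearSystem", function(x) x@M)

#' State space of a generator
#' @param x a GeneratorMatrix.
#' @export
setGeneric("stateSpace", function(x) standardGeneric("stateSpace"))

#' @rdname stateSpace
#' @export
setMethod("stateSpace", "GeneratorMatrix", function(x) x@space)

#' Eigenvalues stored in an object
#' @param x a SpectralSummary or DesignResult.
#' @return complex vector.
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "SpectralSummary", function(x) x@eigenvalues)

#' @rdname eigenvalues
#' @export
setMethod("eigenvalues", "DesignResult", function(x) x@achievedEigenvalues)

#' Time grid of a simulated object
#' @param x a TrajectoryEnsemble or CoupledTrajectory.
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "TrajectoryEnsemble", function(x) x@timeGrid)

#' @rdname timeGrid
#' @export
setMethod("timeGrid", "CoupledTrajectory", function(x) x@time)

#' Trajectory counts array
#' @param x a TrajectoryEnsemble.
#' @return integer array (trajectory, time, species).
#' @export
setGeneric("trajectoryCounts", function(x) standardGeneric("trajectoryCounts"))

#' @rdname trajectoryCounts
#' @export
setMethod("trajectoryCounts", "TrajectoryEnsemble", function(x) x@counts)

#' Number of trajectories in an ensemble
#' @param x a TrajectoryEnsemble.
#' @export
setGeneric("nTrajectories", function(x) standardGeneric("nTrajectories"))

#' @rdname nTrajectories
#' @export
setMethod("nTrajectories", "TrajectoryEnsemble", function(x) dim(x@counts)[1])

#' Assembled coupled-system matrix A
#' @param x a CoupledLinearSystem or DesignResult.
#' @export
setGeneric("coupledMatrix", function(x) standardGeneric("coupledMatrix"))

#' @rdname coupledMatrix
#' @export
setMethod("coupledMatrix", "CoupledLinearSystem", function(x) x@A)

#' @rdname coupledMatrix
#' @export
setMethod("coupledMatrix", "DesignResult", function(x) x@system@A)

#' Coupled system carried by a design result
#' @param x a DesignResult.
#' @export
setGeneric("coupledSystem", function(x) standardGeneric("coupledSystem"))

#' @rdname coupledSystem
#' @export
setMethod("coupledSystem", "DesignResult", function(x) x@system)

#' Designed angular frequency
#' @param x a DesignResult.
#' @export
setGeneric("predictedOmega", function(x) standardGeneric("predictedOmega"))

#' @rdname predictedOmega
#' @export
setMethod("predictedOmega", "DesignResult", function(x) x@predictedOmega)
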