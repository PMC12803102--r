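#' Shipped model fixtures
#'
#' Returns one of the built-in reaction networks together with its
#' recommended initial condition. The trimolecular closed cycle starts from
#' (10, 5, 5) and the Brusselator from (1, 1); rate constants are
#' documented package defaults (see the model files under
#' \code{inst/extdata} and the methods vignette), chosen to place the rate
#' equations in their oscillatory regimes.
#'
#' @param name one of \code{"trimolecular"}, \code{"brusselator"},
#'   \code{"birth-death"}, \code{"two-state"}.
#' @return a list with \code{network} (\linkS4class{ReactionNetwork}),
#'   \code{init} (integer state) and \code{notes}.
#' @examples
#' fixture("two-state")$network
#' @export
fixture <- function(name) {
  files <- c("trimolecular" = "trimolecular.yaml",
             "brusselator" = "brusselator.yaml",
             "birth-death" = "birth_death.yaml",
             "two-state" = "two_state.yaml")
  if (!name %in% names(files))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(files), collapse = ", "))
  path <- system.file("extdata", files[[name]], package = "MarkovRhythm",
                      mustWork = TRUE)
  net <- loadNetwork(path)
  init <- switch(name,
                 "trimolecular" = c(10L, 5L, 5L),
                 "brusselator" = c(1L, 1L),
                 "birth-death" = 0L,
                 "two-state" = c(1L, 0L))
  notes <- switch(name,
    "trimolecular" = paste(
      "Closed autocatalytic cycle; conserved total 20 from (10, 5, 5).",
      "Unit rate constants are package defaults."),
    "brusselator" = paste(
      "Open-system oscillator; constants are package defaults in the",
      "oscillatory rate-equation regime (reduced a = 1, b = 3), Omega = 5."),
    "birth-death" = "Linear birth-death test network (moments closure-free).",
    "two-state" = "Symmetric two-state chain used in unit tests.")
  list(network = net, init = init, notes = notes)
}

#' Serialize a design result to a structured text document
#'
#' Writes the coupled-system blocks (row-major, with dimensions), the
#' design parameters and the achieved spectrum as JSON, so that a design
#' can be reloaded and re-integrated without recomputation.
#'
#' @param design a \linkS4class{DesignResult}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeDesign <- function(design, path) {
  sys <- design@system
  mat <- function(m) list(dim = dim(m), data = as.numeric(t(m)))
  doc <- list(
    targetKind = design@targetKind,
    targetIndex = design@targetIndex,
    sigma2 = design@sigma2,
    q1 = design@q1, q2 = design@q2,
    couplingProduct = design@couplingProduct,
    predictedOmega = design@predictedOmega,
    maxOtherRealPart = design@maxOtherRealPart,
    leadingEigenvalue = c(Re(design@leadingEigenvalue),
                          Im(design@leadingEigenvalue)),
    n = sys@n, l = sys@l,
    M = mat(sys@M), B1 = mat(sys@B1), B2 = mat(sys@B2), C = mat(sys@Cmat))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a serialized design back into a coupled system
#'
#' @param path a file written by \code{\link{writeDesign}}.
#' @return a list with \code{system} (\linkS4class{CoupledLinearSystem})
#'   and the stored design parameters.
#' @export
readDesign <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  unmat <- function(m) matrix(m$data, m$dim[1], m$dim[2], byrow = TRUE)
  sys <- coupledLinearSystem(unmat(doc$M), unmat(doc$B1), unmat(doc$B2),
                             unmat(doc$C))
  doc$system <- sys
  doc
}
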