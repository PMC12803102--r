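#' Construct a mass-action reaction network
#'
#' Low-level constructor; most users will call \code{\link{loadNetwork}} or
#' \code{\link{fixture}} instead.
#'
#' @param species character vector of species names.
#' @param reactants,products integer matrices (species x reactions) of
#'   stoichiometric coefficients.
#' @param rates nonnegative numeric rate constants, one per reaction.
#' @param omegaExponents numeric system-size exponents, one per reaction
#'   (default 0: no system-size scaling).
#' @param omega positive system size (default 1).
#' @param conservation optional list of character vectors naming species
#'   groups whose summed copy number is conserved by every reaction.
#' @return a validated \linkS4class{ReactionNetwork}.
#' @examples
#' twoState <- reactionNetwork(
#'   species = c("A", "B"),
#'   reactants = matrix(c(1, 0, 0, 1), 2),
#'   products  = matrix(c(0, 1, 1, 0), 2),
#'   rates = c(1, 1), conservation = list(c("A", "B")))
#' @export
reactionNetwork <- function(species, reactants, products, rates,
                            omegaExponents = rep(0, length(rates)),
                            omega = 1, conservation = list()) {
  reactants <- as.matrix(reactants)
  products <- as.matrix(products)
  storage.mode(reactants) <- "integer"
  storage.mode(products) <- "integer"
  rownames(reactants) <- rownames(products) <- species
  net <- new("ReactionNetwork",
             speciesNames = as.character(species),
             reactantStoich = reactants, productStoich = products,
             rateConstants = as.numeric(rates),
             omegaExponents = as.numeric(omegaExponents),
             systemSize = as.numeric(omega),
             conservation = conservation)
  .checkConservation(net)
  net
}

.checkConservation <- function(net) {
  S <- netStoich(net)
  for (grp in net@conservation) {
    idx <- match(grp, net@speciesNames)
    if (anyNA(idx))
      stop("conservation group names unknown species: ",
           paste(grp[is.na(idx)], collapse = ", "))
    bad <- which(colSums(S[idx, , drop = FALSE]) != 0)
    if (length(bad))
      stop("reaction(s) ", paste(bad, collapse = ", "),
           " do not conserve the declared total of {",
           paste(grp, collapse = ", "), "}")
  }
  invisible(net)
}

#' Load a reaction network from a structured text model file
#'
#' Reads a YAML (or JSON, a YAML subset) model document with keys
#' \code{species}, \code{reactions} (each with \code{reactants},
#' \code{products} as name->count maps, \code{rate} and optional
#' \code{omega_exponent}), optional \code{omega} and optional
#' \code{conservation} (list of species-name groups).
#'
#' @param path path to the model document.
#' @return a validated \linkS4class{ReactionNetwork}.
#' @seealso \code{\link{fixture}} for the shipped example models.
#' @export
loadNetwork <- function(path) {
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("malformed model document '", path, "': ", conditionMessage(e)))
  for (field in c("species", "reactions"))
    if (is.null(doc[[field]]))
      stop("model document missing required field '", field, "'")
  species <- as.character(doc$species)
  R <- length(doc$reactions)
  if (R < 1) stop("model document declares no reactions")
  N <- length(species)
  reactants <- products <- matrix(0L, N, R)
  rates <- numeric(R)
  wexp <- numeric(R)
  for (j in seq_len(R)) {
    rx <- doc$reactions[[j]]
    if (is.null(rx$rate))
      stop("reaction ", j, " missing required field 'rate'")
    if (rx$rate < 0)
      stop("reaction ", j, " has negative rate ", rx$rate)
    rates[j] <- rx$rate
    wexp[j] <- if (is.null(rx$omega_exponent)) 0 else rx$omega_exponent
    reactants[, j] <- .sideCounts(rx$reactants, species, j, "reactants")
    products[, j] <- .sideCounts(rx$products, species, j, "products")
  }
  omega <- if (is.null(doc$omega)) 1 else doc$omega
  conservation <- if (is.null(doc$conservation)) list() else
    lapply(doc$conservation, as.character)
  reactionNetwork(species, reactants, products, rates,
                  omegaExponents = wexp, omega = omega,
                  conservation = conservation)
}

.sideCounts <- function(side, species, j, what) {
  counts <- integer(length(species))
  if (is.null(side) || !length(side)) return(counts)  # empty side: source/sink
  idx <- match(names(side), species)
  if (anyNA(idx))
    stop("reaction ", j, " ", what, " name unknown species: ",
         paste(names(side)[is.na(idx)], collapse = ", "))
  counts[idx] <- as.integer(unlist(side))
  if (any(counts < 0))
    stop("reaction ", j, " has negative stoichiometry in ", what)
  counts
}

#' Mass-action propensities at a state
#'
#' Combinatorial mass action: reaction j with reactant stoichiometries
#' \eqn{s_{ij}} has propensity
#' \eqn{a_j(n) = c_j \Omega^{w_j} \prod_i n_i (n_i-1) \cdots (n_i-s_{ij}+1)},
#' zero whenever any reactant count is insufficient.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param state integer vector of copy numbers (one per species).
#' @return numeric vector of length \code{nReactions(net)}.
#' @examples
#' tri <- fixture("trimolecular")$network
#' propensities(tri, c(10, 5, 5))
#' @export
propensities <- function(net, state) {
  N <- length(net@speciesNames)
  if (length(state) != N)
    stop("state must have one entry per species (", N, ")")
  if (any(state < 0)) stop("negative copy numbers are not a valid state")
  a <- net@rateConstants * net@systemSize^net@omegaExponents
  for (j in seq_len(nReactions(net))) {
    for (i in seq_len(N)) {
      s <- net@reactantStoich[i, j]
      if (s > 0) {
        if (state[i] < s) { a[j] <- 0; break }
        a[j] <- a[j] * prod(state[i] - seq_len(s) + 1)
      }
    }
  }
  a
}

#' @describeIn propensities propensities for every row of a state matrix
#'   (states x species); returns a states x reactions matrix.
#' @param statesMatrix integer matrix of states (rows).
#' @export
propensityMatrix <- function(net, statesMatrix) {
  nS <- nrow(statesMatrix)
  R <- nReactions(net)
  A <- matrix(rep(net@rateConstants * net@systemSize^net@omegaExponents,
                  each = nS), nS, R)
  for (j in seq_len(R)) {
    for (i in seq_len(length(net@speciesNames))) {
      s <- net@reactantStoich[i, j]
      if (s > 0) {
        f <- statesMatrix[, i]
        fac <- f
        if (s > 1) for (k in seq_len(s - 1)) fac <- fac * (f - k)
        fac[f < s] <- 0
        A[, j] <- A[, j] * fac
      }
    }
  }
  A
}
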