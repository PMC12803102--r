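#' Enumerate the copy-number state space of a network
#'
#' Produces the deterministic (lexicographic) enumeration of states over
#' which the master-equation generator is assembled. Two modes are
#' supported: \code{"closed-conserved"} enumerates all states compatible
#' with the network's declared conservation groups (every species must
#' belong to one), and \code{"truncated-box"} enumerates the box
#' \eqn{0 \le n_i \le b_i} given per-species bounds.
#'
#' @param net a \linkS4class{ReactionNetwork}.
#' @param mode \code{"closed-conserved"} or \code{"truncated-box"}.
#' @param totals named numeric vector/list of conserved totals, one per
#'   conservation group (named by the group's first species); may be
#'   omitted when \code{init} is given.
#' @param bounds integer per-species upper bounds (truncated-box mode).
#' @param init optional initial state; used to derive \code{totals} and to
#'   validate that box bounds can hold it.
#' @return a \linkS4class{StateSpace}.
#' @examples
#' tri <- fixture("trimolecular")$network
#' space <- enumerateStates(tri, "closed-conserved", init = c(10, 5, 5))
#' nStates(space)  # (21 * 22) / 2 = 231
#' @export
enumerateStates <- function(net, mode = c("closed-conserved", "truncated-box"),
                            totals = NULL, bounds = NULL, init = NULL) {
  mode <- match.arg(mode)
  N <- length(net@speciesNames)
  if (!is.null(init) && length(init) != N)
    stop("init must have one entry per species")
  if (mode == "closed-conserved") {
    groups <- net@conservation
    if (!length(groups))
      stop("closed-conserved enumeration requires declared conservation groups")
    gidx <- lapply(groups, match, net@speciesNames)
    covered <- sort(unlist(gidx))
    if (!identical(covered, seq_len(N)))
      stop("conservation groups must cover every species exactly once")
    .checkConservation(net)  # consistency: every reaction conserves totals
    if (is.null(totals)) {
      if (is.null(init))
        stop("supply either conserved totals or an initial state")
      totals <- vapply(gidx, function(ix) sum(init[ix]), numeric(1))
    }
    totals <- as.integer(unlist(totals))
    if (length(totals) != length(groups))
      stop("need one total per conservation group")
    states <- .enumerateConserved(N, gidx, totals)
    new("StateSpace", states = states, kind = "closed-conserved",
        bounds = integer(0),
        totals = as.list(stats::setNames(
          totals, vapply(groups, `[`, character(1), 1L))),
        speciesNames = net@speciesNames)
  } else {
    if (is.null(bounds) || length(bounds) != N)
      stop("truncated-box enumeration requires one bound per species")
    bounds <- as.integer(bounds)
    if (any(bounds < 0)) stop("bounds must be nonnegative")
    if (!is.null(init) && any(init > bounds))
      stop("bound smaller than the initial copy number")
    grid <- expand.grid(rev(lapply(bounds, function(b) 0:b)),
                        KEEP.OUT.ATTRS = FALSE)
    states <- as.matrix(grid[, rev(seq_len(N)), drop = FALSE])
    dimnames(states) <- NULL
    storage.mode(states) <- "integer"
    new("StateSpace", states = states, kind = "truncated-box",
        bounds = bounds, totals = list(), speciesNames = net@speciesNames)
  }
}

## Lexicographic enumeration under per-group fixed totals. Species i ranges
## over 0..remaining(group(i)), forced to the remainder when it is the last
## member of its group.
.enumerateConserved <- function(N, gidx, totals) {
  group <- integer(N)
  for (g in seq_along(gidx)) group[gidx[[g]]] <- g
  lastOfGroup <- vapply(seq_len(N), function(i)
    i == max(which(group == group[i])), logical(1))
  out <- list()
  state <- integer(N)
  recurse <- function(i, remaining) {
    if (i > N) { out[[length(out) + 1L]] <<- state; return(invisible()) }
    g <- group[i]
    if (lastOfGroup[i]) {
      state[i] <<- remaining[g]
      rem2 <- remaining; rem2[g] <- 0L
      recurse(i + 1L, rem2)
    } else {
      for (v in 0:remaining[g]) {
        state[i] <<- v
        rem2 <- remaining; rem2[g] <- remaining[g] - v
        recurse(i + 1L, rem2)
      }
    }
  }
  recurse(1L, as.integer(totals))
  states <- do.call(rbind, out)
  storage.mode(states) <- "integer"
  states
}

.stateKeys <- function(statesMatrix) {
  apply(statesMatrix, 1L, paste, collapse = ",")
}

#' Look up state indices in an enumeration
#'
#' @param space a \linkS4class{StateSpace}.
#' @param queryStates integer matrix of states (rows) or a single state
#'   vector.
#' @return integer indices (NA where a state is not in the space).
#' @export
stateIndex <- function(space, queryStates) {
  if (is.null(dim(queryStates)))
    queryStates <- matrix(queryStates, nrow = 1)
  match(.stateKeys(queryStates), .stateKeys(space@states))
}
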