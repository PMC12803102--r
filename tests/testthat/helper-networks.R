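# Shared in-code fixtures for the test suite.

# random proper generator: uniform off-diagonals, diagonal balancing columns
randomGenerator <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  diag(M) <- 0
  diag(M) <- -colSums(M)
  M
}

# unidirectional 3-state cycle: eigenvalues 0, -3/2 +- i sqrt(3)/2 -- the
# smallest generator with a complex (2x2 Schur block) mode
cycleGenerator <- function(rate = 1) {
  M <- matrix(0, 3, 3)
  M[2, 1] <- rate; M[3, 2] <- rate; M[1, 3] <- rate
  diag(M) <- -rate
  M
}

# linear decay network A -> 0
decayNetwork <- function(k = 1) {
  reactionNetwork("A", matrix(1), matrix(0), rates = k)
}

# small random mass-action network on a closed conserved space (pairwise
# conversions keep the total fixed)
randomClosedNetwork <- function(seed) {
  set.seed(seed)
  reactionNetwork(
    c("A", "B", "C"),
    reactants = matrix(c(1, 1, 0, 0, 1, 1, 1, 0, 1), 3),
    products = matrix(c(2, 0, 0, 0, 2, 0, 0, 0, 2), 3),
    rates = stats::runif(3, 0.2, 2),
    conservation = list(c("A", "B", "C")))
}

# build a TrajectoryEnsemble from a deterministic signal generator, for
# metric tests (counts are rounded nonnegative values)
syntheticEnsemble <- function(signals, dt = 0.05) {
  nTraj <- nrow(signals); nT <- ncol(signals)
  counts <- array(0L, c(nTraj, nT, 2))
  counts[, , 1] <- pmax(0L, round(signals))
  counts[, , 2] <- 0L
  new("TrajectoryEnsemble", timeGrid = (seq_len(nT) - 1) * dt,
      counts = counts, seeds = seq_len(nTraj), baseSeed = 1L,
      speciesNames = c("A", "B"), network = fixture("two-state")$network,
      absorptionTimes = rep(Inf, nTraj))
}
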