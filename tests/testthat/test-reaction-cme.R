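test_that("model loading validates structure and stoichiometry", {
  br <- fixture("brusselator")$network
  S <- netStoich(br)
  expect_equal(unname(S[, 1]), c(1, -1))   # 2X + Y -> 3X
  expect_equal(unname(S[, 2]), c(-1, 1))   # X -> Y
  expect_equal(unname(S[, 3]), c(1, 0))    # source -> X
  expect_equal(unname(S[, 4]), c(-1, 0))   # X -> sink
  expect_equal(br@omegaExponents, c(-2, 0, 1, 0))

  tri <- fixture("trimolecular")$network
  St <- netStoich(tri)
  expect_true(all(colSums(St) == 0))
  expect_true(all(apply(St, 2, function(s) sum(s == 1) == 1 &&
                                            sum(s == -1) == 1)))

  expect_error(reactionNetwork("A", matrix(1, 1, 0), matrix(1, 1, 0),
                               rates = numeric(0)),
               "at least one reaction")
  expect_error(reactionNetwork("A", matrix(1), matrix(0), rates = -1),
               "nonnegative")
  # malformed document: unknown species in a reaction
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("species: [A]", "reactions:",
               "  - reactants: {Z: 1}", "    products: {A: 1}",
               "    rate: 1"), bad)
  expect_error(loadNetwork(bad), "unknown species")
})

test_that("propensities follow combinatorial mass action", {
  tri <- fixture("trimolecular")$network
  expect_equal(propensities(tri, c(1, 1, 0)), c(1, 0, 0))
  expect_equal(propensities(tri, c(10, 5, 5)), c(50, 25, 50))
  br <- fixture("brusselator")$network
  expect_equal(propensities(br, c(0, 5))[1], 0)  # no X pairs available
  # trimolecular jump needs two distinct reactants present
  expect_equal(propensities(br, c(1, 5))[1], 0)  # x(x-1) = 0 at x = 1
  expect_error(propensities(tri, c(-1, 2, 2)), "negative")
  # system-size scaling enters as declared per reaction
  a <- propensities(br, c(3, 4))
  omega <- br@systemSize
  expect_equal(a[1], 1 * omega^-2 * 3 * 2 * 4)
  expect_equal(a[3], 1 * omega)
})

test_that("state enumeration is complete, deterministic and validated", {
  tri <- fixture("trimolecular")$network
  expect_equal(nStates(enumerateStates(tri, "closed-conserved", totals = 2)),
               6)
  sp20 <- enumerateStates(tri, "closed-conserved", init = c(10, 5, 5))
  expect_equal(nStates(sp20), 231)  # (T+1)(T+2)/2 at T = 20
  expect_true(all(rowSums(states(sp20)) == 20))
  expect_false(anyDuplicated(apply(states(sp20), 1, paste, collapse = ",")) >
                 0)
  # lexicographic ordering is reproducible
  expect_equal(states(sp20)[1, ], c(0, 0, 20))
  expect_equal(states(sp20)[231, ], c(20, 0, 0))

  bd <- fixture("birth-death")$network
  expect_equal(nStates(enumerateStates(bd, "truncated-box", bounds = 0)), 1)
  expect_error(enumerateStates(bd, "truncated-box", bounds = 3,
                               init = 5), "bound smaller")
  # non-conserving network under closed mode is rejected
  open <- reactionNetwork(c("A", "B"), matrix(c(1, 0), 2),
                          matrix(c(0, 0), 2), rates = 1,
                          conservation = list())
  expect_error(enumerateStates(open, "closed-conserved", totals = 3),
               "conservation")
})

test_that("generator assembly matches the master equation balance", {
  ts <- fixture("two-state")
  G <- buildGenerator(ts$network,
                      enumerateStates(ts$network, "closed-conserved",
                                      totals = 1))
  expect_equal(as.matrix(rateMatrix(G)), matrix(c(-1, 1, 1, -1), 2))

  tri <- fixture("trimolecular")$network
  sp <- enumerateStates(tri, "closed-conserved", totals = 2)
  G2 <- buildGenerator(tri, sp)
  # pure single-species states are absorbing: all-zero columns
  pure <- which(rowSums(states(sp) > 0) == 1)
  M2 <- as.matrix(rateMatrix(G2))
  expect_true(all(abs(M2[, pure]) == 0))
  expect_lt(max(abs(Matrix::colSums(rateMatrix(G2)))), 1e-12)

  # generator action equals direct evaluation of the probability balance
  for (seed in 1:3) {
    net <- randomClosedNetwork(seed)
    spc <- enumerateStates(net, "closed-conserved", totals = 5)
    M <- as.matrix(rateMatrix(buildGenerator(net, spc)))
    set.seed(seed + 100)
    P <- stats::runif(nStates(spc))
    S <- netStoich(net)
    direct <- numeric(nStates(spc))
    for (r in seq_len(nStates(spc))) {
      n <- states(spc)[r, ]
      for (j in seq_len(nReactions(net))) {
        src <- n - S[, j]
        if (all(src >= 0)) {
          idx <- stateIndex(spc, src)
          if (!is.na(idx))
            direct[r] <- direct[r] + propensities(net, src)[j] * P[idx]
        }
        direct[r] <- direct[r] - propensities(net, n)[j] * P[r]
      }
    }
    expect_lt(max(abs(M %*% P - direct)), 1e-10)
  }
})

test_that("generator spectra are nonpositive with a stationary null space", {
  ss <- spectralSummary(matrix(c(-1, 1, 1, -1), 2))
  expect_equal(ss@eigenvalues, as.complex(c(0, -2)))
  expect_equal(as.numeric(ss@nullVectors), c(0.5, 0.5))

  tri <- fixture("trimolecular")$network
  G <- buildGenerator(tri, enumerateStates(tri, "closed-conserved",
                                           totals = 2))
  expect_equal(spectralSummary(G)@zeroMultiplicity, 3L)

  for (seed in 1:50) {
    n <- 2 + (seed %% 8)
    ev <- spectralSummary(randomGenerator(n, seed))@eigenvalues
    expect_lte(max(Re(ev)), 1e-10)
    nz <- ev[Mod(ev) > 1e-10]
    if (length(nz)) expect_lt(max(Re(nz)), 0)
    expect_gte(sum(Mod(ev) <= 1e-10), 1)
  }
})

test_that("absorbing-state count matches zero-eigenvalue multiplicity", {
  tri <- fixture("trimolecular")$network
  for (total in c(2, 5, 9)) {
    G <- buildGenerator(tri, enumerateStates(tri, "closed-conserved",
                                             totals = total))
    expect_equal(length(absorbingStates(G)), 3L)
    expect_equal(spectralSummary(G)@zeroMultiplicity, 3L)
  }
})

test_that("generator TSV export round-trips values and state labels", {
  ts <- fixture("two-state")
  G <- buildGenerator(ts$network,
                      enumerateStates(ts$network, "closed-conserved",
                                      totals = 1))
  path <- tempfile(fileext = ".tsv")
  exportGenerator(G, path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE)
  expect_equal(df$state, c("0,1", "1,0"))
  expect_equal(unname(as.matrix(df[, -1])), matrix(c(-1, 1, 1, -1), 2))
})
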