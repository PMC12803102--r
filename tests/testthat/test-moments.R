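test_that("moment derivatives are exact against a matrix-exponential oracle", {
  # d<n^m>/dt from the symbolic expansion must match the derivative of the
  # expm-propagated expectation on a truncated space
  bd <- fixture("birth-death")$network
  sp <- enumerateStates(bd, "truncated-box", bounds = 40)
  M <- as.matrix(rateMatrix(buildGenerator(bd, sp)))
  ms <- deriveMoments(bd, 3)
  P0 <- numeric(nStates(sp)); P0[stateIndex(sp, 2)] <- 1
  tt <- 0.4; h <- 1e-5
  P1 <- as.matrix(Matrix::expm(Matrix::Matrix(M * tt))) %*% P0
  P2 <- as.matrix(Matrix::expm(Matrix::Matrix(M * (tt + h)))) %*% P0
  n <- states(sp)[, 1]
  raws <- vapply(1:4, function(o) sum(n^o * P1), numeric(1))
  for (r in 1:3) {
    tab <- ms@rhs[[r]]
    sym <- sum(tab$coef * vapply(seq_along(tab$coef), function(t) {
      e <- tab$idx[t, 1]; if (e == 0) 1 else raws[e]
    }, numeric(1)))
    fd <- (sum(n^r * P2) - sum(n^r * P1)) / h
    expect_lt(abs(sym - fd), 1e-3 * max(1, abs(fd)))
  }
})

test_that("first-order closure reproduces the classical rate equations", {
  # linear decay: d<n>/dt = -k<n>, exact and closure-free
  dec <- decayNetwork(2)
  ms <- deriveMoments(dec, 1)
  expect_equal(ms@rhs[[1]]$coef, -2)
  expect_equal(ms@rhs[[1]]$idx[1, 1], 1L)

  # the q = 1 system has exactly N equations in the means
  br <- fixture("brusselator")$network
  cl1 <- closeSystem(deriveMoments(br, 1))
  expect_equal(nrow(cl1$indices), 2L)
  expect_equal(cl1$labels, c("m1_0", "m0_1"))

  # and equals the rate-equation vector field S a(mu) at arbitrary states
  S <- netStoich(br)
  set.seed(7)
  for (i in 1:5) {
    mu <- stats::runif(2, 2, 25)
    expect_equal(cl1$rhs(mu), as.numeric(S %*% propensities(br, mu)),
                 tolerance = 1e-12)
  }
})

test_that("central-moment neglect substitutes the Gaussian-style raw moment", {
  # at q = 2 the closed third raw moment is 3<n><n^2> - 2<n>^3
  dimer <- reactionNetwork("A", matrix(2), matrix(1), rates = 1)
  cl <- closeSystem(deriveMoments(dimer, 2))
  mu <- 4; m2 <- 19
  # exact: d<n^2>/dt = -2<n^3> + 3<n^2> - <n>
  expected <- -2 * (3 * mu * m2 - 2 * mu^3) + 3 * m2 - mu
  expect_equal(cl$rhs(c(mu, m2))[2], expected, tolerance = 1e-12)
})

test_that("closure is exact on linear networks at any order", {
  bd <- fixture("birth-death")$network
  sp <- enumerateStates(bd, "truncated-box", bounds = 60)
  M <- as.matrix(rateMatrix(buildGenerator(bd, sp)))
  tGrid <- seq(0, 2, by = 0.25)
  P0 <- numeric(nStates(sp)); P0[stateIndex(sp, 3)] <- 1
  Emat <- as.matrix(Matrix::expm(Matrix::Matrix(M * 0.25)))
  n <- states(sp)[, 1]
  for (q in c(1, 2, 3)) {
    cl <- closeSystem(deriveMoments(bd, q))
    tr <- integrateMoments(cl, deterministicInitialMoments(cl, 3), tGrid)
    P <- P0
    for (k in 2:length(tGrid)) {
      P <- Emat %*% P
      for (o in seq_len(q)) {
        oracle <- sum(n^o * P)
        expect_lt(abs(tr[k, 1 + o] - oracle), 1e-5 * max(1, oracle))
      }
    }
  }
})

test_that("linear-decay means integrate to the closed form", {
  dec <- decayNetwork(1.3)
  cl <- closeSystem(deriveMoments(dec, 1))
  tGrid <- seq(0, 3, by = 0.05)
  tr <- integrateMoments(cl, deterministicInitialMoments(cl, 10), tGrid)
  expect_lt(max(abs(tr[, 2] - 10 * exp(-1.3 * tGrid))), 1e-7)
})

test_that("rate equations sustain the oscillation the generator forbids", {
  # open system: the q = 1 Brusselator keeps a non-decaying periodic orbit
  br <- fixture("brusselator")$network
  cl1 <- closeSystem(deriveMoments(br, 1))
  tGrid <- seq(0, 120, by = 0.1)
  tr <- integrateMoments(cl1, deterministicInitialMoments(cl1, c(1, 1)),
                         tGrid, rtol = 1e-8, atol = 1e-8)
  x <- tr[, 2]
  n <- length(x)
  third <- floor(n / 3)
  ampEarly <- diff(range(x[(third + 1):(2 * third)])) / 2
  ampLate <- diff(range(x[(2 * third + 1):n])) / 2
  expect_gt(ampLate, 0.9 * ampEarly)

  # closed system: REs predict a sustained orbit while every nonzero
  # generator eigenvalue strictly decays -- the central discrepancy
  tri <- fixture("trimolecular")
  clT <- closeSystem(deriveMoments(tri$network, 1))
  tG <- seq(0, 6, by = 0.005)
  trT <- integrateMoments(clT, deterministicInitialMoments(clT, tri$init),
                          tG)
  xa <- trT[, 2]
  half <- floor(length(xa) / 2)
  expect_gt(diff(range(xa[(half + 1):length(xa)])) / 2,
            0.9 * diff(range(xa[1:half])) / 2)
  G <- buildGenerator(tri$network,
                      enumerateStates(tri$network, "closed-conserved",
                                      totals = 20))
  ev <- spectralSummary(G)@eigenvalues
  expect_lt(max(Re(ev[Mod(ev) > 1e-10])), 0)
})

test_that("closure order changes the predicted dynamics of nonlinear nets", {
  br <- fixture("brusselator")$network
  tGrid <- seq(0, 3, by = 0.1)
  cl1 <- closeSystem(deriveMoments(br, 1))
  cl5 <- closeSystem(deriveMoments(br, 5))
  tr1 <- integrateMoments(cl1, deterministicInitialMoments(cl1, c(1, 1)),
                          tGrid, rtol = 1e-6, atol = 1e-8)
  tr5 <- integrateMoments(cl5, deterministicInitialMoments(cl5, c(1, 1)),
                          tGrid, rtol = 1e-6, atol = 1e-8)
  expect_gt(max(abs(tr1[, "m1_0"] - tr5[, "m1_0"])), 0.05)
})

test_that("linearized modes report frequency and decay from the Jacobian", {
  # pure relaxation: no complex pair, decay equals the spectral gap
  ts <- fixture("two-state")$network
  clTS <- closeSystem(deriveMoments(ts, 1))
  lmTS <- linearizedMode(clTS, c(0.6, 0.4))
  expect_false(lmTS$hasComplexPair)
  expect_true(is.na(lmTS$omega))
  expect_equal(lmTS$gamma, 2, tolerance = 1e-8)

  # q = 1 Brusselator past its oscillatory onset: growing focus
  br <- fixture("brusselator")$network
  cl1 <- closeSystem(deriveMoments(br, 1))
  lm1 <- linearizedMode(cl1, c(9, 30))
  expect_true(lm1$hasComplexPair)
  expect_lt(lm1$gamma, 0)   # growth sustains the limit cycle

  # q = 2: Jacobian mode agrees with a damped-sinusoid fit of the
  # integrated moments near the fixed point (internal cross-method oracle)
  cl2 <- closeSystem(deriveMoments(br, 2))
  tr0 <- integrateMoments(cl2, deterministicInitialMoments(cl2, c(8, 30)),
                          seq(0, 25, by = 0.5), rtol = 1e-8)
  lm2 <- linearizedMode(cl2, colMeans(tr0[-(1:10), -1]))
  y0 <- lm2$fixedPoint
  y0[1] <- y0[1] * 1.02   # small kick off the fixed point
  tG <- seq(0, 40, by = 0.02)
  f <- function(t, y, parms) list(cl2$rhs(y))
  tr <- deSolve::ode(y0, tG, f, NULL, rtol = 1e-10, atol = 1e-10)
  fit <- fitDampedOscillation(tr[, 2], tG)
  expect_true(fit@converged)
  expect_lt(abs(fit@omega - lm2$omega) / lm2$omega, 0.05)
  expect_lt(abs(fit@decayRate - lm2$gamma) /
              max(abs(lm2$gamma), 0.02), 0.05)
})
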