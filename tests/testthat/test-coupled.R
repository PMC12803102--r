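test_that("decoupled systems relax to the stationary law with free input", {
  tri <- fixture("trimolecular")$network
  sp <- enumerateStates(tri, "closed-conserved", totals = 4)
  M <- as.matrix(rateMatrix(buildGenerator(tri, sp)))
  n <- nrow(M)
  sys <- coupledLinearSystem(M, matrix(0, n, 1), matrix(0, 1, n),
                             matrix(-0.5, 1, 1))
  P0 <- numeric(n); P0[stateIndex(sp, c(2, 1, 1))] <- 1
  tg <- seq(0, 12, by = 0.05)
  tr <- integrateCoupled(sys, P0, x0 = 2, tg)
  expect_lt(tr@conservationResidual, 1e-10)
  expect_lt(max(abs(tr@x - 2 * exp(-0.5 * tg))), 1e-9)
  # late-time P lies in the null space of M (absorbing mixture)
  late <- tr@P[length(tg), ]
  expect_lt(max(abs(M %*% late)), 1e-8)
})

test_that("designed systems sustain the tracked oscillation; isolated decay", {
  wf <- workflowCoherentDesign(targetOmega = 1, total = 12, nPeriods = 12)
  expect_gte(wf$ratioCoupled, 0.99)
  expect_lte(wf$ratioCoupled, 1.01)
  expect_lt(wf$ratioIsolated, 0.5)
  expect_true(wf$fitCoupled@converged)
  expect_lt(abs(wf$fitCoupled@omega - 1), 0.01)
  expect_lt(wf$conservationResidual, 1e-8)
})

test_that("the convolution solution for x matches the ODE integration", {
  # designed two-state system over a horizon where the unstable-kernel
  # amplification still leaves quadrature headroom
  sf <- orderedSchur(matrix(c(-1, 1, 1, -1), 2))
  d <- designRealMode(sf, 1L, 1)
  tg <- seq(0, 5, by = 0.0025)
  tr <- integrateCoupled(d$system, c(1, 0), 0, tg)
  x2 <- xIntegralSolution(tr@P, d$system@Cmat, d$system@B2, 0, tg)
  expect_lt(max(abs(x2 - tr@x)), 1e-6 * max(abs(tr@x)))

  # B2 = 0: x(t) = e^{tC} x0 exactly
  n <- 2
  sys0 <- coupledLinearSystem(d$system@M, matrix(0, n, 1), matrix(0, 1, n),
                              matrix(0.3, 1, 1))
  tr0 <- integrateCoupled(sys0, c(1, 0), 1, tg)
  x0p <- xIntegralSolution(tr0@P, sys0@Cmat, sys0@B2, 1, tg)
  expect_lt(max(abs(x0p - exp(0.3 * tg))), 1e-8)

  # C = 0 with a constant readout of a conserved vector: pure integrator
  sysI <- coupledLinearSystem(d$system@M, matrix(0, n, 1), matrix(1, 1, n),
                              matrix(0, 1, 1))
  trI <- integrateCoupled(sysI, c(0.5, 0.5), 0.5, tg)
  xi <- xIntegralSolution(trI@P, sysI@Cmat, sysI@B2, 0.5, tg)
  expect_lt(max(abs(xi - (0.5 + tg))), 1e-9)

  expect_error(xIntegralSolution(tr@P[1:10, ], d$system@Cmat, d$system@B2,
                                 0, tg), "lengths differ")
})

test_that("cubic saturation produces an amplitude-independent limit cycle", {
  sf <- orderedSchur(matrix(c(-1, 1, 1, -1), 2))
  d <- designRealMode(sf, 1L, 1)
  sys <- d$system
  # kappa = 0 reduces exactly to the linear propagation
  tg <- seq(0, 10, by = 0.05)
  lin <- integrateCoupled(sys, c(0.5, 0.5), 0.2, tg)
  cub0 <- integrateWithCubic(sys, c(0.5, 0.5), 0.2, kappa = 0, tg)
  expect_equal(cub0@x, lin@x, tolerance = 1e-9)

  # slightly growing design + cubic: bounded, and the late amplitude
  # forgets the initial amplitude (x10 apart) within 2%
  grow <- coupledLinearSystem(sys@M, sys@B1, sys@B2, sys@Cmat + 0.05)
  tgl <- seq(0, 300, by = 0.02)
  r1 <- integrateWithCubic(grow, c(0.5, 0.5), 0.01, kappa = 0.5, tgl)
  r2 <- integrateWithCubic(grow, c(0.5, 0.5), 0.1, kappa = 0.5, tgl)
  expect_true(all(is.finite(r1@x)))
  expect_lt(max(abs(r1@x)), 10)
  late <- tgl > 250
  a1 <- diff(range(r1@x[late, 1])) / 2
  a2 <- diff(range(r2@x[late, 1])) / 2
  expect_lt(abs(a1 - a2) / a1, 0.02)
})

test_that("integrated designed dynamics recover the designed frequency", {
  # end-to-end: design, integrate, fit -- the fitted frequency equals the
  # eigenvalue-level prediction within 1%
  tri <- fixture("trimolecular")$network
  sp <- enumerateStates(tri, "closed-conserved", totals = 10)
  sf <- orderedSchur(buildGenerator(tri, sp))
  d <- designRealMode(sf, slowestRealMode(sf)$position, 1.7)
  P0 <- numeric(nStates(sp)); P0[stateIndex(sp, c(4, 3, 3))] <- 1
  tg <- seq(0, 10 * 2 * pi / 1.7, length.out = 1201)
  tr <- integrateCoupled(d$system, P0, 0, tg)
  tracked <- which.max(abs(sf@Q[, slowestRealMode(sf)$position]))
  skip <- floor(0.2 * length(tg))
  fit <- fitDampedOscillation(tr@P[-seq_len(skip), tracked],
                              tg[-seq_len(skip)])
  expect_true(fit@converged)
  expect_lt(abs(fit@omega - d$design@predictedOmega) / 1.7, 0.01)
  expect_lt(tr@conservationResidual, 1e-9)
})
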