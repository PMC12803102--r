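test_that("the targeted 2x2 factor has the designed imaginary pair", {
  # sigma1 = -1, omega* = sqrt(2): sigma2 = 1, product = -3
  q1 <- sqrt(3); q2 <- -sqrt(3)
  ev <- eigen(matrix(c(-1, q2, q1, 1), 2), only.values = TRUE)$values
  expect_equal(sort(Im(ev)), c(-sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_lt(max(abs(Re(ev))), 1e-12)
  # omega* -> 0: the product approaches the coherence boundary sigma1*sigma2
  expect_equal(-1 * 1 - 1e-12, -1 - 1e-12)
})

test_that("real-mode designs hit the target frequency on the full system", {
  ts <- orderedSchur(matrix(c(-1, 1, 1, -1), 2))
  d <- designRealMode(ts, 1L, sqrt(2))
  expect_equal(d$design@sigma2, 2)
  expect_equal(d$design@couplingProduct, -4 - 2)
  expect_lt(abs(Re(d$design@leadingEigenvalue)), 1e-10)
  expect_equal(Im(d$design@leadingEigenvalue), sqrt(2), tolerance = 1e-9)

  tri <- fixture("trimolecular")$network
  sf <- orderedSchur(buildGenerator(tri,
          enumerateStates(tri, "closed-conserved", totals = 20)))
  mode <- slowestRealMode(sf)
  for (w in c(0.5, 1, 2)) {
    d <- designRealMode(sf, mode$position, w)
    lead <- d$design@leadingEigenvalue
    expect_lte(abs(Re(lead)), 1e-8)
    expect_lte(abs(Im(lead) - w) / w, 0.01)
    expect_lte(d$design@maxOtherRealPart, 1e-8)
    # negative-feedback necessity
    expect_lt(d$design@couplingProduct, 0)
    expect_lt(d$design@q1 * d$design@q2, 0)
    # probability conservation of the coupling
    expect_lt(max(abs(colSums(cbind(d$system@M, d$system@B1)))), 1e-12)
  }
  expect_error(designRealMode(sf, sf@S2[1], 1), "scalar")
})

test_that("single-mode coupling preserves the rest of the spectrum", {
  tri <- fixture("trimolecular")$network
  sf <- orderedSchur(buildGenerator(tri,
          enumerateStates(tri, "closed-conserved", totals = 8)))
  mode <- slowestRealMode(sf)
  d <- designRealMode(sf, mode$position, 1.3)
  evA <- d$design@achievedEigenvalues
  evM <- eigen(d$system@M, only.values = TRUE)$values
  # predicted spectrum: M's spectrum with sigma1 replaced by the pair
  drop1 <- which.min(abs(evM - mode$sigma1))
  predicted <- c(evM[-drop1], complex(real = 0, imaginary = 1.3),
                 complex(real = 0, imaginary = -1.3))
  match <- vapply(predicted, function(z) min(Mod(evA - z)), numeric(1))
  # exact in theory (block-triangular similarity); in practice limited by
  # the eigenvalue conditioning of the non-normal generator
  expect_lt(max(match), 1e-4)
})

test_that("frequency formula matches 2x2 eigenvalues over random designs", {
  set.seed(31)
  for (i in 1:2000) {
    s1 <- -stats::runif(1, 0.1, 5)
    s2 <- -s1
    prod <- s1 * s2 - stats::runif(1, 0.01, 25)   # below critical
    w <- sqrt(s1 * s2 - prod)
    q1 <- sqrt(-prod)
    ev <- eigen(matrix(c(s1, -q1, q1, s2), 2), only.values = TRUE)$values
    expect_lt(abs(max(Im(ev)) - w) / w, 1e-9)
  }
})

test_that("the reduced cubic condition is equivalent to an imaginary pair", {
  set.seed(13)
  tol <- 1e-7
  nWith <- 0; nWithout <- 0
  for (i in 1:5000) {
    if (i %% 2 == 0) {
      # constructed to satisfy the condition: (lambda + r)(lambda^2 + w2)
      r <- stats::runif(1, 0.05, 3); w2 <- stats::runif(1, 0.05, 9)
      co <- c(1, r, w2, r * w2)
    } else {
      co <- c(1, stats::runif(3, -2, 2))
    }
    roots <- polyroot(rev(co))
    pair <- any(abs(Re(roots)) < tol & abs(Im(roots)) > tol)
    cond <- hasImaginaryPair(co, relTol = 1e-9)
    expect_equal(cond, pair)
    if (pair) nWith <- nWith + 1 else nWithout <- nWithout + 1
  }
  expect_gt(nWith, 100); expect_gt(nWithout, 100)
})

test_that("complex-mode designs solve bc = ad and verify on the spectrum", {
  sf <- orderedSchur(cycleGenerator())      # block eigenvalues -3/2 +- i√3/2
  expect_equal(length(sf@S2), 1L)
  j <- sf@S2[1]
  d <- designComplexMode(sf, j, sigma2 = 2, searchRange = c(-100, 100))
  co <- d$cubic@coefficients
  expect_lt(abs(co[2] * co[3] - co[1] * co[4]),
            1e-9 * max(abs(co[2] * co[3]), 1))
  expect_gt(co[2], 0); expect_gt(co[3], 0)
  lead <- d$design@leadingEigenvalue
  expect_lte(abs(Re(lead)), 1e-8)
  expect_gt(Im(lead), 0)
  expect_lt(max(abs(colSums(cbind(d$system@M, d$system@B1)))), 1e-12)
  # predicted frequency agrees with the cubic's imaginary root
  rts <- d$cubic@roots
  wCubic <- max(Im(rts))
  expect_equal(d$design@predictedOmega, wCubic, tolerance = 1e-8)
  expect_error(designComplexMode(sf, j + 5L, 2), "2x2")
})

test_that("zero coupling leaves the spectrum unchanged plus sigma2", {
  M <- cycleGenerator()
  sf <- orderedSchur(M)
  cub <- characteristicCubic(sf@D1[sf@S2[1] + 0:1, sf@S2[1] + 0:1],
                             sigma2 = -0.7, product = 0)
  blockEv <- eigen(sf@D1[sf@S2[1] + 0:1, sf@S2[1] + 0:1],
                   only.values = TRUE)$values
  expected <- c(blockEv, -0.7 + 0i)
  match <- vapply(expected, function(z) min(Mod(cub@roots - z)), numeric(1))
  expect_lt(max(match), 1e-9)
  expect_false(hasImaginaryPair(cub))
})

test_that("positive coupling suppresses weakly rotating modes only", {
  sf <- orderedSchur(cycleGenerator(0.2))   # block -0.3 +- i 0.1732
  j <- sf@S2[1]
  strong <- suppressOscillatoryMode(sf, j, product = 50, sigma2 = -1)
  expect_true(strong$suppressed)
  weak <- suppressOscillatoryMode(sf, j, product = 1e-4, sigma2 = -1)
  expect_false(weak$suppressed)
  # moving the product toward zero moves the pair back toward the block's
  im <- vapply(c(1e-4, 1e-2, 0.05), function(p)
    max(abs(Im(suppressOscillatoryMode(sf, j, p, -1)$targetEigenvalues))),
    numeric(1))
  expect_true(all(diff(im) <= 1e-9))
})

test_that("regime classification follows trace and determinant", {
  expect_equal(classifyRegime(-1, 0.5, 0), "unstable-nonoscillatory")
  expect_equal(classifyRegime(-1, 1, -3), "coherent")
  expect_equal(classifyRegime(-1, -1, -0.1), "decaying-oscillatory")
  expect_equal(classifyRegime(-1, 0.5, -3), "decaying-oscillatory")
  expect_equal(classifyRegime(-1, 1.5, -3), "growing-oscillatory")
  expect_equal(classifyRegime(-1, -2, 1), "stable-nonoscillatory")
  expect_error(classifyRegime(0.5, 1, -3), "negative")
})

test_that("phase diagrams show four open regions and continuous frequency", {
  pd <- phaseDiagram(-1, seq(-2, 2, length.out = 61),
                     seq(-4, 4, length.out = 61))
  expect_equal(attr(pd, "nOpenRegions"), 4L)
  expect_setequal(setdiff(unique(pd$regime), "coherent"),
                  c("stable-nonoscillatory", "decaying-oscillatory",
                    "growing-oscillatory", "unstable-nonoscillatory"))
  # zero coupling: no oscillatory cells at all
  pd0 <- phaseDiagram(-1, seq(-2, 2, length.out = 41), 0)
  expect_true(all(pd0$regime %in% c("stable-nonoscillatory",
                                    "unstable-nonoscillatory")))
  # frequency is continuous inside each oscillatory region
  osc <- pd[!is.na(pd$omega), ]
  for (s2 in unique(osc$sigma2)[c(3, 20)]) {
    row <- osc[osc$sigma2 == s2, ]
    row <- row[order(row$product), ]
    if (nrow(row) > 3)
      expect_lt(max(abs(diff(row$omega))), 0.5)
  }
})

test_that("frequency scales as the square root of the coupling offset", {
  sc <- scalingExponent(-1, 10^seq(-4, -1, by = 0.5))
  expect_equal(sc$slope, 0.5, tolerance = 1e-6)
  expect_lt(sc$residual, 1e-10)
  for (s1 in c(-0.5, -2)) {
    expect_equal(scalingExponent(s1, 10^seq(-3, -1, by = 0.5))$slope, 0.5,
                 tolerance = 1e-6)
  }
  expect_error(scalingExponent(-1, rep(0.1, 5)), "insufficient")
})

test_that("designs serialize and reload into the same coupled system", {
  sf <- orderedSchur(matrix(c(-1, 1, 1, -1), 2))
  d <- designRealMode(sf, 1L, 1)
  path <- tempfile(fileext = ".json")
  writeDesign(d$design, path)
  back <- readDesign(path)
  expect_equal(back$system@A, d$system@A, tolerance = 1e-12)
  expect_equal(back$predictedOmega, 1)
})
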