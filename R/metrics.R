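#' Normalized autocorrelation of oscillatory signals
#'
#' Mean-subtracted, variance-normalized autocorrelation with the biased
#' (1/L) estimator, which is bounded in [-1, 1] by construction and equals
#' exactly 1 at lag zero. Two modes: \code{"per-trajectory"} computes the
#' ACF of each row of a signal matrix and averages the curves;
#' \code{"ensemble"} computes the ACF of a single (for example
#' ensemble-mean) signal.
#'
#' @param signal numeric vector, or matrix with one trajectory per row
#'   (per-trajectory mode), uniformly sampled.
#' @param maxLag maximum lag in samples (must be < series length).
#' @param mode \code{"ensemble"} or \code{"per-trajectory"}.
#' @param dt sample spacing used to express lags in time units (default 1).
#' @return an \linkS4class{AutocorrelationCurve}.
#' @examples
#' t <- seq(0, 40, by = 0.05)
#' ac <- autocorrelation(cos(1.5 * t), maxLag = 400, dt = 0.05)
#' ac@values[1]  # 1 at lag zero
#' @export
autocorrelation <- function(signal, maxLag,
                            mode = c("ensemble", "per-trajectory"), dt = 1) {
  mode <- match.arg(mode)
  if (mode == "ensemble") {
    sig <- as.numeric(signal)
    if (maxLag >= length(sig)) stop("maxLag must be below the series length")
    if (stats::var(sig) == 0)
      stop("degenerate signal: zero variance, autocorrelation undefined")
    vals <- as.numeric(stats::acf(sig, lag.max = maxLag, plot = FALSE,
                                  demean = TRUE)$acf)
  } else {
    if (is.null(dim(signal))) signal <- matrix(signal, nrow = 1)
    if (maxLag >= ncol(signal)) stop("maxLag must be below the series length")
    ok <- apply(signal, 1L, stats::var) > 0
    if (!any(ok))
      stop("degenerate signal: zero variance in every trajectory")
    curves <- apply(signal[ok, , drop = FALSE], 1L, function(s)
      as.numeric(stats::acf(s, lag.max = maxLag, plot = FALSE,
                            demean = TRUE)$acf))
    vals <- rowMeans(curves)
    vals <- vals / vals[1]   # exact renormalization at lag 0
  }
  new("AutocorrelationCurve", lags = (0:maxLag) * dt, values = vals,
      mode = mode, meta = list(nSignals = if (is.null(dim(signal))) 1L
                               else nrow(signal)))
}

#' Fit a damped sinusoid to a series
#'
#' Nonlinear least squares of \eqn{A_0 e^{-\gamma t} \cos(\omega t + \phi)
#' + c}. The frequency is initialized from the dominant nonzero peak of the
#' discrete Fourier spectrum and the decay rate from the slope of the
#' log-envelope (local extrema of the detrended series). Growth (negative
#' gamma) is returned as fitted, never clamped. Non-convergence is flagged
#' on the result, never thrown.
#'
#' @param series numeric signal values (length >= 8, finite).
#' @param tGrid matching time points (uniform).
#' @return an \linkS4class{OscillationFit}.
#' @examples
#' t <- seq(0, 25, by = 0.02)
#' y <- 2 * exp(-0.3 * t) * cos(1.7 * t + 0.4) + 5
#' fitDampedOscillation(y, t)
#' @export
fitDampedOscillation <- function(series, tGrid) {
  series <- as.numeric(series)
  if (length(series) < 8) stop("need at least 8 samples to fit")
  if (any(!is.finite(series))) stop("series contains non-finite values")
  # fit in time shifted to start at zero (a far-from-zero origin makes the
  # amplitude/decay and phase/frequency gradient columns collinear), then
  # map amplitude and phase back to the caller's time origin
  t0 <- tGrid[1]
  tGrid <- tGrid - t0
  dt <- tGrid[2] - tGrid[1]
  off0 <- mean(series)
  y <- series - off0
  # initial omega: dominant nonzero discrete-spectrum peak, refined by
  # quadratic interpolation of the log-magnitude around the peak bin
  sp <- Mod(stats::fft(y))[seq_len(floor(length(y) / 2))]
  sp[1] <- 0
  kPeak <- which.max(sp)
  delta <- 0
  if (kPeak > 1 && kPeak < length(sp) && all(sp[kPeak + c(-1, 1)] > 0)) {
    la <- log(sp[kPeak - 1]); lb <- log(sp[kPeak]); lc <- log(sp[kPeak + 1])
    den <- la - 2 * lb + lc
    if (is.finite(den) && abs(den) > 1e-12) {
      delta <- 0.5 * (la - lc) / den
      if (!is.finite(delta) || abs(delta) > 0.5) delta <- 0
    }
  }
  binw <- 2 * pi / (length(y) * dt)
  w0 <- (kPeak - 1 + delta) * binw
  if (w0 <= 0) w0 <- 2 * pi / (diff(range(tGrid)))
  # candidate frequencies around the peak; spectral leakage makes any single
  # estimate unreliable at this resolution
  wCands <- unique(pmax(c(w0, (kPeak - 1) * binw, (kPeak - 2) * binw,
                          kPeak * binw), binw / 4))
  # initial gamma: log-envelope slope through local |y| maxima
  ay <- abs(y)
  pk <- which(diff(sign(diff(ay))) < 0) + 1L
  pk <- pk[ay[pk] > 1e-12 * max(ay)]
  g0 <- 0
  if (length(pk) >= 3) {
    fitEnv <- stats::lm(log(ay[pk]) ~ tGrid[pk])
    g0 <- -unname(stats::coef(fitEnv)[2])
    # a tiny nonzero start defeats the optimizer's parameter scaling
    if (!is.finite(g0) || abs(g0) < 1e-8) g0 <- 0
  }
  A0 <- max(ay)
  fitOnce <- function(start) {
    tryCatch(
      minpack.lm::nlsLM(
        series ~ A * exp(-g * tGrid) * cos(w * tGrid + phi) + c0,
        start = start,
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)),
      error = function(e) NULL)
  }
  best <- NULL
  for (wc in wCands) {
    for (phi0 in c(0, pi / 2, pi, -pi / 2)) {
      fit <- fitOnce(list(A = A0, g = g0, w = wc, phi = phi0, c0 = off0))
      if (!is.null(fit)) {
        if (is.null(best) ||
            sum(stats::resid(fit)^2) < sum(stats::resid(best)^2))
          best <- fit
      }
    }
  }
  if (is.null(best))
    return(new("OscillationFit", amplitude = A0, decayRate = g0, omega = w0,
               phase = 0, offset = off0, residualNorm = sqrt(sum(y^2)),
               converged = FALSE))
  p <- stats::coef(best)
  A <- unname(p["A"]); phi <- unname(p["phi"]); w <- unname(p["w"])
  g <- unname(p["g"])
  if (A < 0) { A <- -A; phi <- phi + pi }  # canonical A >= 0
  if (w < 0) { w <- -w; phi <- -phi }      # canonical omega >= 0
  # undo the time shift: A e^{-g(t - t0)} cos(w (t - t0) + phi)
  A <- A * exp(g * t0)
  phi <- phi - w * t0
  phi <- atan2(sin(phi), cos(phi))
  new("OscillationFit", amplitude = A, decayRate = unname(p["g"]),
      omega = w, phase = phi, offset = unname(p["c0"]),
      residualNorm = sqrt(sum(stats::resid(best)^2)), converged = TRUE)
}

#' Evaluate an oscillation fit on a time grid
#'
#' @param fit an \linkS4class{OscillationFit}.
#' @param tGrid time points.
#' @return fitted values.
#' @export
evaluateFit <- function(fit, tGrid) {
  fit@amplitude * exp(-fit@decayRate * tGrid) *
    cos(fit@omega * tGrid + fit@phase) + fit@offset
}

## amplitude of a window: half the peak-to-peak range
.windowAmplitude <- function(y) (max(y) - min(y)) / 2

#' Per-trajectory sustained-amplitude ratio
#'
#' For each trajectory, compares the oscillation amplitude (half
#' peak-to-peak range) of a late window against an early window, after
#' skipping an initial transient. A ratio near 1 indicates individually
#' sustained oscillation (dephasing regime: open-system oscillators); a
#' ratio near 0 indicates individual trajectories losing oscillation
#' (absorbing closed systems).
#'
#' @param signals matrix (trajectory x time) of a tracked species.
#' @param transientFrac fraction of the horizon discarded as transient.
#' @param windowFrac length of each comparison window as a fraction of the
#'   post-transient horizon.
#' @return numeric vector of per-trajectory late/early amplitude ratios.
#' @export
amplitudeRatios <- function(signals, transientFrac = 0.2,
                            windowFrac = 0.25) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  L <- ncol(signals)
  i0 <- floor(transientFrac * L) + 1L
  span <- L - i0 + 1L
  w <- max(4L, floor(windowFrac * span))
  early <- i0:(i0 + w - 1L)
  late <- (L - w + 1L):L
  apply(signals, 1L, function(s) {
    a0 <- .windowAmplitude(s[early])
    a1 <- .windowAmplitude(s[late])
    # flat in both windows: the trajectory shows no oscillation at all
    # (e.g. absorbed before the early window) -> no defined ratio
    if (a0 == 0) return(if (a1 == 0) NA_real_ else Inf)
    a1 / a0
  })
}

#' Coherence report for a trajectory ensemble
#'
#' Bundles the three diagnostics used to tell dephasing apart from loss of
#' individual oscillation: a damped-sinusoid fit of the ensemble mean
#' (ensemble-level frequency and decay), the averaged per-trajectory
#' autocorrelation, and per-trajectory sustained-amplitude statistics.
#' For closed systems the per-trajectory ACF is computed on each
#' trajectory's pre-absorption segment (post-absorption constants are
#' degenerate).
#'
#' @param ens a \linkS4class{TrajectoryEnsemble} with >= 10 trajectories.
#' @param species species name or index to analyse.
#' @param maxLag maximum ACF lag in samples (default: a third of the grid).
#' @return a list with \code{fit} (\linkS4class{OscillationFit} of the
#'   ensemble mean), \code{omega}, \code{gamma}, \code{acfPerTrajectory},
#'   \code{acfEnsembleMean}, \code{amplitudeRatios} and
#'   \code{meanAmplitudeRatio}.
#' @export
coherenceReport <- function(ens, species = 1, maxLag = NULL) {
  if (nTrajectories(ens) < 10)
    stop("coherence report needs at least 10 trajectories")
  if (is.character(species)) species <- match(species, ens@speciesNames)
  dt <- ens@timeGrid[2] - ens@timeGrid[1]
  sig <- ens@counts[, , species]
  if (is.null(maxLag)) maxLag <- floor(length(ens@timeGrid) / 3)
  meanSig <- colMeans(sig)
  fit <- fitDampedOscillation(meanSig, ens@timeGrid)
  # pre-absorption segments for the per-trajectory estimator
  segs <- lapply(seq_len(nrow(sig)), function(k) {
    tAbs <- ens@absorptionTimes[k]
    keep <- ens@timeGrid <= tAbs
    sig[k, keep]
  })
  lens <- vapply(segs, length, integer(1))
  usable <- which(lens > maxLag &
                  vapply(segs, function(s) stats::var(s) > 0, logical(1)))
  acfPT <- if (length(usable)) {
    curves <- vapply(usable, function(k)
      as.numeric(stats::acf(segs[[k]], lag.max = maxLag, plot = FALSE,
                            demean = TRUE)$acf), numeric(maxLag + 1))
    v <- rowMeans(curves)
    new("AutocorrelationCurve", lags = (0:maxLag) * dt, values = v / v[1],
        mode = "per-trajectory", meta = list(nSignals = length(usable)))
  } else NULL
  acfEns <- autocorrelation(meanSig, maxLag, mode = "ensemble", dt = dt)
  ratios <- amplitudeRatios(sig)
  list(fit = fit, omega = fit@omega, gamma = fit@decayRate,
       acfPerTrajectory = acfPT, acfEnsembleMean = acfEns,
       amplitudeRatios = ratios,
       nFlatTrajectories = sum(is.na(ratios)),
       meanAmplitudeRatio = mean(ratios[is.finite(ratios)]))
}
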