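## Bunch-wise maximum-likelihood donor lifetime estimation.
##
## The decay model is a mono-exponential convolved with a Gaussian IRF --
## the exponentially modified Gaussian (EMG) -- truncated and renormalized on
## the TCSPC window, mixed with a uniform background term whose fraction is
## measured separately and held fixed during fitting.

## log EMG density: exponential (rate 1/tau) convolved with N(m, s^2).
## Stable form via pnorm(log.p = TRUE); s = 0 reduces to a shifted
## exponential.
logEmgDensity <- function(t, tau, m, s) {
  if (s <= 0) {
    out <- ifelse(t >= m, -(t - m) / tau - log(tau), -Inf)
    return(out)
  }
  s2t <- s^2 / tau
  -log(tau) + s2t^2 / (2 * s^2) - (t - m) / tau +
    stats::pnorm((t - m - s2t) / s, log.p = TRUE)
}

## EMG cumulative distribution function.
emgCdf <- function(t, tau, m, s) {
  if (s <= 0) {
    out <- ifelse(t >= m, 1 - exp(-(t - m) / tau), 0)
    return(out)
  }
  s2t <- s^2 / tau
  stats::pnorm((t - m) / s) -
    exp(s2t^2 / (2 * s^2) - (t - m) / tau +
          stats::pnorm((t - m - s2t) / s, log.p = TRUE))
}

#' Nanotime model density
#'
#' Probability density of a donor nanotime under the fitted model: the
#' Gaussian-IRF-convolved mono-exponential truncated to `[0, window]`, mixed
#' with a uniform background fraction.
#'
#' @param t nanotimes, ns.
#' @param tau lifetime, ns.
#' @param tcspc a [TcspcSpec-class] (window, IRF mean/sigma).
#' @param backgroundFraction uniform-background mixture weight in `[0, 1)`.
#' @return Density values.
#' @export
decayDensity <- function(t, tau, tcspc, backgroundFraction = 0) {
  W <- tcspc@window
  Z <- emgCdf(W, tau, tcspc@irfMean, tcspc@irfSigma) -
    emgCdf(0, tau, tcspc@irfMean, tcspc@irfSigma)
  sig <- exp(logEmgDensity(t, tau, tcspc@irfMean, tcspc@irfSigma)) / Z
  out <- (1 - backgroundFraction) * sig + backgroundFraction / W
  out[t < 0 | t > W] <- 0
  out
}

decayLogLik <- function(tau, nanotimes, tcspc, backgroundFraction) {
  sum(log(decayDensity(nanotimes, tau, tcspc, backgroundFraction)))
}

#' Split FRET-level nanotimes into consecutive 1000-photon bunches
#'
#' @param nanotimes donor nanotimes in temporal (macrotime) order, already
#'   restricted to FRET levels.
#' @param bunchSize photons per bunch (default 1000).
#' @return List of numeric vectors, each of length `bunchSize`, consecutive
#'   and non-overlapping; the trailing remainder is discarded.
#' @export
bunchPhotons <- function(nanotimes, bunchSize = 1000L) {
  nBunch <- length(nanotimes) %/% bunchSize
  if (nBunch == 0) return(list())
  lapply(seq_len(nBunch), function(i)
    nanotimes[((i - 1L) * bunchSize + 1L):(i * bunchSize)])
}

#' Maximum-likelihood mono-exponential decay fit of one photon bunch
#'
#' Maximizes the per-photon log-likelihood of the truncated EMG + uniform
#' background density over the lifetime, with the background fraction fixed
#' (it is measured separately on a blank). The optimization is a
#' deterministic golden-section search over a fixed bracket.
#'
#' @param nanotimes photon delays, ns.
#' @param tcspc a [TcspcSpec-class].
#' @param backgroundFraction fixed uniform-background fraction.
#' @param bracket lifetime search interval, ns.
#' @return List (`DecayFit`): `lifetime` (ns), `logLik`,
#'   `backgroundFraction`, `amplitudeFraction` (= 1 - background),
#'   `converged` (FALSE when the optimum sits at the bracket edge), `n`.
#' @export
fitDecayMLE <- function(nanotimes, tcspc, backgroundFraction = 0,
                        bracket = c(0.02, 2 * tcspc@window)) {
  stopifnot2(length(nanotimes) > 0, "empty photon bunch")
  opt <- stats::optimize(decayLogLik, interval = bracket,
                         nanotimes = nanotimes, tcspc = tcspc,
                         backgroundFraction = backgroundFraction,
                         maximum = TRUE, tol = 1e-6)
  edge <- opt$maximum < bracket[1] * 1.01 || opt$maximum > bracket[2] * 0.99
  list(lifetime = opt$maximum, logLik = opt$objective,
       backgroundFraction = backgroundFraction,
       amplitudeFraction = 1 - backgroundFraction,
       converged = !edge && is.finite(opt$objective),
       n = length(nanotimes))
}

#' Fit all bunches of a set of molecules
#'
#' @param nanotimesByMolecule named list of FRET-level nanotime vectors.
#' @param tcspc a [TcspcSpec-class].
#' @param backgroundFraction fixed background fraction for every fit.
#' @param bunchSize photons per bunch.
#' @return data.frame: `molecule_id`, `bunch_index`, `lifetime_ns`,
#'   `loglik`, `converged`.
#' @export
fitBunchLifetimes <- function(nanotimesByMolecule, tcspc,
                              backgroundFraction = 0, bunchSize = 1000L) {
  rows <- lapply(names(nanotimesByMolecule), function(id) {
    bunches <- bunchPhotons(nanotimesByMolecule[[id]], bunchSize)
    if (!length(bunches)) return(NULL)
    fits <- lapply(bunches, fitDecayMLE, tcspc = tcspc,
                   backgroundFraction = backgroundFraction)
    data.frame(molecule_id = id, bunch_index = seq_along(fits),
               lifetime_ns = vapply(fits, `[[`, numeric(1), "lifetime"),
               loglik = vapply(fits, `[[`, numeric(1), "logLik"),
               converged = vapply(fits, `[[`, logical(1), "converged"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(molecule_id = character(), bunch_index = integer(),
                      lifetime_ns = numeric(), loglik = numeric(),
                      converged = logical())
  out
}

#' Square-root-rule lifetime histogram
#'
#' Equal-width bins spanning the observed lifetime range, with the number of
#' bins set to the rounded square root of the number of bunches.
#'
#' @param lifetimes converged per-bunch lifetime estimates, ns.
#' @param condition condition label.
#' @return A [LifetimeHistogram-class].
#' @export
buildLifetimeHistogram <- function(lifetimes, condition = "condition") {
  stopifnot2(length(lifetimes) >= 1, "no converged fits to histogram")
  n <- length(lifetimes)
  nbins <- max(1L, as.integer(round(sqrt(n))))
  rng <- range(lifetimes)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5) * max(1e-6, abs(rng[1]) * 1e-6)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(pmin(findInterval(lifetimes, edges,
                                       rightmost.closed = TRUE), nbins), nbins)
  new("LifetimeHistogram", binEdges = edges, counts = as.integer(counts),
      nBunches = as.integer(n), condition = condition)
}
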