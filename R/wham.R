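## Weighted Histogram Analysis Method: self-consistent reweighting of
## umbrella-biased collective-variable series to recover the unbiased free
## energy profile and unbiased averages of per-sample observables.

#' WHAM reweighting of umbrella windows
#'
#' Iterates the standard WHAM equations in kT units until the window free
#' energies change by less than `tol`:
#' `P(b) = sum_s n_sb / sum_s N_s exp(f_s - B_s(x_b))` and
#' `exp(-f_s) = sum_b P(b) exp(-B_s(x_b))`, with `B_s` the harmonic bias of
#' window `s` evaluated at bin centres. The free-energy profile
#' `-kT log P` is shifted so its minimum is zero. Per-sample weights
#' `w_i = 1 / sum_s N_s exp(f_s - B_s(x_i))` (normalized) reweight any
#' per-sample observable to its unbiased mean.
#'
#' @param windows list of [UmbrellaWindow-class] objects.
#' @param bins number of histogram bins over the pooled CV range, or a
#'   vector of break points.
#' @param kT thermal energy for reporting the profile (biases are already in
#'   kT units).
#' @param tol convergence tolerance on the window free energies (kT).
#' @param maxIter iteration cap; non-convergence is an error.
#' @param observable optional function of CV value (or numeric vector, one
#'   value per pooled sample, window order) to reweight.
#' @return List: `pmf` (data.frame `x`, `pmf`), `probability` (per bin),
#'   `f` (window free energies, kT), `weights` (per pooled sample),
#'   `observableMean` (or `NA`), `iterations`.
#' @export
whamReweight <- function(windows, bins = 50L, kT = 1, tol = 1e-8,
                         maxIter = 100000L, observable = NULL) {
  stopifnot2(length(windows) >= 1, "need at least one window")
  lapply(windows, function(w)
    stopifnot2(is(w, "UmbrellaWindow"), "windows must be UmbrellaWindow objects"))
  S <- length(windows)
  x <- unlist(lapply(windows, cvSeries))
  Ns <- vapply(windows, function(w) length(w@cv), numeric(1))
  if (length(bins) == 1L) {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  } else breaks <- sort(bins)
  nb <- length(breaks) - 1L
  centres <- (breaks[-1L] + breaks[-(nb + 1L)]) / 2

  binOf <- pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), nb)
  winOf <- rep(seq_len(S), Ns)
  counts <- matrix(0, S, nb)
  for (s in seq_len(S)) {
    tab <- tabulate(binOf[winOf == s], nb)
    counts[s, ] <- tab
  }
  nTot <- colSums(counts)

  ## overlap check: windows must be connected through shared occupied bins
  if (S > 1) {
    adj <- (counts > 0) %*% t(counts > 0) > 0
    reached <- logical(S); reached[1] <- TRUE
    repeat {
      newly <- which(!reached & colSums(adj[reached, , drop = FALSE]) > 0)
      if (!length(newly)) break
      reached[newly] <- TRUE
    }
    if (!all(reached))
      stop("umbrella windows do not overlap (histograms share no occupied ",
           "bins); add intermediate windows")
  }

  ## bias energy of each window at each bin centre, kT
  bias <- matrix(0, S, nb)
  for (s in seq_len(S))
    bias[s, ] <- windows[[s]]@springK / 2 * (centres - windows[[s]]@center)^2

  f <- numeric(S)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ## denominator per bin: sum_s N_s exp(f_s - bias_sb)
    denom <- colSums(Ns * exp(f - bias))   # f recycles down rows (length S)
    P <- ifelse(denom > 0, nTot / denom, 0)
    fNew <- -log(as.numeric(exp(-bias) %*% P))
    fNew <- fNew - fNew[1]
    if (max(abs(fNew - f)) < tol) { f <- fNew; break }
    f <- fNew
    if (iter >= maxIter)
      stop("WHAM failed to converge within ", maxIter, " iterations")
  }
  denom <- colSums(Ns * exp(f - bias))
  P <- ifelse(denom > 0, nTot / denom, 0)
  Psum <- sum(P)
  P <- P / Psum

  pmf <- -kT * log(ifelse(P > 0, P, NA))
  pmf <- pmf - min(pmf, na.rm = TRUE)

  ## per-sample unbiased weights
  biasAt <- vapply(seq_len(S), function(s)
    windows[[s]]@springK / 2 * (x - windows[[s]]@center)^2, numeric(length(x)))
  biasAt <- matrix(biasAt, ncol = S)
  wDen <- as.numeric(exp(sweep(-biasAt, 2, -f, "+")) %*% Ns)
  wts <- 1 / wDen
  wts <- wts / sum(wts)

  obsMean <- NA_real_
  if (!is.null(observable)) {
    ov <- if (is.function(observable)) observable(x) else as.numeric(observable)
    stopifnot2(length(ov) == length(x),
               "observable must give one value per pooled sample")
    obsMean <- sum(wts * ov)
  }
  list(pmf = data.frame(x = centres, pmf = pmf), probability = P, f = f,
       weights = wts, observableMean = obsMean, iterations = iter)
}
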