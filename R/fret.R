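## Conversion of donor lifetimes to FRET efficiencies and donor-acceptor
## distances, per-condition median distances with bootstrap CIs, and
## beyond-range flagging.

#' Donor-only reference lifetime
#'
#' Median of per-bunch lifetimes measured on a separately characterized
#' donor-only construct.
#'
#' @param donorOnlyLifetimes per-bunch lifetimes, ns.
#' @return tau_D in ns.
#' @export
estimateDonorReference <- function(donorOnlyLifetimes) {
  stopifnot2(length(donorOnlyLifetimes) >= 1, "no donor-only lifetimes")
  stats::median(donorOnlyLifetimes)
}

#' FRET efficiency from donor lifetimes
#'
#' `E = 1 - tauDA / tauD`, the fractional reduction of the donor lifetime in
#' the presence of the acceptor. Values outside `[0, 1]` are clipped, with
#' the unclipped values kept in the `"raw"` attribute.
#'
#' @param tauDA donor lifetime with acceptor present, ns (`>= 0`).
#' @param tauD donor-only reference lifetime, ns (`> 0`).
#' @return Efficiencies in `[0, 1]` with attribute `raw`.
#' @export
efficiencyFromLifetimes <- function(tauDA, tauD) {
  stopifnot2(tauD > 0, "tauD must be > 0")
  stopifnot2(all(tauDA >= 0), "tauDA must be >= 0")
  raw <- 1 - tauDA / tauD
  structure(pmin(pmax(raw, 0), 1), raw = raw)
}

#' Donor-acceptor distance from a donor lifetime
#'
#' `r = r0 * ((1 - E) / E)^(1/6)` with `E = 1 - tauDA / tauD`; at `E = 0.5`
#' the distance equals the Förster distance exactly. Lifetimes at or above
#' the donor-only reference give `E <= 0`, where the relation diverges: the
#' distance is reported as `Inf` (beyond the FRET range).
#'
#' @param tauDA donor lifetime(s) with acceptor present, ns.
#' @param params a [FretParams-class] (Förster distance and reference
#'   lifetime).
#' @return Distances in nm; `Inf` where `E <= 0`, `0` where `E = 1`.
#' @export
distanceFromLifetime <- function(tauDA, params) {
  E <- attr(efficiencyFromLifetimes(tauDA, params@tauD), "raw")
  r <- ifelse(E <= 0, Inf,
              ifelse(E >= 1, 0, params@r0 * ((1 - E) / E)^(1 / 6)))
  as.numeric(r)
}

#' Solve the donor-only reference from one lifetime/distance anchor
#'
#' Finds the reference lifetime tau_D at which a given donor lifetime maps
#' to a given distance under [distanceFromLifetime()], by root finding on
#' the conversion itself.
#'
#' @param tauDA anchoring donor lifetime, ns.
#' @param r anchoring distance, nm.
#' @param r0 Förster distance, nm.
#' @return tau_D in ns.
#' @export
solveDonorReference <- function(tauDA, r, r0) {
  stopifnot2(tauDA > 0 && r > 0 && r0 > 0, "all anchors must be > 0")
  f <- function(tauD) distanceFromLifetime(tauDA, FretParams(r0, tauD)) - r
  stats::uniroot(f, lower = tauDA * (1 + 1e-9), upper = tauDA * 1e3,
                 tol = 1e-12)$root
}

#' Median distance with percentile-bootstrap 95% CI
#'
#' Converts per-bunch lifetimes to distances, reports their median, and a
#' seeded percentile bootstrap CI over the lifetimes.
#'
#' @param lifetimes per-bunch donor lifetimes, ns (at least 10).
#' @param params a [FretParams-class].
#' @param nBoot bootstrap resamples.
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @param thresholdRatio beyond-range threshold passed to
#'   [flagBeyondRange()].
#' @return List (`DistanceEstimate`): `median`, `ciLow`, `ciHigh` (nm), `n`,
#'   `beyondRange`.
#' @export
medianDistanceCI <- function(lifetimes, params, nBoot = 10000L, level = 0.95,
                             seed = 1L, thresholdRatio = 1.5) {
  stopifnot2(length(lifetimes) >= 10, "need at least 10 lifetimes")
  d <- distanceFromLifetime(lifetimes, params)
  med <- stats::median(d)
  qs <- withLocalSeed(seed, {
    n <- length(d)
    boots <- vapply(seq_len(nBoot), function(i)
      stats::median(d[sample.int(n, n, replace = TRUE)]), numeric(1))
    stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE, type = 7)
  })
  list(median = med, ciLow = qs[1], ciHigh = qs[2], n = length(d),
       beyondRange = flagBeyondRange(med, params, thresholdRatio))
}

#' Flag distances beyond the reliable FRET range
#'
#' A distance is flagged when it exceeds `thresholdRatio * r0` (transfer too
#' weak to resolve) or when the efficiency fell at or below the floor
#' (lifetime at or above the donor-only reference, distance unbounded).
#'
#' @param r distance in nm (may be `Inf`).
#' @param params a [FretParams-class].
#' @param thresholdRatio multiple of the Förster distance beyond which the
#'   conversion is no longer trusted; per-dye-pair configurable.
#' @return Logical flag.
#' @export
flagBeyondRange <- function(r, params, thresholdRatio = 1.5) {
  !is.finite(r) | r > thresholdRatio * params@r0
}

#' Table of per-condition median distances
#'
#' @param lifetimeSets named list of per-condition lifetime vectors.
#' @param params a [FretParams-class].
#' @param ... passed to [medianDistanceCI()].
#' @return data.frame: condition, median_nm, ci_low_nm, ci_high_nm, n,
#'   beyond_range.
#' @export
distanceTable <- function(lifetimeSets, params, ...) {
  rows <- lapply(names(lifetimeSets), function(cond) {
    est <- medianDistanceCI(lifetimeSets[[cond]], params, ...)
    data.frame(condition = cond, median_nm = est$median,
               ci_low_nm = est$ciLow, ci_high_nm = est$ciHigh, n = est$n,
               beyond_range = est$beyondRange)
  })
  do.call(rbind, rows)
}
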