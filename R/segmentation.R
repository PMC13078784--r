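## Intensity-trace binning, Poisson change-point segmentation and
## single-step photobleaching trace selection.

#' Bin a photon stream into a two-channel intensity trace
#'
#' Counts photons with macrotime in `[i w, (i+1) w)` per channel; the trailing
#' partial bin is dropped.
#'
#' @param stream a [PhotonStream-class].
#' @param binWidth bin width in seconds (default 0.1 s).
#' @return A [BinnedTrace-class]; an empty stream gives a zero-length trace.
#' @export
binPhotons <- function(stream, binWidth = 0.1) {
  stopifnot2(binWidth > 0, "binWidth must be > 0")
  span <- if (length(stream) > 0) max(stream@duration, max(stream@macrotime))
          else stream@duration
  nbins <- floor(span / binWidth + 1e-9)
  if (nbins < 1)
    return(new("BinnedTrace", binWidth = binWidth, countsDonor = integer(),
               countsAcceptor = integer(), startTime = 0))
  idx <- floor(stream@macrotime / binWidth) + 1L
  keep <- idx <= nbins
  donor <- tabulate(idx[keep & stream@channel == "donor"], nbins)
  acceptor <- tabulate(idx[keep & stream@channel == "acceptor"], nbins)
  new("BinnedTrace", binWidth = binWidth, countsDonor = as.integer(donor),
      countsAcceptor = as.integer(acceptor), startTime = 0)
}

## Maximum generalized likelihood-ratio statistic over all binary splits of a
## Poisson count vector; returns the split index (bins before the boundary)
## and the statistic. Ties break toward the earlier index.
maxSplitStat <- function(counts) {
  n <- length(counts)
  S <- sum(counts)
  cs <- cumsum(counts)[-n]
  j <- seq_len(n - 1L)
  stat <- 2 * (xlogy(cs, cs / j) + xlogy(S - cs, (S - cs) / (n - j)) -
                 xlogy(S, S / n))
  best <- which.max(stat)
  list(index = best, stat = stat[best])
}

## Monte-Carlo p-value for the max-GLR statistic under a constant-rate
## Poisson null with the segment's MLE rate, with the +1 correction.
splitPValue <- function(observed, n, lambda, nSim) {
  sims <- matrix(stats::rpois(nSim * n, lambda), nrow = nSim)
  simStat <- apply(sims, 1, function(x) maxSplitStat(x)$stat)
  (1 + sum(simStat >= observed)) / (nSim + 1)
}

#' Poisson change-point segmentation of a count trace
#'
#' Recursive binary segmentation: at each step the split maximizing the
#' generalized likelihood-ratio statistic is accepted if its Monte-Carlo
#' calibrated p-value (simulated under the segment's fitted constant-rate
#' null) is below `alpha`. Deterministic given `(counts, alpha, seed)`.
#'
#' @param counts nonnegative integer vector, length `>= 2`.
#' @param alpha significance level in (0, 1).
#' @param nSim Monte-Carlo null replicates per tested split.
#' @param seed calibration seed (fixed default keeps results deterministic).
#' @param minLength smallest segment length considered for further splitting.
#' @return data.frame with columns `start`, `end` (inclusive 1-based bin
#'   range) and `rate` (segment mean counts per bin, the Poisson MLE);
#'   segments are contiguous and ordered.
#' @export
detectChangepoints <- function(counts, alpha = 0.01, nSim = 199L,
                               seed = 1402L, minLength = 2L) {
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts))
    stop("counts must be nonnegative integers")
  stopifnot2(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  stopifnot2(length(counts) >= 2, "need at least 2 bins")
  counts <- as.integer(round(counts))
  n <- length(counts)
  boundaries <- integer()  # split positions: bins before each boundary
  withLocalSeed(seed, {
    recurse <- function(lo, hi) {   # inclusive bin range
      len <- hi - lo + 1L
      if (len < max(2L, minLength)) return()
      seg <- counts[lo:hi]
      if (sum(seg) == 0) return()
      sp <- maxSplitStat(seg)
      p <- splitPValue(sp$stat, len, mean(seg), nSim)
      if (p < alpha) {
        cut <- lo + sp$index - 1L
        boundaries <<- c(boundaries, cut)
        recurse(lo, cut)
        recurse(cut + 1L, hi)
      }
    }
    recurse(1L, n)
  })
  boundaries <- sort(boundaries)
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  data.frame(start = starts, end = ends,
             rate = vapply(seq_along(starts), function(i)
               mean(counts[starts[i]:ends[i]]), numeric(1)))
}

#' Merge short segments into their closer-rate neighbour
#'
#' Bleach events rarely align with bin edges, so the transition bin carries an
#' intermediate count that the change-point search may isolate as a one- or
#' two-bin segment; such slivers would read as extra intensity steps. Any
#' segment shorter than `minLen` is absorbed into the adjacent segment with
#' the closer mean rate. The absorbing segment keeps its own rate: the
#' sliver's counts are a rate mixture and would bias it (in particular they
#' would lift a background segment above the bleach-acceptance tolerance).
#'
#' @param segs segment table from [detectChangepoints()].
#' @param counts the counts the segments were fitted on (used only to pick
#'   the closer neighbour when both adjoin).
#' @param minLen minimum retained segment length in bins.
#' @return A segment table with the same structure, spans contiguous.
#' @export
mergeShortSegments <- function(segs, counts, minLen = 3L) {
  repeat {
    len <- segs$end - segs$start + 1L
    if (nrow(segs) <= 1 || all(len >= minLen)) return(segs)
    short <- which(len < minLen)
    i <- short[which.min(len[short])]
    gap <- c(if (i > 1) abs(segs$rate[i] - segs$rate[i - 1]) else Inf,
             if (i < nrow(segs)) abs(segs$rate[i] - segs$rate[i + 1]) else Inf)
    into <- if (which.min(gap) == 1) i - 1L else i + 1L
    segs$start[into] <- min(segs$start[i], segs$start[into])
    segs$end[into] <- max(segs$end[i], segs$end[into])
    segs <- segs[-i, , drop = FALSE]
    rownames(segs) <- NULL
  }
}

## Classify segments as background: |rate - bg| <= nSigma * sqrt(bg / len),
## the standard error of a Poisson mean at the background rate.
isBackgroundSegment <- function(segs, background, nSigma = 3) {
  len <- segs$end - segs$start + 1L
  tol <- nSigma * sqrt(pmax(background, 0.25) / len)
  abs(segs$rate - background) <= tol
}

#' Select traces with single-step donor and acceptor photobleaching
#'
#' A molecule is analyzable when each channel shows exactly one downward
#' intensity step that terminates at the background level, with no recovery
#' (blinking) afterwards, the acceptor signal is clearly above background
#' before its bleach, and the acceptor bleaches no later than the donor.
#' The FRET window runs from the start of the trace to acceptor bleaching;
#' donor photons inside it form the FRET-level photon set.
#'
#' @param trace a [BinnedTrace-class].
#' @param segsDonor,segsAcceptor segment tables from [detectChangepoints()]
#'   for the donor and acceptor counts of `trace`.
#' @param background expected background counts per bin.
#' @param nSigma background-matching tolerance in Poisson standard errors.
#' @param acceptorMinFactor required ratio of acceptor pre-bleach rate to
#'   background (stand-in for a direct-excitation acceptor check).
#' @param minSegLen segments shorter than this are merged away first (see
#'   [mergeShortSegments()]); bleach-boundary bins otherwise masquerade as
#'   extra steps.
#' @return List: `accepted` flag, `acceptorBleachBin` / `donorBleachBin`
#'   (first background bin after the step, `NA` if none), `fretWindow`
#'   (start/end seconds), `rejectionReason` (`NA` when accepted; otherwise
#'   `"multi-step"`, `"no-bleach"`, `"blinking"`, `"no-acceptor"` or
#'   `"donor-first"`).
#' @export
selectTraces <- function(trace, segsDonor, segsAcceptor, background,
                         nSigma = 3, acceptorMinFactor = 3, minSegLen = 3L) {
  w <- trace@binWidth
  segsDonor <- mergeShortSegments(segsDonor, trace@countsDonor, minSegLen)
  segsAcceptor <- mergeShortSegments(segsAcceptor, trace@countsAcceptor,
                                     minSegLen)
  judge <- function(segs) {
    bg <- isBackgroundSegment(segs, background, nSigma)
    nSeg <- length(bg)
    fromSignal <- !bg[-nSeg]             # steps that leave a signal segment
    down <- which(diff(segs$rate) < 0 & bg[-1] & fromSignal)
    recovery <- any(diff(bg) < 0)        # background -> signal again
    nDown <- sum(diff(segs$rate) < 0 & fromSignal)
    list(bg = bg, downToBg = down, nDown = nDown, recovery = recovery)
  }
  d <- judge(segsDonor); a <- judge(segsAcceptor)

  reject <- function(reason) list(accepted = FALSE,
                                  acceptorBleachBin = NA_integer_,
                                  donorBleachBin = NA_integer_,
                                  fretWindow = c(NA_real_, NA_real_),
                                  rejectionReason = reason)
  if (d$recovery || a$recovery) return(reject("blinking"))
  if (d$nDown > 1 || a$nDown > 1) return(reject("multi-step"))
  if (length(d$downToBg) != 1 || length(a$downToBg) != 1 ||
      !all(d$bg[(d$downToBg + 1):length(d$bg)]) ||
      !all(a$bg[(a$downToBg + 1):length(a$bg)]))
    return(reject("no-bleach"))
  aPre <- max(segsAcceptor$rate[seq_len(a$downToBg)])
  if (aPre < acceptorMinFactor * max(background, 0.5))
    return(reject("no-acceptor"))
  donorBleachBin <- segsDonor$start[d$downToBg + 1L]
  acceptorBleachBin <- segsAcceptor$start[a$downToBg + 1L]
  if (acceptorBleachBin > donorBleachBin) return(reject("donor-first"))
  list(accepted = TRUE, acceptorBleachBin = acceptorBleachBin,
       donorBleachBin = donorBleachBin,
       fretWindow = c(0, (acceptorBleachBin - 1L) * w),
       rejectionReason = NA_character_)
}

#' Extract FRET-level donor nanotimes of an accepted molecule
#'
#' @param stream a [PhotonStream-class].
#' @param selection result of [selectTraces()].
#' @return Numeric vector of donor nanotimes with macrotime inside the FRET
#'   window, in temporal order.
#' @export
fretWindowNanotimes <- function(stream, selection) {
  if (!isTRUE(selection$accepted)) return(numeric())
  keep <- stream@channel == "donor" &
    stream@macrotime >= selection$fretWindow[1] &
    stream@macrotime < selection$fretWindow[2]
  stream@nanotime[keep]
}
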