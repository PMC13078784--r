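#' TCSPC acquisition specification
#'
#' Describes the time-correlated single-photon counting geometry used both by
#' the synthetic photon generator and by the decay-fit likelihood: the pulse
#' window, a Gaussian instrument response function (IRF), a uniform background
#' fraction, and the nominal channel discretization.
#'
#' The default window of 12.5 ns corresponds to an 80 MHz pulsed excitation
#' source. Nanotimes are treated as continuous; `channelWidth` documents the
#' hardware discretization but photon delays are modelled at channel centres.
#'
#' @slot window pulse period in ns; nanotimes live in `[0, window]`.
#' @slot irfMean,irfSigma Gaussian IRF location and width, ns.
#' @slot backgroundFraction fraction of detected photons whose nanotime is
#'   uniform over the window (dark counts, scattered light).
#' @slot channelWidth TCSPC channel width in ns (documentation only).
#' @export
setClass("TcspcSpec", representation(
  window = "numeric", irfMean = "numeric", irfSigma = "numeric",
  backgroundFraction = "numeric", channelWidth = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@window <= 0) msg <- c(msg, "window must be > 0")
  if (object@irfSigma < 0) msg <- c(msg, "irfSigma must be >= 0")
  if (object@backgroundFraction < 0 || object@backgroundFraction >= 1)
    msg <- c(msg, "backgroundFraction must be in [0, 1)")
  if (object@channelWidth <= 0) msg <- c(msg, "channelWidth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param window,irfMean,irfSigma,backgroundFraction,channelWidth see slots.
#' @return A `TcspcSpec` object.
#' @rdname TcspcSpec-class
#' @export
TcspcSpec <- function(window = 12.5, irfMean = 2, irfSigma = 0.15,
                      backgroundFraction = 0, channelWidth = 12.5 / 4096) {
  new("TcspcSpec", window = window, irfMean = irfMean, irfSigma = irfSigma,
      backgroundFraction = backgroundFraction, channelWidth = channelWidth)
}

#' Gaussian lifetime-mixture specification
#'
#' Shared component peak lifetimes and widths plus per-condition amplitudes,
#' the generative model assumed for donor-lifetime distributions of a
#' two-state (compact/open) conformational equilibrium.
#'
#' @slot means component peak lifetimes (ns), strictly increasing.
#' @slot sigmas component standard deviations (ns), `>= 0` (0 gives a
#'   degenerate point component, useful for exact tests).
#' @slot weights numeric matrix, one row per condition (rownames are the
#'   condition labels), one column per component; rows sum to 1.
#' @export
setClass("MixtureSpec", representation(
  means = "numeric", sigmas = "numeric", weights = "matrix"
), validity = function(object) {
  msg <- character()
  k <- length(object@means)
  if (k >= 2 && any(diff(object@means) <= 0))
    msg <- c(msg, "means must be strictly increasing")
  if (length(object@sigmas) != k) msg <- c(msg, "sigmas length must match means")
  if (any(object@sigmas < 0)) msg <- c(msg, "sigmas must be >= 0")
  if (ncol(object@weights) != k)
    msg <- c(msg, "weights must have one column per component")
  if (is.null(rownames(object@weights)))
    msg <- c(msg, "weights rows must be named by condition")
  if (any(object@weights < 0 | object@weights > 1))
    msg <- c(msg, "weights must lie in [0, 1]")
  if (any(abs(rowSums(object@weights) - 1) > 1e-9))
    msg <- c(msg, "each condition's weights must sum to 1")
  if (length(msg)) msg else TRUE
})

#' @param means,sigmas,weights see slots; `weights` may also be a named list
#'   of per-condition amplitude vectors.
#' @return A `MixtureSpec` object.
#' @rdname MixtureSpec-class
#' @export
MixtureSpec <- function(means, sigmas, weights) {
  if (is.list(weights))
    weights <- do.call(rbind, weights)
  if (is.null(dim(weights))) weights <- matrix(weights, nrow = 1,
                                               dimnames = list("condition1"))
  new("MixtureSpec", means = as.numeric(means), sigmas = as.numeric(sigmas),
      weights = weights)
}

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec: %d component(s), %d condition(s)\n",
              length(object@means), nrow(object@weights)))
  cat("  means (ns): ", paste(format(object@means), collapse = ", "), "\n")
  cat("  sigmas (ns):", paste(format(object@sigmas), collapse = ", "), "\n")
  for (cond in rownames(object@weights))
    cat(sprintf("  %s: %s\n", cond,
                paste(format(object@weights[cond, ], digits = 3), collapse = ", ")))
})

#' Per-molecule simulation template
#'
#' Emission rates, photobleaching times and stage lifetimes for one
#' immobilized molecule. When used as a template by [simulateCondition()],
#' rates are taken as given and bleach times as exponential means.
#'
#' @slot stateIndex mixture component assignment (1-based).
#' @slot donorRateFret,donorRatePostbleach,acceptorRate mean detected photons
#'   per second in each acquisition stage.
#' @slot acceptorBleachTime,donorBleachTime single-step photobleaching times, s.
#' @slot backgroundRate dark counts per second per channel.
#' @slot lifetimeFret,lifetimeDonorOnly donor excited-state lifetime (ns)
#'   before and after acceptor photobleaching.
#' @export
setClass("MoleculeSim", representation(
  stateIndex = "integer", donorRateFret = "numeric",
  donorRatePostbleach = "numeric", acceptorRate = "numeric",
  acceptorBleachTime = "numeric", donorBleachTime = "numeric",
  backgroundRate = "numeric", lifetimeFret = "numeric",
  lifetimeDonorOnly = "numeric"
), validity = function(object) {
  msg <- character()
  rates <- c(object@donorRateFret, object@donorRatePostbleach,
             object@acceptorRate, object@backgroundRate)
  if (any(rates < 0)) msg <- c(msg, "rates must be >= 0")
  if (object@acceptorBleachTime <= 0 || object@donorBleachTime <= 0)
    msg <- c(msg, "bleach times must be > 0")
  if (object@lifetimeFret <= 0 || object@lifetimeDonorOnly <= 0)
    msg <- c(msg, "lifetimes must be > 0")
  if (length(msg)) msg else TRUE
})

#' @param stateIndex,donorRateFret,donorRatePostbleach,acceptorRate see slots.
#' @param acceptorBleachTime,donorBleachTime,backgroundRate see slots.
#' @param lifetimeFret,lifetimeDonorOnly see slots.
#' @return A `MoleculeSim` object.
#' @rdname MoleculeSim-class
#' @export
MoleculeSim <- function(stateIndex = 1L, donorRateFret = 500,
                        donorRatePostbleach = 700, acceptorRate = 300,
                        acceptorBleachTime = 20, donorBleachTime = 30,
                        backgroundRate = 10, lifetimeFret = 1.3,
                        lifetimeDonorOnly = 3.0) {
  new("MoleculeSim", stateIndex = as.integer(stateIndex),
      donorRateFret = donorRateFret, donorRatePostbleach = donorRatePostbleach,
      acceptorRate = acceptorRate, acceptorBleachTime = acceptorBleachTime,
      donorBleachTime = donorBleachTime, backgroundRate = backgroundRate,
      lifetimeFret = lifetimeFret, lifetimeDonorOnly = lifetimeDonorOnly)
}

#' Photon stream for one immobilized molecule
#'
#' Time-sorted photon records: absolute arrival time (macrotime, s), delay
#' after the excitation pulse (nanotime, ns) and detection channel.
#'
#' @slot macrotime arrival times in seconds, nondecreasing.
#' @slot nanotime TCSPC delays in ns, within the pulse window.
#' @slot channel `"donor"` or `"acceptor"` per photon.
#' @slot duration total acquisition time, s.
#' @slot meta list of acquisition metadata (molecule id, ground truth, ...).
#' @export
setClass("PhotonStream", representation(
  macrotime = "numeric", nanotime = "numeric", channel = "character",
  duration = "numeric", meta = "list"
), validity = function(object) {
  msg <- character()
  n <- length(object@macrotime)
  if (length(object@nanotime) != n || length(object@channel) != n)
    msg <- c(msg, "macrotime, nanotime, channel must have equal length")
  if (n > 1 && any(diff(object@macrotime) < 0))
    msg <- c(msg, "macrotime must be nondecreasing")
  if (!all(object@channel %in% c("donor", "acceptor")))
    msg <- c(msg, "channel must be 'donor' or 'acceptor'")
  if (object@duration < 0) msg <- c(msg, "duration must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @param macrotime,nanotime,channel,duration,meta see slots.
#' @return A `PhotonStream` object.
#' @rdname PhotonStream-class
#' @export
PhotonStream <- function(macrotime = numeric(), nanotime = numeric(),
                         channel = character(), duration = NA_real_,
                         meta = list()) {
  if (is.na(duration))
    duration <- if (length(macrotime)) max(macrotime) else 0
  new("PhotonStream", macrotime = as.numeric(macrotime),
      nanotime = as.numeric(nanotime), channel = as.character(channel),
      duration = duration, meta = meta)
}

setMethod("show", "PhotonStream", function(object) {
  cat(sprintf("PhotonStream: %d photons over %.2f s (%d donor, %d acceptor)\n",
              length(object@macrotime), object@duration,
              sum(object@channel == "donor"),
              sum(object@channel == "acceptor")))
})

setMethod("length", "PhotonStream", function(x) length(x@macrotime))

#' Binned two-channel intensity trace
#'
#' @slot binWidth bin width in seconds (0.1 s default workflow).
#' @slot countsDonor,countsAcceptor photon counts per bin.
#' @slot startTime macrotime of the first bin's left edge, s.
#' @export
setClass("BinnedTrace", representation(
  binWidth = "numeric", countsDonor = "integer", countsAcceptor = "integer",
  startTime = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (length(object@countsDonor) != length(object@countsAcceptor))
    msg <- c(msg, "channel count vectors must have equal length")
  if (any(object@countsDonor < 0) || any(object@countsAcceptor < 0))
    msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BinnedTrace", function(object) {
  cat(sprintf("BinnedTrace: %d bins of %.3f s\n",
              length(object@countsDonor), object@binWidth))
})

setMethod("length", "BinnedTrace", function(x) length(x@countsDonor))

#' Lifetime histogram with square-root-rule binning
#'
#' Equal-width histogram of per-bunch lifetime estimates; the number of bins
#' is the rounded square root of the number of bunches.
#'
#' @slot binEdges bin boundaries, ns.
#' @slot counts bunch counts per bin; sums to `nBunches`.
#' @slot nBunches total number of photon bunches.
#' @slot condition condition label.
#' @export
setClass("LifetimeHistogram", representation(
  binEdges = "numeric", counts = "integer", nBunches = "integer",
  condition = "character"
), validity = function(object) {
  msg <- character()
  if (length(object@binEdges) != length(object@counts) + 1L)
    msg <- c(msg, "binEdges must have length(counts) + 1 entries")
  if (sum(object@counts) != object@nBunches)
    msg <- c(msg, "counts must sum to nBunches")
  if (length(object@counts) != max(1L, round(sqrt(object@nBunches))))
    msg <- c(msg, "bin count must be round(sqrt(nBunches))")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LifetimeHistogram", function(object) {
  cat(sprintf("LifetimeHistogram [%s]: %d bunches in %d bins over [%.2f, %.2f] ns\n",
              object@condition, object@nBunches, length(object@counts),
              min(object@binEdges), max(object@binEdges)))
})

#' Globally fitted shared-component Gaussian mixture
#'
#' Result of fitting lifetime distributions from several conditions jointly:
#' peak positions and widths are shared, only per-condition amplitudes vary.
#'
#' @slot k number of Gaussian components.
#' @slot means,sigmas shared component parameters (ns), means increasing.
#' @slot weights per-condition amplitude matrix (rows = conditions).
#' @slot weightSE approximate standard errors of the amplitudes.
#' @slot logLik maximized joint log-likelihood.
#' @slot n total number of photon bunches across all conditions.
#' @slot bic Bayesian Information Criterion, `-2 logLik + p log(n)` with
#'   `p = 2k + (k - 1) * nConditions` free parameters.
#' @slot converged logical EM convergence flag.
#' @slot fingerprint data checksum used to verify that candidate models
#'   being compared were fitted on identical data.
#' @export
setClass("GaussianMixtureModel", representation(
  k = "integer", means = "numeric", sigmas = "numeric", weights = "matrix",
  weightSE = "matrix", logLik = "numeric", n = "integer", bic = "numeric",
  converged = "logical", fingerprint = "numeric"
), validity = function(object) {
  msg <- character()
  if (length(object@means) != object@k || length(object@sigmas) != object@k)
    msg <- c(msg, "means/sigmas must have k entries")
  if (object@k >= 2 && any(diff(object@means) <= 0))
    msg <- c(msg, "means must be strictly increasing")
  if (any(object@sigmas <= 0)) msg <- c(msg, "sigmas must be > 0")
  if (ncol(object@weights) != object@k)
    msg <- c(msg, "weights must have k columns")
  if (any(abs(rowSums(object@weights) - 1) > 1e-6))
    msg <- c(msg, "each condition's weights must sum to 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GaussianMixtureModel", function(object) {
  cat(sprintf("GaussianMixtureModel: k = %d, %d condition(s), n = %d bunches\n",
              object@k, nrow(object@weights), object@n))
  cat("  means (ns): ", paste(format(object@means, digits = 4), collapse = ", "), "\n")
  cat("  sigmas (ns):", paste(format(object@sigmas, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.2f, BIC = %.2f, converged = %s\n",
              object@logLik, object@bic, object@converged))
})

#' Förster conversion parameters
#'
#' @slot r0 Förster distance in nm (donor-acceptor separation at E = 0.5);
#'   8.4 nm for the snap surface 594 / Cy5 pair, 7.5 nm for snap surface
#'   594 / atto 647N.
#' @slot tauD donor-only reference lifetime, ns.
#' @export
setClass("FretParams", representation(r0 = "numeric", tauD = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@r0 <= 0) msg <- c(msg, "r0 must be > 0")
    if (object@tauD <= 0) msg <- c(msg, "tauD must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param r0,tauD see slots.
#' @return A `FretParams` object.
#' @rdname FretParams-class
#' @export
FretParams <- function(r0 = 8.4, tauD = 3.0) new("FretParams", r0 = r0, tauD = tauD)

#' Labeled coarse-grained coordinate frame
#'
#' One frame of bead coordinates with kind labels (lipid / protein / solvent),
#' per-protein-bead residue ids and an orthorhombic box.
#'
#' @slot coords N x 3 coordinate matrix, Angstrom.
#' @slot kind per-bead kind: `"lipid"`, `"protein"` or `"solvent"`.
#' @slot residueId integer residue id per bead (`NA` for non-protein beads).
#' @slot box orthorhombic box edge lengths, Angstrom.
#' @slot periodic whether minimum-image wrapping applies.
#' @export
setClass("TrajectoryFrame", representation(
  coords = "matrix", kind = "character", residueId = "integer",
  box = "numeric", periodic = "logical"
), validity = function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 3) msg <- c(msg, "coords must be N x 3")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coords must be finite")
  if (length(object@kind) != n || length(object@residueId) != n)
    msg <- c(msg, "kind and residueId must have one entry per bead")
  if (!all(object@kind %in% c("lipid", "protein", "solvent")))
    msg <- c(msg, "kind must be lipid/protein/solvent")
  if (length(object@box) != 3 || any(object@box <= 0))
    msg <- c(msg, "box must be three positive edge lengths")
  bad <- !is.na(object@residueId) & object@residueId <= 0
  if (any(bad)) msg <- c(msg, "residue ids must be positive")
  if (length(msg)) msg else TRUE
})

#' @param coords,kind,residueId,box,periodic see slots.
#' @return A `TrajectoryFrame` object.
#' @rdname TrajectoryFrame-class
#' @export
TrajectoryFrame <- function(coords, kind, residueId = rep(NA_integer_, nrow(coords)),
                            box, periodic = TRUE) {
  new("TrajectoryFrame", coords = as.matrix(coords), kind = as.character(kind),
      residueId = as.integer(residueId), box = as.numeric(box),
      periodic = periodic)
}

setMethod("show", "TrajectoryFrame", function(object) {
  cat(sprintf("TrajectoryFrame: %d beads (%d lipid, %d protein) in %s A box%s\n",
              nrow(object@coords), sum(object@kind == "lipid"),
              sum(object@kind == "protein"),
              paste(format(object@box), collapse = " x "),
              if (object@periodic) ", periodic" else ""))
})

#' Umbrella-sampling window
#'
#' A biased collective-variable (CV) time series with its harmonic bias.
#' Energies are in kT units: the bias at CV value x is
#' `springK / 2 * (x - center)^2`.
#'
#' @slot center bias center, CV units.
#' @slot springK harmonic spring constant, kT per CV unit squared.
#' @slot cv sampled CV series.
#' @export
setClass("UmbrellaWindow", representation(
  center = "numeric", springK = "numeric", cv = "numeric"
), validity = function(object) {
  msg <- character()
  if (object@springK < 0) msg <- c(msg, "springK must be >= 0")
  if (!length(object@cv)) msg <- c(msg, "cv series must be non-empty")
  if (length(msg)) msg else TRUE
})

#' @param center,springK,cv see slots.
#' @return An `UmbrellaWindow` object.
#' @rdname UmbrellaWindow-class
#' @export
UmbrellaWindow <- function(center, springK, cv) {
  new("UmbrellaWindow", center = center, springK = springK, cv = as.numeric(cv))
}

setMethod("show", "UmbrellaWindow", function(object) {
  cat(sprintf("UmbrellaWindow: center %.3f, k = %.3f kT, %d samples\n",
              object@center, object@springK, length(object@cv)))
})
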