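## Synthetic-data generators: seeded photon streams, lifetime samples,
## coarse-grained frames and umbrella-biased CV series with the statistical
## structure the downstream analysis assumes.

#' Condition presets: open-state amplitudes across membrane compositions
#'
#' Open-conformation amplitudes for the eight POPC/POPS membrane conditions
#' (with and without EGF) used as generator defaults, expressed as the weight
#' of the long-lifetime (open) component.
#'
#' @return Named numeric vector of open-state fractions.
#' @export
egfrConditionWeights <- function() {
  c("0% POPS -EGF"  = 0.87, "0% POPS +EGF"  = 0.60,
    "15% POPS -EGF" = 0.69, "15% POPS +EGF" = 0.91,
    "30% POPS -EGF" = 0.74, "30% POPS +EGF" = 0.96,
    "60% POPS -EGF" = 0.90, "60% POPS +EGF" = 0.95)
}

#' Default two-state donor-lifetime mixture
#'
#' The globally fitted two-state model for the EGFR C-terminal tail: a compact
#' conformation at 1.3 ns (sigma 0.35 ns) and an open conformation at 2.7 ns
#' (sigma 0.67 ns), with per-condition open-state amplitudes from
#' [egfrConditionWeights()].
#'
#' @param conditions subset of condition labels (default: all eight presets),
#'   or a named numeric vector of open fractions.
#' @return A [MixtureSpec-class] object.
#' @export
egfrMixtureSpec <- function(conditions = egfrConditionWeights()) {
  if (is.character(conditions)) {
    all <- egfrConditionWeights()
    missing <- setdiff(conditions, names(all))
    if (length(missing))
      stop("unknown condition label(s): ", paste(missing, collapse = ", "))
    conditions <- all[conditions]
  }
  w <- cbind(1 - conditions, conditions)
  rownames(w) <- names(conditions)
  MixtureSpec(means = c(1.3, 2.7), sigmas = c(0.35, 0.67), weights = w)
}

#' Sample lifetimes from a condition's Gaussian mixture
#'
#' Draws from the condition's component mixture; non-positive draws are
#' rejected and redrawn since lifetimes must be positive.
#'
#' @param spec a [MixtureSpec-class].
#' @param condition condition label (a rowname of the weight matrix).
#' @param n number of draws, `> 0`.
#' @param seed integer seed for reproducibility, or `NULL`.
#' @return Numeric vector of `n` lifetimes (ns).
#' @export
sampleMixtureLifetimes <- function(spec, condition, n, seed = NULL) {
  stopifnot2(is(spec, "MixtureSpec"), "spec must be a MixtureSpec")
  stopifnot2(n > 0, "n must be > 0")
  if (!condition %in% rownames(spec@weights))
    stop("unknown condition label '", condition, "'; available: ",
         paste(rownames(spec@weights), collapse = ", "))
  w <- spec@weights[condition, ]
  withLocalSeed(seed, {
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    x <- stats::rnorm(n, spec@means[comp], spec@sigmas[comp])
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- stats::rnorm(length(bad), spec@means[comp[bad]],
                             spec@sigmas[comp[bad]])
      bad <- bad[x[bad] <= 0]
    }
    x
  })
}

## Draw nanotimes from the truncated (Gaussian IRF (*) exponential) law on
## [0, window]: out-of-window draws are redrawn, matching the truncated and
## renormalized likelihood used by the decay fit.
rTruncatedDecay <- function(n, tau, tcspc) {
  W <- tcspc@window
  t <- stats::rnorm(n, tcspc@irfMean, tcspc@irfSigma) + stats::rexp(n, 1 / tau)
  bad <- which(t < 0 | t > W)
  while (length(bad)) {
    t[bad] <- stats::rnorm(length(bad), tcspc@irfMean, tcspc@irfSigma) +
      stats::rexp(length(bad), 1 / tau)
    bad <- bad[t[bad] < 0 | t[bad] > W]
  }
  t
}

## Homogeneous Poisson arrivals on [t0, t1) at the given rate, sorted.
rPoissonArrivals <- function(rate, t0, t1) {
  if (rate <= 0 || t1 <= t0) return(numeric())
  n <- stats::rpois(1, rate * (t1 - t0))
  sort(stats::runif(n, t0, t1))
}

#' Simulate the photon stream of one immobilized molecule
#'
#' Donor and acceptor arrivals are homogeneous Poisson processes whose rates
#' switch at the single-step photobleaching times: FRET stage before acceptor
#' bleach, donor-only stage between acceptor and donor bleach, background only
#' afterwards. Donor nanotimes follow the stage lifetime convolved with the
#' Gaussian IRF and truncated to the pulse window; a `backgroundFraction` of
#' photons plus all dark counts carry uniform nanotimes.
#'
#' @param mol a [MoleculeSim-class] with rates, bleach times and stage
#'   lifetimes.
#' @param tcspc a [TcspcSpec-class].
#' @param duration acquisition length in seconds, `> 0`.
#' @param seed integer seed or `NULL`.
#' @return A [PhotonStream-class], time-sorted.
#' @export
simulatePhotonStream <- function(mol, tcspc, duration, seed = NULL) {
  stopifnot2(is(mol, "MoleculeSim"), "mol must be a MoleculeSim")
  stopifnot2(duration > 0, "duration must be > 0")
  W <- tcspc@window
  bf <- tcspc@backgroundFraction
  withLocalSeed(seed, {
    ab <- min(mol@acceptorBleachTime, duration)
    db <- min(mol@donorBleachTime, duration)
    dOnlyStart <- min(ab, db)

    dFret <- rPoissonArrivals(mol@donorRateFret, 0, dOnlyStart)
    dPost <- rPoissonArrivals(mol@donorRatePostbleach, dOnlyStart, db)
    aSig  <- rPoissonArrivals(mol@acceptorRate, 0, ab)
    dBg   <- rPoissonArrivals(mol@backgroundRate, 0, duration)
    aBg   <- rPoissonArrivals(mol@backgroundRate, 0, duration)

    ntFret <- rTruncatedDecay(length(dFret), mol@lifetimeFret, tcspc)
    ntPost <- rTruncatedDecay(length(dPost), mol@lifetimeDonorOnly, tcspc)
    if (bf > 0) {
      u <- stats::runif(length(ntFret)) < bf
      ntFret[u] <- stats::runif(sum(u), 0, W)
      u <- stats::runif(length(ntPost)) < bf
      ntPost[u] <- stats::runif(sum(u), 0, W)
    }

    macro <- c(dFret, dPost, dBg, aSig, aBg)
    nano <- c(ntFret, ntPost, stats::runif(length(dBg), 0, W),
              stats::runif(length(aSig) + length(aBg), 0, W))
    chan <- c(rep("donor", length(dFret) + length(dPost) + length(dBg)),
              rep("acceptor", length(aSig) + length(aBg)))
    ord <- order(macro)
    PhotonStream(macrotime = macro[ord], nanotime = nano[ord],
                 channel = chan[ord], duration = duration,
                 meta = list(acceptorBleach = ab, donorBleach = db,
                             state = mol@stateIndex,
                             lifetimeFret = mol@lifetimeFret))
  })
}

#' Simulate all molecules of one experimental condition
#'
#' Each molecule's conformational state is drawn from the condition's mixture
#' weights and its FRET-stage donor lifetime from that component; bleach times
#' are exponential with the template means (donor bleach follows acceptor
#' bleach by an exponential waiting time). After acceptor photobleaching the
#' donor count rate rises by `1 / (1 - E)`, consistent with the loss of energy
#' transfer.
#'
#' Within one state the donor lifetime is not frozen: it fluctuates around
#' the state's peak (conformational breathing within the open or compact
#' well). This is modelled as a piecewise-constant lifetime redrawn from the
#' state's Gaussian component every `redrawInterval` seconds -- slow
#' compared to a photon bunch, fast compared to the trace -- so that
#' per-bunch lifetime estimates sample the state's full width rather than a
#' single frozen value per molecule. `redrawInterval = Inf` freezes one
#' lifetime per molecule.
#'
#' @param spec a [MixtureSpec-class].
#' @param condition condition label.
#' @param nMolecules number of molecules, `> 0`.
#' @param molTemplate a [MoleculeSim-class]; rates are used as given, bleach
#'   times as exponential means.
#' @param tcspc a [TcspcSpec-class].
#' @param seed integer seed or `NULL`; per-molecule substreams are derived
#'   from it by counter.
#' @param redrawInterval within-state lifetime correlation time, s.
#' @return List with `streams` (list of [PhotonStream-class]) and `truth`
#'   (data.frame: molecule_id, state, lifetime_ns -- the molecule's drawn
#'   state lifetime, around which within-state redraws fluctuate --
#'   acceptor_bleach_s, donor_bleach_s).
#' @export
simulateCondition <- function(spec, condition, nMolecules,
                              molTemplate = MoleculeSim(), tcspc = TcspcSpec(),
                              seed = NULL, redrawInterval = 2) {
  stopifnot2(nMolecules > 0, "nMolecules must be > 0")
  if (!condition %in% rownames(spec@weights))
    stop("unknown condition label '", condition, "'")
  w <- spec@weights[condition, ]
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  drawn <- withLocalSeed(seed, {
    state <- sample.int(length(w), nMolecules, replace = TRUE, prob = w)
    tau <- stats::rnorm(nMolecules, spec@means[state], spec@sigmas[state])
    bad <- which(tau <= 0)
    while (length(bad)) {
      tau[bad] <- stats::rnorm(length(bad), spec@means[state[bad]],
                               spec@sigmas[state[bad]])
      bad <- bad[tau[bad] <= 0]
    }
    ab <- stats::rexp(nMolecules, 1 / molTemplate@acceptorBleachTime)
    gap <- max(molTemplate@donorBleachTime - molTemplate@acceptorBleachTime,
               .Machine$double.eps)
    db <- ab + stats::rexp(nMolecules, 1 / gap)
    list(state = state, tau = tau, ab = ab, db = db)
  })
  tauD <- molTemplate@lifetimeDonorOnly
  streams <- vector("list", nMolecules)
  for (i in seq_len(nMolecules)) {
    tauFret <- drawn$tau[i]
    ## rate step at acceptor bleach: 1/(1-E), with E floored so molecules
    ## whose drawn lifetime approaches or exceeds tauD keep a flat-or-upward
    ## donor step (near-zero transfer) instead of an unphysical drop
    E <- max(1 - tauFret / tauD, 0.05)
    mol <- new("MoleculeSim", stateIndex = drawn$state[i],
               donorRateFret = molTemplate@donorRateFret,
               donorRatePostbleach = molTemplate@donorRateFret / (1 - E),
               acceptorRate = molTemplate@acceptorRate,
               acceptorBleachTime = drawn$ab[i], donorBleachTime = drawn$db[i],
               backgroundRate = molTemplate@backgroundRate,
               lifetimeFret = tauFret, lifetimeDonorOnly = tauD)
    streams[[i]] <- simulatePhotonStream(mol, tcspc,
                                         duration = drawn$db[i] + 5,
                                         seed = subSeed(seed, i))
    if (is.finite(redrawInterval))
      streams[[i]] <- redrawFretLifetimes(streams[[i]], mol, tcspc,
                                          spec@means[drawn$state[i]],
                                          spec@sigmas[drawn$state[i]],
                                          redrawInterval,
                                          seed = subSeed(seed, nMolecules + i))
    streams[[i]]@meta$molecule_id <- i
    streams[[i]]@meta$condition <- condition
  }
  truth <- data.frame(molecule_id = seq_len(nMolecules), state = drawn$state,
                      lifetime_ns = drawn$tau, acceptor_bleach_s = drawn$ab,
                      donor_bleach_s = drawn$db)
  list(streams = streams, truth = truth)
}

## Resample FRET-stage donor nanotimes under a piecewise-constant lifetime
## redrawn from the state's Gaussian component on a fixed interval grid.
## Each photon is uniform (dark count or scattered light) with the stage's
## overall uniform-nanotime probability, else a truncated decay draw, so the
## regenerated stage is statistically consistent with the original model.
redrawFretLifetimes <- function(stream, mol, tcspc, mu, sigma, interval,
                                seed = NULL) {
  ab <- stream@meta$acceptorBleach
  idx <- which(stream@channel == "donor" & stream@macrotime < ab)
  if (!length(idx)) return(stream)
  W <- tcspc@window
  pUnif <- (mol@backgroundRate +
              tcspc@backgroundFraction * mol@donorRateFret) /
    (mol@backgroundRate + mol@donorRateFret)
  withLocalSeed(seed, {
    piece <- floor(stream@macrotime[idx] / interval)
    for (pc in unique(piece)) {
      sub <- idx[piece == pc]
      tau <- stats::rnorm(1, mu, sigma)
      while (tau <= 0) tau <- stats::rnorm(1, mu, sigma)
      nt <- rTruncatedDecay(length(sub), tau, tcspc)
      u <- stats::runif(length(sub)) < pUnif
      nt[u] <- stats::runif(sum(u), 0, W)
      stream@nanotime[sub] <- nt
    }
  })
  stream
}

#' Overdamped Langevin sampling of a biased 1-D collective variable
#'
#' Euler-Maruyama integration of `dx = -grad(U(x) + k/2 (x - c)^2) dt +
#' sqrt(2 dt) dW` in kT units, one series per umbrella window. For long runs
#' each window's samples converge to the Boltzmann law of the biased
#' potential.
#'
#' @param potential function of one CV value returning energy in kT.
#' @param windows data.frame with columns `center` and `springK` (kT/unit^2),
#'   one row per window.
#' @param nSteps number of recorded steps per window, `> 0`.
#' @param stepSize integration step `dt / friction`.
#' @param friction friction coefficient (scales the step).
#' @param burnIn fraction of initial steps discarded.
#' @param seed integer seed or `NULL`.
#' @return List of [UmbrellaWindow-class] objects.
#' @export
simulateLangevinCV <- function(potential, windows, nSteps, stepSize = 0.01,
                               friction = 1, burnIn = 0.1, seed = NULL) {
  stopifnot2(nSteps > 0, "nSteps must be > 0")
  windows <- as.data.frame(windows)
  stopifnot2(nrow(windows) >= 1, "at least one window is required")
  stopifnot2(all(windows$springK >= 0), "spring constants must be >= 0")
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  h <- stepSize / friction
  eps <- 1e-4
  nBurn <- floor(burnIn * nSteps)
  total <- nSteps + nBurn
  out <- vector("list", nrow(windows))
  for (wIdx in seq_len(nrow(windows))) {
    cen <- windows$center[wIdx]; k <- windows$springK[wIdx]
    out[[wIdx]] <- withLocalSeed(subSeed(seed, wIdx), {
      noise <- stats::rnorm(total, sd = sqrt(2 * h))
      x <- cen
      xs <- numeric(total)
      for (i in seq_len(total)) {
        grad <- (potential(x + eps) - potential(x - eps)) / (2 * eps) +
          k * (x - cen)
        x <- x - grad * h + noise[i]
        xs[i] <- x
      }
      UmbrellaWindow(center = cen, springK = k,
                     cv = xs[(nBurn + 1):total])
    })
  }
  out
}

#' Build a labeled coarse-grained frame
#'
#' Lipid beads are placed uniformly in the box; protein beads are taken at the
#' caller's coordinates with residue labels (e.g. the ATP-site residues and
#' residues 721 / 1186 for the accessibility metrics).
#'
#' @param nLipidBeads number of uniformly placed lipid beads.
#' @param proteinBeads data.frame with columns `residueId`, `x`, `y`, `z`
#'   (Angstrom), or `NULL` for a lipid-only frame.
#' @param box orthorhombic edge lengths, Angstrom.
#' @param periodic logical; minimum-image wrapping downstream.
#' @param seed integer seed or `NULL`.
#' @return A [TrajectoryFrame-class].
#' @export
makeCGFrame <- function(nLipidBeads, proteinBeads = NULL, box, periodic = TRUE,
                        seed = NULL) {
  stopifnot2(all(box > 0), "box edges must be > 0")
  pcoords <- matrix(numeric(), 0, 3)
  pres <- integer()
  if (!is.null(proteinBeads) && nrow(proteinBeads)) {
    pcoords <- as.matrix(proteinBeads[, c("x", "y", "z")])
    if (any(pcoords < 0) || any(sweep(pcoords, 2, box) > 0))
      stop("protein bead outside box")
    pres <- as.integer(proteinBeads$residueId)
  }
  lcoords <- withLocalSeed(seed, {
    matrix(stats::runif(3 * nLipidBeads), ncol = 3) %*% diag(box, 3)
  })
  coords <- rbind(lcoords, pcoords)
  dimnames(coords) <- NULL
  TrajectoryFrame(coords = coords,
                  kind = c(rep("lipid", nLipidBeads),
                           rep("protein", length(pres))),
                  residueId = c(rep(NA_integer_, nLipidBeads), pres),
                  box = box, periodic = periodic)
}
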