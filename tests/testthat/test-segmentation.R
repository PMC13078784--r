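test_that("photon binning drops the trailing partial bin and keeps channels", {
  s <- PhotonStream(macrotime = c(0.01, 0.05, 0.15), nanotime = c(1, 2, 3),
                    channel = rep("donor", 3), duration = 0.2)
  tr <- binPhotons(s, 0.1)
  expect_equal(tr@countsDonor, c(2L, 1L))
  expect_equal(tr@countsAcceptor, c(0L, 0L))

  expect_length(binPhotons(PhotonStream(duration = 0), 0.1), 0)

  tc <- TcspcSpec()
  mol <- MoleculeSim(donorRateFret = 500, acceptorRate = 0, backgroundRate = 0,
                     acceptorBleachTime = 100, donorBleachTime = 101)
  tr2 <- binPhotons(simulatePhotonStream(mol, tc, 10, seed = 1), 0.1)
  expect_length(tr2, 100)
  expect_lt(abs(mean(tr2@countsDonor) - 50), 3 * sqrt(50 / 100))
  expect_equal(sum(tr2@countsAcceptor), 0)
})

test_that("segment rates are the Poisson MLE (segment sample means)", {
  set.seed(3)
  counts <- c(rpois(40, 60), rpois(40, 6))
  segs <- detectChangepoints(counts, alpha = 0.01)
  for (i in seq_len(nrow(segs)))
    expect_equal(segs$rate[i], mean(counts[segs$start[i]:segs$end[i]]))
})

test_that("a noiseless step yields one change point at the boundary", {
  segs <- detectChangepoints(c(rep(50L, 30), rep(0L, 30)), alpha = 0.01)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end[1], 30)
  expect_equal(segs$rate, c(50, 0))
  expect_error(detectChangepoints(c(1.5, 2, 3)), "nonnegative integers")
  expect_error(detectChangepoints(c(-1L, 2L)), "nonnegative integers")
})

test_that("well-separated double steps are recovered within 2 bins", {
  nrec <- 0L
  nsim <- 60
  set.seed(17)
  for (i in seq_len(nsim)) {
    counts <- c(rpois(100, 60), rpois(100, 30), rpois(100, 5))
    segs <- detectChangepoints(counts, alpha = 0.01)
    cuts <- segs$end[-nrow(segs)]
    ok <- any(abs(cuts - 100) <= 2) && any(abs(cuts - 200) <= 2)
    nrec <- nrec + ok
  }
  expect_gte(nrec / nsim, 0.95)
})

test_that("false-split rate under a constant Poisson null stays near alpha", {
  set.seed(23)
  hits <- 0L
  ntr <- 300
  for (i in seq_len(ntr)) {
    segs <- detectChangepoints(rpois(100, 20), alpha = 0.01, seed = 100 + i)
    hits <- hits + (nrow(segs) > 1)
  }
  expect_lte(hits / ntr, 0.04)  # 2*alpha plus binomial slack at 300 traces
})

test_that("single-step bleaching selection accepts and rejects correctly", {
  trace <- new("BinnedTrace", binWidth = 0.1,
               countsDonor = as.integer(c(rep(50, 40), rep(1, 20))),
               countsAcceptor = as.integer(c(rep(30, 30), rep(1, 30))),
               startTime = 0)
  segD <- data.frame(start = c(1, 41), end = c(40, 60), rate = c(50, 1))
  segA <- data.frame(start = c(1, 31), end = c(30, 60), rate = c(30, 1))
  sel <- selectTraces(trace, segD, segA, background = 1)
  expect_true(sel$accepted)
  expect_equal(sel$acceptorBleachBin, 31)
  expect_equal(sel$fretWindow, c(0, 3.0))

  segD2 <- data.frame(start = c(1, 21, 41), end = c(20, 40, 60),
                      rate = c(50, 25, 1))
  expect_equal(selectTraces(trace, segD2, segA, 1)$rejectionReason,
               "multi-step")

  segD3 <- data.frame(start = c(1, 21, 41), end = c(20, 40, 60),
                      rate = c(50, 1, 48))
  expect_equal(selectTraces(trace, segD3, segA, 1)$rejectionReason,
               "blinking")

  segDflat <- data.frame(start = 1, end = 60, rate = 50)
  expect_equal(selectTraces(trace, segDflat, segA, 1)$rejectionReason,
               "no-bleach")

  segAweak <- data.frame(start = c(1, 31), end = c(30, 60), rate = c(2, 1))
  expect_equal(selectTraces(trace, segD, segAweak, 1)$rejectionReason,
               "no-acceptor")
})

test_that("selection is invariant to appended post-bleach background bins", {
  trace <- new("BinnedTrace", binWidth = 0.1,
               countsDonor = as.integer(c(rep(50, 40), rep(1, 20))),
               countsAcceptor = as.integer(c(rep(30, 30), rep(1, 30))),
               startTime = 0)
  segD <- data.frame(start = c(1, 41), end = c(40, 60), rate = c(50, 1))
  segA <- data.frame(start = c(1, 31), end = c(30, 60), rate = c(30, 1))
  base <- selectTraces(trace, segD, segA, 1)

  traceExt <- new("BinnedTrace", binWidth = 0.1,
                  countsDonor = as.integer(c(rep(50, 40), rep(1, 60))),
                  countsAcceptor = as.integer(c(rep(30, 30), rep(1, 70))),
                  startTime = 0)
  segDe <- data.frame(start = c(1, 41), end = c(40, 100), rate = c(50, 1))
  segAe <- data.frame(start = c(1, 31), end = c(30, 100), rate = c(30, 1))
  ext <- selectTraces(traceExt, segDe, segAe, 1)
  expect_equal(ext$accepted, base$accepted)
  expect_equal(ext$fretWindow, base$fretWindow)
})

test_that("selected FRET windows track true acceptor bleach times", {
  spec <- egfrMixtureSpec("30% POPS -EGF")
  tc <- TcspcSpec(backgroundFraction = 0.02)
  mol <- MoleculeSim(acceptorBleachTime = 8, donorBleachTime = 12)
  sim <- simulateCondition(spec, "30% POPS -EGF", 40, mol, tc, seed = 31)
  nOk <- 0L; nAcc <- 0L
  for (i in seq_along(sim$streams)) {
    tr <- binPhotons(sim$streams[[i]], 0.1)
    if (length(tr) < 2) next
    segD <- detectChangepoints(tr@countsDonor, seed = 1000 + i)
    segA <- detectChangepoints(tr@countsAcceptor, seed = 2000 + i)
    sel <- selectTraces(tr, segD, segA, background = 1)
    if (!sel$accepted) next
    nAcc <- nAcc + 1L
    trueEnd <- sim$truth$acceptor_bleach_s[i]
    nOk <- nOk + (abs(sel$fretWindow[2] - trueEnd) <= 0.1)
  }
  expect_gt(nAcc, 20)
  expect_gte(nOk / nAcc, 0.9)
})
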