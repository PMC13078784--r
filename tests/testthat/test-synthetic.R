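test_that("mixture sampler honours weights, positivity and seeding", {
  one <- MixtureSpec(means = 2.0, sigmas = 0, weights = 1)
  expect_equal(sampleMixtureLifetimes(one, "condition1", 5, seed = 1),
               rep(2.0, 5))

  spec <- MixtureSpec(c(1.3, 2.7), c(0.35, 0.67),
                      list(mix = c(0.25, 0.75)))
  x <- sampleMixtureLifetimes(spec, "mix", 1e5, seed = 42)
  expect_true(all(x > 0))
  m <- 0.25 * 1.3 + 0.75 * 2.7
  v <- 0.25 * (0.35^2 + 1.3^2) + 0.75 * (0.67^2 + 2.7^2) - m^2
  expect_lt(abs(mean(x) - m), 3 * sqrt(v / 1e5) + 0.002)

  expect_identical(sampleMixtureLifetimes(spec, "mix", 100, seed = 7),
                   sampleMixtureLifetimes(spec, "mix", 100, seed = 7))
  expect_error(sampleMixtureLifetimes(spec, "nope", 10), "unknown condition")
})

test_that("sampled mixture matches its law (chi-square on CDF bins)", {
  spec <- MixtureSpec(c(1.3, 2.7), c(0.35, 0.67), list(mix = c(0.25, 0.75)))
  x <- sampleMixtureLifetimes(spec, "mix", 1e5, seed = 11)
  breaks <- c(-Inf, seq(0.5, 4.5, by = 0.25), Inf)
  pmix <- function(q) 0.25 * pnorm(q, 1.3, 0.35) + 0.75 * pnorm(q, 2.7, 0.67)
  p <- diff(pmix(breaks)) / (1 - pmix(0))   # positivity truncation
  obs <- table(cut(x, breaks))
  keep <- p > 1e-6
  expect_gt(chisq.test(as.numeric(obs[keep]), p = p[keep] / sum(p[keep]))$p.value,
            0.01)
})

test_that("photon streams follow the staged Poisson/decay model", {
  tc <- TcspcSpec(backgroundFraction = 0)
  silent <- MoleculeSim(donorRateFret = 0, donorRatePostbleach = 0,
                        acceptorRate = 0, backgroundRate = 0)
  expect_length(simulatePhotonStream(silent, tc, 5, seed = 1), 0)
  expect_error(simulatePhotonStream(silent, tc, -1), "duration")

  mol <- MoleculeSim(donorRateFret = 500, acceptorRate = 0,
                     backgroundRate = 0, acceptorBleachTime = 4,
                     donorBleachTime = 4 + 1e-9)
  s <- simulatePhotonStream(mol, tc, 10, seed = 2)
  nFret <- sum(channels(s) == "donor" & macrotimes(s) < 4)
  expect_lt(abs(nFret - 2000), 3 * sqrt(2000))
  expect_false(is.unsorted(macrotimes(s)))
  expect_true(all(nanotimes(s) >= 0 & nanotimes(s) <= tc@window))

  # delta IRF at zero: nanotime mean is the truncated-exponential mean
  tc0 <- TcspcSpec(irfMean = 0, irfSigma = 0, backgroundFraction = 0)
  mol2 <- MoleculeSim(donorRateFret = 2000, acceptorRate = 0,
                      backgroundRate = 0, acceptorBleachTime = 50,
                      donorBleachTime = 50.1, lifetimeFret = 2)
  s2 <- simulatePhotonStream(mol2, tc0, 10, seed = 3)
  nt <- nanotimes(s2)[channels(s2) == "donor"]
  W <- tc0@window
  truncMean <- 2 - W / (exp(W / 2) - 1)
  expect_lt(abs(mean(nt) - truncMean), 3 * sd(nt) / sqrt(length(nt)))
})

test_that("inter-photon intervals within a stage are exponential", {
  tc <- TcspcSpec()
  mol <- MoleculeSim(donorRateFret = 1500, acceptorRate = 0,
                     backgroundRate = 0, acceptorBleachTime = 100,
                     donorBleachTime = 101)
  s <- simulatePhotonStream(mol, tc, 10, seed = 4)
  gaps <- diff(macrotimes(s)[channels(s) == "donor"])
  expect_gt(length(gaps), 1e4)
  expect_gt(suppressWarnings(ks.test(gaps, "pexp", 1500))$p.value, 0.01)
})

test_that("nanotime law matches the analytic IRF (x) truncated exponential", {
  tc <- TcspcSpec(irfMean = 2, irfSigma = 0.15, backgroundFraction = 0.05)
  mol <- MoleculeSim(donorRateFret = 1e5, acceptorRate = 0,
                     backgroundRate = 0, acceptorBleachTime = 20,
                     donorBleachTime = 21, lifetimeFret = 2.7)
  s <- simulatePhotonStream(mol, tc, 10, seed = 5)
  nt <- nanotimes(s)[channels(s) == "donor"]
  expect_gt(length(nt), 9e5)
  breaks <- seq(0, tc@window, length.out = 101)
  centres <- (breaks[-1] + breaks[-101]) / 2
  pHat <- tabulate(findInterval(nt, breaks, rightmost.closed = TRUE), 100)
  pHat <- pHat / sum(pHat)
  pRef <- oracleDecayDensity(centres, 2.7, 2, 0.15, tc@window, 0.05)
  pRef <- pRef / sum(pRef)
  kl <- sum(ifelse(pHat > 0, pHat * log(pHat / pRef), 0))
  expect_lt(kl, 1e-3)
})

test_that("Langevin windows reach the biased stationary law", {
  flat <- function(x) 0 * x
  w <- simulateLangevinCV(flat, data.frame(center = 0, springK = 1),
                          nSteps = 1e5, stepSize = 0.05, seed = 8)[[1]]
  expect_lt(abs(var(cvSeries(w)) - 1), 0.05)

  free <- simulateLangevinCV(flat, data.frame(center = 0, springK = 0),
                             nSteps = 2e4, stepSize = 0.05, seed = 8)[[1]]
  x <- cvSeries(free)
  expect_gt(var(x[10001:20000]), var(x[1:10000]))

  again <- simulateLangevinCV(flat, data.frame(center = 0, springK = 1),
                              nSteps = 100, stepSize = 0.05, seed = 9)
  again2 <- simulateLangevinCV(flat, data.frame(center = 0, springK = 1),
                               nSteps = 100, stepSize = 0.05, seed = 9)
  expect_identical(cvSeries(again[[1]]), cvSeries(again2[[1]]))
  expect_error(simulateLangevinCV(flat, data.frame(center = 0, springK = 1),
                                  nSteps = 0), "nSteps")
})

test_that("coarse-grained frames respect the box and labels", {
  prot <- data.frame(residueId = c(721L, 1186L), x = c(10, 20), y = c(10, 20),
                     z = c(10, 20))
  f0 <- makeCGFrame(0, prot, box = c(50, 50, 50), seed = 1)
  expect_equal(nrow(beadCoords(f0)), 2)
  expect_true(all(f0@kind == "protein"))

  f <- makeCGFrame(1000, NULL, box = c(100, 100, 100), seed = 2)
  expect_equal(nrow(beadCoords(f)), 1000)
  expect_true(all(beadCoords(f) >= 0 & beadCoords(f) <= 100))
  # density ~ 1e-3 beads/A^3 by construction
  expect_equal(1000 / prod(f@box), 1e-3)

  f2 <- makeCGFrame(1000, NULL, box = c(100, 100, 100), seed = 2)
  expect_identical(beadCoords(f), beadCoords(f2))

  bad <- data.frame(residueId = 1L, x = 60, y = 10, z = 10)
  expect_error(makeCGFrame(0, bad, box = c(50, 50, 50)), "outside box")
})
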