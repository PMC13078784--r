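test_that("contact counting uses a strict minimum-image cutoff", {
  mk <- function(lipidXyz, siteXyz, box = c(100, 100, 100), periodic = TRUE) {
    coords <- rbind(lipidXyz, siteXyz)
    TrajectoryFrame(coords = coords,
                    kind = c(rep("lipid", nrow(lipidXyz)),
                             rep("protein", nrow(siteXyz))),
                    residueId = c(rep(NA_integer_, nrow(lipidXyz)),
                                  rep(721L, nrow(siteXyz))),
                    box = box, periodic = periodic)
  }
  near <- mk(matrix(c(10, 10, 10), 1), matrix(c(25.9, 10, 10), 1))
  far <- mk(matrix(c(10, 10, 10), 1), matrix(c(26.1, 10, 10), 1))
  expect_equal(countAtpSiteContacts(near, 721, 16), 1)
  expect_equal(countAtpSiteContacts(far, 721, 16), 0)

  wrap <- mk(matrix(c(95, 10, 10), 1), matrix(c(5, 10, 10), 1))
  expect_equal(countAtpSiteContacts(wrap, 721, 16), 1)   # image distance 10 A

  expect_error(countAtpSiteContacts(mk(matrix(c(1, 1, 1), 1),
                                       matrix(numeric(), 0, 3)), 721),
               "residue labels")
})

test_that("contact counts equal the brute-force pair scan", {
  set.seed(21)
  box <- c(60, 60, 60)
  for (i in 1:10) {
    prot <- randomProteinBeads(12, box, c(atpSiteResidues(), 721L, 1186L))
    f <- makeCGFrame(80, prot, box, seed = i)
    expect_identical(countAtpSiteContacts(f),
                     oracleContactCount(f, atpSiteResidues(), 16))
  }
})

test_that("contact counts are translation invariant (periodic)", {
  set.seed(22)
  box <- c(50, 50, 50)
  prot <- randomProteinBeads(10, box, atpSiteResidues())
  f <- makeCGFrame(60, prot, box, seed = 4)
  n0 <- countAtpSiteContacts(f)
  shifted <- f
  shifted@coords <- (f@coords + rep(c(13.7, -8.1, 22.9), each = nrow(f@coords))) %% rep(box, each = nrow(f@coords))
  expect_identical(countAtpSiteContacts(shifted), n0)
  imaged <- f
  imaged@coords[3, ] <- imaged@coords[3, ] + box   # one bead moved by a box vector
  expect_identical(countAtpSiteContacts(imaged), n0)
})

test_that("residue distances use centroids, images and nm units", {
  f <- TrajectoryFrame(coords = rbind(c(0, 0, 0), c(30, 40, 0)),
                       kind = c("protein", "protein"),
                       residueId = c(721L, 1186L),
                       box = c(200, 200, 200), periodic = FALSE)
  expect_equal(residueDistance(f), 5.0)

  same <- TrajectoryFrame(coords = rbind(c(7, 7, 7), c(7, 7, 7)),
                          kind = c("protein", "protein"),
                          residueId = c(721L, 1186L),
                          box = c(50, 50, 50))
  expect_equal(residueDistance(same), 0)

  set.seed(23)
  box <- c(30, 30, 30)
  for (i in 1:20) {
    a <- runif(3, 0, 30); b <- runif(3, 0, 30)
    f2 <- TrajectoryFrame(coords = rbind(a, b),
                          kind = c("protein", "protein"),
                          residueId = c(721L, 1186L), box = box)
    expect_equal(residueDistance(f2), oracleImageDistance(a, b, box) / 10,
                 tolerance = 1e-12)
  }
  expect_error(residueDistance(same, 721, 999), "residue 999")
})

test_that("block statistics partition contiguously with remainder to last", {
  bs <- blockStats(1:6, 3, "mean")
  expect_equal(bs$blocks, c(1.5, 3.5, 5.5))
  expect_equal(bs$min, 1.5)
  expect_equal(bs$max, 5.5)
  expect_equal(bs$value, 3.5)

  const <- blockStats(rep(4, 9), 3, "median")
  expect_equal(const$min, const$max)

  set.seed(24)
  x <- rnorm(100)
  bs2 <- blockStats(x, 3, "median")
  expect_equal(bs2$blocks,
               c(median(x[1:33]), median(x[34:66]), median(x[67:100])))
  expect_error(blockStats(1:2, 3), "shorter")
})

test_that("zero-bias WHAM reproduces pooled statistics exactly", {
  set.seed(25)
  x <- rnorm(4000)
  w <- UmbrellaWindow(0, 0, x)
  res <- whamReweight(list(w), bins = 30, observable = function(v) v^2)
  expect_equal(res$observableMean, mean(x^2), tolerance = 1e-12)
  expect_equal(res$iterations, 1L)
  h <- tabulate(findInterval(x, seq(min(x), max(x), length.out = 31),
                             rightmost.closed = TRUE), 30)
  expect_equal(res$probability, h / sum(h), tolerance = 1e-12)
  # PMF equals -log(histogram) up to its minimum shift
  ref <- -log(h / sum(h)); ref <- ref - min(ref[h > 0])
  expect_equal(res$pmf$pmf[h > 0], ref[h > 0], tolerance = 1e-12)
})

test_that("duplicating all samples leaves the WHAM profile unchanged", {
  set.seed(26)
  wins <- simulateLangevinCV(function(x) 0.5 * x^2,
                             data.frame(center = c(-1, 0, 1), springK = 2),
                             nSteps = 4000, stepSize = 0.02, seed = 5)
  doubled <- lapply(wins, function(w)
    UmbrellaWindow(w@center, w@springK, c(cvSeries(w), cvSeries(w))))
  breaks <- seq(-4, 4, length.out = 41)
  r1 <- whamReweight(wins, bins = breaks)
  r2 <- whamReweight(doubled, bins = breaks)
  expect_equal(r1$probability, r2$probability, tolerance = 1e-6)
})

test_that("a constant observable reweights to itself", {
  set.seed(27)
  wins <- simulateLangevinCV(function(x) 0.5 * x^2,
                             data.frame(center = c(-1, 1), springK = 2),
                             nSteps = 3000, stepSize = 0.02, seed = 6)
  res <- whamReweight(wins, bins = 25, observable = function(x) rep(7, length(x)))
  expect_equal(res$observableMean, 7, tolerance = 1e-12)
})

test_that("non-overlapping windows fail with a diagnostic", {
  w1 <- UmbrellaWindow(-50, 100, rnorm(500, -50, 0.1))
  w2 <- UmbrellaWindow(50, 100, rnorm(500, 50, 0.1))
  expect_error(whamReweight(list(w1, w2), bins = 40), "do not overlap")
})
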