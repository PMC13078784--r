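test_that("a one-component fit reduces to the sample moments", {
  set.seed(15)
  x <- rnorm(2000, 2, 0.3)
  m <- fitGlobalMixture(list(c1 = x), k = 1, nStarts = 3, seed = 1)
  expect_lt(abs(componentMeans(m) - mean(x)), 1e-6)
  expect_lt(abs(componentSigmas(m) - sd(x) * sqrt(1999 / 2000)), 1e-6)
  expect_equal(unname(componentWeights(m)[1, 1]), 1)
})

test_that("shared components are recovered across conditions", {
  spec <- MixtureSpec(c(1.3, 2.7), c(0.35, 0.67),
                      list(a = c(0.40, 0.60), b = c(0.26, 0.74),
                           c = c(0.09, 0.91), d = c(0.04, 0.96)))
  sets <- lapply(conditionNames(spec), function(cc)
    sampleMixtureLifetimes(spec, cc, 1500, seed = 100 + match(cc, conditionNames(spec))))
  names(sets) <- conditionNames(spec)
  m <- fitGlobalMixture(sets, 2, nStarts = 10, seed = 2)
  expect_true(m@converged)
  expect_lt(max(abs(componentMeans(m) - c(1.3, 2.7))), 0.08)
  expect_lt(max(abs(componentWeights(m)[, 2] - c(0.60, 0.74, 0.91, 0.96))),
            0.05)
})

test_that("permuting conditions permutes only the weight rows", {
  spec <- MixtureSpec(c(1.3, 2.7), c(0.35, 0.67),
                      list(a = c(0.4, 0.6), b = c(0.1, 0.9)))
  sets <- list(a = sampleMixtureLifetimes(spec, "a", 800, seed = 1),
               b = sampleMixtureLifetimes(spec, "b", 800, seed = 2))
  m1 <- fitGlobalMixture(sets, 2, nStarts = 5, seed = 3)
  m2 <- fitGlobalMixture(rev(sets), 2, nStarts = 5, seed = 3)
  expect_equal(componentMeans(m1), componentMeans(m2), tolerance = 1e-4)
  expect_equal(componentWeights(m1)["a", ], componentWeights(m2)["a", ],
               tolerance = 1e-3)
  expect_equal(componentWeights(m1)["b", ], componentWeights(m2)["b", ],
               tolerance = 1e-3)
})

test_that("BIC uses the shared-parameter count and total bunch number", {
  set.seed(16)
  sets <- list(a = rnorm(300, 2, 0.3), b = rnorm(300, 2.2, 0.3))
  m <- fitGlobalMixture(sets, 2, nStarts = 5, seed = 4)
  p <- 2 * 2 + (2 - 1) * 2
  expect_equal(BIC(m), -2 * m@logLik + p * log(600))
  expect_equal(attr(logLik(m), "df"), p)
  m1 <- fitGlobalMixture(sets, 1, nStarts = 2, seed = 4)
  p1 <- 2 * 1 + (1 - 1) * 2
  expect_equal(BIC(m1) - BIC(m),
               -2 * (m1@logLik - m@logLik) + (p1 - p) * log(600))
})

test_that("selectK picks the lowest BIC with ties toward smaller k", {
  set.seed(17)
  sets <- list(a = rnorm(400, 2, 0.3))
  m1 <- fitGlobalMixture(sets, 1, nStarts = 2, seed = 5)
  m2 <- fitGlobalMixture(sets, 2, nStarts = 5, seed = 5)
  expect_equal(selectK(list(m1, m2))@k, 1L)   # single Gaussian data

  m2tie <- m2; m2tie@bic <- m1@bic
  expect_equal(selectK(list(m2tie, m1))@k, 1L)

  other <- fitGlobalMixture(list(a = rnorm(400, 2, 0.3)), 1, nStarts = 2,
                            seed = 6)
  expect_error(selectK(list(m1, other)), "differing data")
})

test_that("Ashman's D matches its closed form and scale equivariance", {
  expect_equal(ashmanD(c(2, 2), c(0.5, 0.5))[1, 2], 0)
  expect_equal(ashmanD(c(0, 2), c(1, 1))[1, 2], 2)
  expect_equal(ashmanD(c(1.3, 2.7), c(0.35, 0.67))[1, 2], 2.6192,
               tolerance = 1e-4)
  D <- ashmanD(c(1, 2, 4), c(0.3, 0.4, 0.8))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 3))
  expect_equal(ashmanD(3 * c(1, 2, 4), 3 * c(0.3, 0.4, 0.8)), D)
})

test_that("EGF amplitude changes difference the open-component weights", {
  w <- rbind("m" = c(0.31, 0.69), "p" = c(0.09, 0.91))
  se <- rbind("m" = c(0.01, 0.01), "p" = c(0.02, 0.02))
  mdl <- new("GaussianMixtureModel", k = 2L, means = c(1.3, 2.7),
             sigmas = c(0.35, 0.67), weights = w, weightSE = se,
             logLik = -1, n = 100L, bic = 0, converged = TRUE,
             fingerprint = c(1, 1, 1))
  out <- egfAmplitudeChange(mdl, data.frame(minus = "m", plus = "p"))
  expect_equal(out$delta_pct, 22)
  expect_equal(out$se_pct, sqrt(1^2 + 2^2))
  flip <- egfAmplitudeChange(mdl, data.frame(minus = "p", plus = "m"))
  expect_equal(flip$delta_pct, -22)
  same <- egfAmplitudeChange(mdl, data.frame(minus = "m", plus = "m"))
  expect_equal(same$delta_pct, 0)
  expect_error(egfAmplitudeChange(mdl, data.frame(minus = "m", plus = "x")),
               "not in model")
})

test_that("one-way ANOVA behaves classically", {
  x <- c(1, 2, 3, 4)
  out <- anovaPair(x, x)
  expect_equal(out$F, 0)
  expect_equal(out$p, 1)
  expect_false(out$significant)

  set.seed(18)
  a <- rnorm(30); b <- rnorm(30, 1)
  r1 <- anovaPair(a, b)
  r2 <- anovaPair(a + 100, b + 100)
  expect_equal(r1$F, r2$F, tolerance = 1e-8)
  expect_error(anovaPair(a), "at least two groups")

  # cross-check against the aov route
  ref <- summary(aov(c(a, b) ~ factor(rep(1:2, each = 30))))[[1]]
  expect_equal(r1$F, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(r1$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("refitting data simulated from a fit recovers its parameters", {
  spec <- MixtureSpec(c(1.3, 2.7), c(0.35, 0.67), list(a = c(0.3, 0.7)))
  x <- sampleMixtureLifetimes(spec, "a", 3000, seed = 19)
  m <- fitGlobalMixture(list(a = x), 2, nStarts = 10, seed = 7)
  respec <- MixtureSpec(componentMeans(m), componentSigmas(m),
                        list(a = componentWeights(m)[1, ]))
  y <- sampleMixtureLifetimes(respec, "a", 3000, seed = 20)
  m2 <- fitGlobalMixture(list(a = y), 2, nStarts = 10, seed = 8)
  expect_lt(max(abs(componentMeans(m2) - componentMeans(m))), 0.1)
  expect_lt(abs(componentWeights(m2)[1, 2] - componentWeights(m)[1, 2]), 0.05)
})
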