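## Global shared-component Gaussian mixture fitting across conditions, BIC
## model selection, Ashman's D separation, EGF amplitude changes and ANOVA.

dataFingerprint <- function(lifetimeSets) {
  x <- unlist(lifetimeSets, use.names = FALSE)
  c(length(x), sum(x), sum(x^2))
}

## One EM run from a given start. Shared means/sigmas across conditions,
## free per-condition weights; the joint log-likelihood is checked to be
## non-decreasing at every iteration.
emRun <- function(sets, k, means, sigmas, weights, maxIter, tol, sigmaFloor) {
  C <- length(sets)
  prev <- -Inf
  converged <- FALSE
  for (iter in seq_len(maxIter)) {
    num <- numeric(k); den <- numeric(k); ssq <- numeric(k)
    ll <- 0
    respList <- vector("list", C)
    for (ci in seq_len(C)) {
      x <- sets[[ci]]
      dens <- vapply(seq_len(k), function(j)
        weights[ci, j] * stats::dnorm(x, means[j], sigmas[j]), numeric(length(x)))
      dens <- matrix(dens, ncol = k)
      rs <- rowSums(dens)
      rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
      ll <- ll + sum(log(rs))
      respList[[ci]] <- dens / rs
    }
    if (ll < prev - 1e-6 * abs(prev) - 1e-8)
      stop("EM log-likelihood decreased; numerical failure")
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      break
    }
    prev <- ll
    for (ci in seq_len(C)) {
      r <- respList[[ci]]; x <- sets[[ci]]
      weights[ci, ] <- colMeans(r)
      num <- num + colSums(r * x)
      den <- den + colSums(r)
    }
    means <- num / den
    for (ci in seq_len(C)) {
      r <- respList[[ci]]; x <- sets[[ci]]
      ssq <- ssq + colSums(r * (outer(x, means, "-"))^2)
    }
    sigmas <- pmax(sqrt(ssq / den), sigmaFloor)
  }
  list(means = means, sigmas = sigmas, weights = weights, logLik = ll,
       converged = converged)
}

#' Global shared-component Gaussian mixture fit
#'
#' Maximizes the joint likelihood of per-bunch lifetimes from several
#' conditions under a Gaussian mixture whose peak positions and widths are
#' shared between conditions while the relative amplitudes are free per
#' condition. Fitting is expectation-maximization with multiple seeded
#' starts; components are returned sorted by mean.
#'
#' @param lifetimeSets named list of per-condition lifetime vectors (each of
#'   length `>= 10 k`).
#' @param k number of components (1-3 in the intended workflow).
#' @param nStarts number of seeded EM starts; the best likelihood wins.
#' @param seed integer seed controlling the starts.
#' @param maxIter,tol EM iteration cap and relative log-likelihood tolerance.
#' @param sigmaFloor lower bound on component widths (ns), guarding against
#'   degenerate collapse.
#' @return A [GaussianMixtureModel-class].
#' @export
fitGlobalMixture <- function(lifetimeSets, k, nStarts = 20L, seed = 1L,
                             maxIter = 500L, tol = 1e-8, sigmaFloor = 0.01) {
  stopifnot2(is.list(lifetimeSets) && length(lifetimeSets) >= 1,
             "lifetimeSets must be a non-empty list")
  if (is.null(names(lifetimeSets)))
    names(lifetimeSets) <- paste0("condition", seq_along(lifetimeSets))
  lens <- lengths(lifetimeSets)
  stopifnot2(all(lens >= 10 * k), "each condition needs at least 10*k values")
  k <- as.integer(k)
  C <- length(lifetimeSets)
  pooled <- unlist(lifetimeSets, use.names = FALSE)
  n <- length(pooled)
  sdP <- stats::sd(pooled)

  best <- NULL
  for (s in seq_len(nStarts)) {
    start <- withLocalSeed(subSeed(seed, s), {
      qs <- stats::quantile(pooled, probs = (seq_len(k) - 0.5) / k,
                            names = FALSE)
      list(means = sort(qs + if (s > 1) stats::rnorm(k, 0, sdP / 2) else 0),
           sigmas = rep(max(sdP / k, 2 * sigmaFloor), k),
           weights = {
             w <- matrix(stats::rgamma(C * k, shape = if (s > 1) 2 else 1e6),
                         nrow = C)
             w / rowSums(w)
           })
    })
    fit <- tryCatch(
      emRun(lifetimeSets, k, start$means, start$sigmas, start$weights,
            maxIter, tol, sigmaFloor),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$logLik > best$logLik))
      best <- fit
  }
  if (is.null(best)) stop("all EM starts failed")

  ord <- order(best$means)
  means <- best$means[ord]
  ## enforce strictly increasing means for the container (exact ties are a
  ## degenerate fit; nudge by the floor)
  if (k >= 2) for (j in 2:k) if (means[j] <= means[j - 1])
    means[j] <- means[j - 1] + 1e-9
  sigmas <- best$sigmas[ord]
  weights <- matrix(best$weights[, ord], nrow = C,
                    dimnames = list(names(lifetimeSets), NULL))

  ## Per-condition amplitude SEs from the observed information of the
  ## condition likelihood in its own (k-1) free weights, shared shapes held
  ## fixed (multinomial-logit-free parameterization, delta method on the
  ## final component).
  weightSE <- matrix(NA_real_, C, k, dimnames = dimnames(weights))
  for (ci in seq_len(C)) {
    x <- lifetimeSets[[ci]]
    phi <- vapply(seq_len(k), function(j) stats::dnorm(x, means[j], sigmas[j]),
                  numeric(length(x)))
    phi <- matrix(phi, ncol = k)
    mix <- as.numeric(phi %*% weights[ci, ])
    if (k >= 2) {
      d <- sweep(phi[, -k, drop = FALSE], 1, phi[, k], "-") / mix
      info <- crossprod(d)
      v <- tryCatch(solve(info), error = function(e)
        matrix(NA_real_, k - 1, k - 1))
      se <- sqrt(pmax(diag(v), 0))
      weightSE[ci, seq_len(k - 1)] <- se
      weightSE[ci, k] <- sqrt(pmax(sum(v), 0))
    } else weightSE[ci, 1] <- 0
  }

  p <- 2L * k + (k - 1L) * C
  new("GaussianMixtureModel", k = k, means = means, sigmas = sigmas,
      weights = weights, weightSE = weightSE, logLik = best$logLik,
      n = as.integer(n), bic = -2 * best$logLik + p * log(n),
      converged = best$converged, fingerprint = dataFingerprint(lifetimeSets))
}

#' Select the component count by BIC
#'
#' Returns the minimum-BIC model among candidates fitted on identical data;
#' ties break toward the smaller component count.
#'
#' @param models list of [GaussianMixtureModel-class] objects.
#' @return The selected model.
#' @export
selectK <- function(models) {
  stopifnot2(length(models) >= 2, "need at least two candidate models")
  fps <- vapply(models, function(m) m@fingerprint, numeric(3))
  if (any(abs(fps - fps[, 1]) > 1e-6 * (abs(fps[, 1]) + 1)))
    stop("candidate models were fitted on differing data")
  bics <- vapply(models, BIC, numeric(1))
  ks <- vapply(models, function(m) m@k, integer(1))
  ord <- order(bics, ks)
  models[[ord[1]]]
}

#' Ashman's D separation matrix
#'
#' `D_ij = |mu_i - mu_j| / sqrt((sigma_i^2 + sigma_j^2) / 2)`; a score above
#' 2 indicates good separation between two Gaussian components.
#'
#' @param means,sigmas component parameters, or pass a fitted
#'   [GaussianMixtureModel-class] as `means`.
#' @return Symmetric k x k matrix with zero diagonal.
#' @export
ashmanD <- function(means, sigmas = NULL) {
  if (is(means, "GaussianMixtureModel")) {
    sigmas <- means@sigmas
    means <- means@means
  }
  k <- length(means)
  mu <- outer(means, means, function(a, b) abs(a - b))
  sg <- sqrt(0.5 * outer(sigmas^2, sigmas^2, "+"))
  D <- mu / sg
  diag(D) <- 0
  D
}

#' EGF-induced amplitude change of the open conformation
#'
#' The open conformation is the largest-mean component (distance increases
#' with donor lifetime). For each -EGF/+EGF condition pair the change in its
#' amplitude is reported in percentage points, with uncertainties propagated
#' from the fit's observed-information weight standard errors.
#'
#' @param model a [GaussianMixtureModel-class].
#' @param pairs data.frame with columns `minus` and `plus` naming the
#'   paired conditions (and optionally `label`).
#' @return data.frame: label, open_minus_pct, open_plus_pct, delta_pct,
#'   se_pct.
#' @export
egfAmplitudeChange <- function(model, pairs) {
  pairs <- as.data.frame(pairs)
  conds <- rownames(model@weights)
  missing <- setdiff(c(pairs$minus, pairs$plus), conds)
  if (length(missing))
    stop("condition(s) not in model: ", paste(missing, collapse = ", "))
  open <- model@k   # largest mean after sorting
  lab <- if ("label" %in% names(pairs)) pairs$label else pairs$minus
  wm <- model@weights[pairs$minus, open] * 100
  wp <- model@weights[pairs$plus, open] * 100
  sem <- model@weightSE[pairs$minus, open] * 100
  sep <- model@weightSE[pairs$plus, open] * 100
  data.frame(label = lab, open_minus_pct = wm, open_plus_pct = wp,
             delta_pct = wp - wm, se_pct = sqrt(sem^2 + sep^2),
             row.names = NULL)
}

#' Classical one-way ANOVA between condition lifetime sets
#'
#' Equal-variance one-way analysis of variance across two or more groups,
#' with the significance call at `p <= 0.001`.
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @param alpha significance threshold.
#' @return List: `F`, `p`, `df` (between, within), `significant`.
#' @export
anovaPair <- function(..., alpha = 0.001) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  stopifnot2(length(groups) >= 2, "need at least two groups")
  stopifnot2(all(lengths(groups) >= 2), "each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  Fv <- unname(ow$statistic)
  p <- unname(ow$p.value)
  if (!is.finite(Fv)) { Fv <- 0; p <- 1 }   # identical groups: no variance
  list(F = Fv, p = p, df = unname(ow$parameter), significant = p <= alpha)
}
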