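#' @name accessors
#' @title Accessors for memfret classes
#' @description Slot accessors for the core S4 containers; user code should
#'   use these rather than `@`.
#' @param x,object a memfret S4 object.
#' @return The corresponding slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("macrotimes", function(x) standardGeneric("macrotimes"))
#' @rdname accessors
#' @export
setMethod("macrotimes", "PhotonStream", function(x) x@macrotime)

#' @rdname accessors
#' @export
setGeneric("nanotimes", function(x) standardGeneric("nanotimes"))
#' @rdname accessors
#' @export
setMethod("nanotimes", "PhotonStream", function(x) x@nanotime)

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))
#' @rdname accessors
#' @export
setMethod("channels", "PhotonStream", function(x) x@channel)

#' @rdname accessors
#' @export
setGeneric("componentMeans", function(x) standardGeneric("componentMeans"))
#' @rdname accessors
#' @export
setMethod("componentMeans", "GaussianMixtureModel", function(x) x@means)
#' @rdname accessors
#' @export
setMethod("componentMeans", "MixtureSpec", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("componentSigmas", function(x) standardGeneric("componentSigmas"))
#' @rdname accessors
#' @export
setMethod("componentSigmas", "GaussianMixtureModel", function(x) x@sigmas)
#' @rdname accessors
#' @export
setMethod("componentSigmas", "MixtureSpec", function(x) x@sigmas)

#' @rdname accessors
#' @export
setGeneric("componentWeights", function(x) standardGeneric("componentWeights"))
#' @rdname accessors
#' @export
setMethod("componentWeights", "GaussianMixtureModel", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("componentWeights", "MixtureSpec", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("conditionNames", function(x) standardGeneric("conditionNames"))
#' @rdname accessors
#' @export
setMethod("conditionNames", "GaussianMixtureModel", function(x) rownames(x@weights))
#' @rdname accessors
#' @export
setMethod("conditionNames", "MixtureSpec", function(x) rownames(x@weights))

#' @rdname accessors
#' @export
setGeneric("beadCoords", function(x) standardGeneric("beadCoords"))
#' @rdname accessors
#' @export
setMethod("beadCoords", "TrajectoryFrame", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("cvSeries", function(x) standardGeneric("cvSeries"))
#' @rdname accessors
#' @export
setMethod("cvSeries", "UmbrellaWindow", function(x) x@cv)

#' @importFrom stats logLik
#' @export
#' @rdname accessors
logLik.GaussianMixtureModel <- function(object, ...) {
  structure(object@logLik, df = 2L * object@k + (object@k - 1L) * nrow(object@weights),
            nobs = object@n, class = "logLik")
}

#' Bayesian Information Criterion of a fitted mixture
#'
#' `BIC = -2 log L + p log n` with `p = 2k + (k - 1) * nConditions` free
#' parameters (shared means and widths plus per-condition amplitudes) and `n`
#' the total number of photon bunches across all conditions. A lower BIC
#' indicates a statistically better model.
#'
#' @param object a [GaussianMixtureModel-class] object.
#' @param ... ignored.
#' @return The BIC value (numeric scalar).
#' @importFrom stats BIC
#' @export
BIC.GaussianMixtureModel <- function(object, ...) object@bic
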