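#' @import methods
NULL

#' Taxon locations on the hyperboloid
#'
#' An ordered set of `n` taxon embedding locations on the `d`-dimensional
#' hyperboloid, stored in ambient coordinates `u = (u0, ..., ud)` with Lorentz
#' self-product `<u,u> = -1` and `u0 >= 1`. The continuous encoding of a tree:
#' pairwise hyperbolic distances between these points are what soft-NJ decodes.
#'
#' @slot points numeric matrix, `n x (d+1)`, one row per taxon.
#' @slot labels character vector of `n` unique taxon labels.
#' @export
setClass("HyperboloidEmbedding",
  representation(points = "matrix", labels = "character"),
  validity = function(object) {
    pts <- object@points
    n <- nrow(pts)
    msg <- character()
    if (n < 3) msg <- c(msg, "need at least 3 taxa")
    if (length(object@labels) != n) msg <- c(msg, "labels must match rows")
    if (anyDuplicated(object@labels)) msg <- c(msg, "labels must be unique")
    if (ncol(pts) < 3) msg <- c(msg, "ambient dimension must be >= 3 (d >= 2)")
    if (n >= 1) {
      sp <- -pts[, 1]^2 + rowSums(pts[, -1, drop = FALSE]^2)
      if (any(abs(sp + 1) > 1e-8))
        msg <- c(msg, "points must satisfy the hyperboloid constraint <u,u> = -1")
      if (any(pts[, 1] < 1 - 1e-12)) msg <- c(msg, "time coordinate u0 must be >= 1")
    }
    if (length(msg)) msg else TRUE
  }
)

#' @param points,labels see slots.
#' @rdname HyperboloidEmbedding-class
#' @export
HyperboloidEmbedding <- function(points, labels = rownames(points)) {
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(points)))
  new("HyperboloidEmbedding", points = unname(as.matrix(points)),
      labels = as.character(labels))
}

#' @param object,x a `HyperboloidEmbedding`.
#' @rdname HyperboloidEmbedding-class
#' @export
setGeneric("embPoints", function(x) standardGeneric("embPoints"))
#' @rdname HyperboloidEmbedding-class
#' @export
setMethod("embPoints", "HyperboloidEmbedding", function(x) x@points)

#' @rdname HyperboloidEmbedding-class
#' @export
setGeneric("embLabels", function(x) standardGeneric("embLabels"))
#' @rdname HyperboloidEmbedding-class
#' @export
setMethod("embLabels", "HyperboloidEmbedding", function(x) x@labels)

#' @details `tangentCoords` returns the `n x d` unconstrained coordinates
#' (the ambient coordinates without `u0`); `projectToHyperboloid` inverts it.
#' @rdname HyperboloidEmbedding-class
#' @export
setGeneric("tangentCoords", function(x) standardGeneric("tangentCoords"))
#' @rdname HyperboloidEmbedding-class
#' @export
setMethod("tangentCoords", "HyperboloidEmbedding",
          function(x) x@points[, -1, drop = FALSE])

setMethod("show", "HyperboloidEmbedding", function(object) {
  cat(sprintf("HyperboloidEmbedding: %d taxa on H^%d\n",
              nrow(object@points), ncol(object@points) - 1L))
  cat("labels:", paste(utils::head(object@labels, 6), collapse = ", "),
      if (length(object@labels) > 6) "...", "\n")
})

#' Nucleotide substitution model
#'
#' JC69 or GTR. A GTR model has six exchangeability rates (order AC, AG, AT,
#' CG, CT, GT) constrained to the simplex and four equilibrium base
#' frequencies (order A, C, G, T) constrained to the simplex; JC69 fixes the
#' rates at 1/6 and the frequencies at 1/4.
#'
#' @slot kind `"JC69"` or `"GTR"`.
#' @slot rates numeric(6), non-negative, summing to one.
#' @slot freqs numeric(4), non-negative, summing to one.
#' @export
setClass("SubstModel",
  representation(kind = "character", rates = "numeric", freqs = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!object@kind %in% c("JC69", "GTR")) msg <- c(msg, "kind must be JC69 or GTR")
    if (length(object@rates) != 6 || any(object@rates < 0) ||
        abs(sum(object@rates) - 1) > 1e-8)
      msg <- c(msg, "rates must be a 6-simplex (non-negative, sum 1)")
    if (length(object@freqs) != 4 || any(object@freqs < 0) ||
        abs(sum(object@freqs) - 1) > 1e-8)
      msg <- c(msg, "freqs must be a 4-simplex (non-negative, sum 1)")
    if (object@kind == "JC69" &&
        (any(abs(object@rates - 1 / 6) > 1e-12) || any(abs(object@freqs - 1 / 4) > 1e-12)))
      msg <- c(msg, "JC69 fixes rates = 1/6 and freqs = 1/4")
    if (length(msg)) msg else TRUE
  }
)

#' @rdname SubstModel-class
#' @export
JC69 <- function() new("SubstModel", kind = "JC69",
                       rates = rep(1 / 6, 6), freqs = rep(1 / 4, 4))

#' @param rates,freqs GTR exchangeabilities (6) and equilibrium frequencies
#'   (4); normalized to sum to one.
#' @rdname SubstModel-class
#' @export
GTR <- function(rates = rep(1, 6), freqs = rep(1, 4)) {
  new("SubstModel", kind = "GTR", rates = rates / sum(rates),
      freqs = freqs / sum(freqs))
}

#' @param x a `SubstModel`.
#' @rdname SubstModel-class
#' @export
setGeneric("modelKind", function(x) standardGeneric("modelKind"))
#' @rdname SubstModel-class
#' @export
setMethod("modelKind", "SubstModel", function(x) x@kind)
#' @rdname SubstModel-class
#' @export
setGeneric("modelRates", function(x) standardGeneric("modelRates"))
#' @rdname SubstModel-class
#' @export
setMethod("modelRates", "SubstModel", function(x) x@rates)
#' @rdname SubstModel-class
#' @export
setGeneric("modelFreqs", function(x) standardGeneric("modelFreqs"))
#' @rdname SubstModel-class
#' @export
setMethod("modelFreqs", "SubstModel", function(x) x@freqs)

setMethod("show", "SubstModel", function(object) {
  cat(sprintf("SubstModel %s\n", object@kind))
  if (object@kind == "GTR") {
    cat("  rates:", paste(signif(object@rates, 4), collapse = " "), "\n")
    cat("  freqs:", paste(signif(object@freqs, 4), collapse = " "), "\n")
  }
})

#' Per-taxon projected-normal mixture over trees
#'
#' Variational family for Bayesian inference: a `K`-component mixture; each
#' component places an independent diagonal (mean-field) multivariate normal
#' in the tangent space `R^d` at the hyperboloid origin for every taxon.
#' Draws are projected onto the hyperboloid, converted to pairwise distances,
#' and decoded to a tree by soft-NJ, so the mixture encodes a distribution
#' over phylogenies.
#'
#' @slot K integer mixture size.
#' @slot logits numeric(K), mixture weights via softmax.
#' @slot mean array `K x n x d` of component means (tangent coordinates).
#' @slot logSigma array `K x n x d` of log standard deviations.
#' @slot labels character(n) taxon labels.
#' @slot kappa negative curvature used when decoding draws.
#' @export
setClass("VariationalParams",
  representation(K = "integer", logits = "numeric", mean = "array",
                 logSigma = "array", labels = "character", kappa = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@K < 1L) msg <- c(msg, "K must be >= 1")
    if (length(object@logits) != object@K) msg <- c(msg, "logits must have length K")
    dm <- dim(object@mean)
    if (length(dm) != 3 || dm[1] != object@K || dm[2] != length(object@labels))
      msg <- c(msg, "mean must be a K x n x d array")
    if (!identical(dim(object@logSigma), dm))
      msg <- c(msg, "logSigma must match dim(mean)")
    if (!(is.finite(object@kappa) && object@kappa < 0))
      msg <- c(msg, "kappa must be finite and negative")
    if (length(msg)) msg else TRUE
  }
)

#' @param x a `VariationalParams`.
#' @rdname VariationalParams-class
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))
#' @rdname VariationalParams-class
#' @export
setMethod("mixtureWeights", "VariationalParams", function(x) {
  w <- exp(x@logits - max(x@logits)); w / sum(w)
})

setMethod("show", "VariationalParams", function(object) {
  dm <- dim(object@mean)
  cat(sprintf("VariationalParams: K = %d components, %d taxa, d = %d, kappa = %g\n",
              object@K, dm[2], dm[3], object@kappa))
  cat("  weights:", paste(signif(mixtureWeights(object), 4), collapse = " "), "\n")
})
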