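#' Lorentz inner product
#'
#' `<u, v> = -u0 v0 + u1 v1 + ... + ud vd`, the bilinear form defining the
#' hyperboloid model of hyperbolic space. Accepts plain numeric vectors or
#' [dualSeed()] duals (derivatives propagate).
#'
#' @param u,v numeric or dual vectors of equal length (>= 2), ambient
#'   coordinates.
#' @return scalar (numeric or dual).
#' @examples
#' lorentzInner(c(1, 0, 0, 0), c(1, 0, 0, 0))  # -1
#' @export
lorentzInner <- function(u, v) {
  if (length(u) != length(v)) stop("dimension mismatch: length(u) != length(v)")
  if (length(u) < 2) stop("ambient vectors must have length >= 2")
  s <- sum(dIndex(u, -1L) * dIndex(v, -1L))
  s - dIndex(u, 1L) * dIndex(v, 1L)
}

.check_kappa <- function(kappa) {
  kv <- dualValue(kappa)
  if (!is.finite(kv) || kv >= 0) stop("curvature kappa must be finite and negative")
  invisible(kappa)
}

#' Hyperbolic distance on the hyperboloid
#'
#' `d_kappa(u, v) = arcosh(-<u,v>) / sqrt(-kappa)`. The `arcosh` argument is
#' clamped to `1 + 1e-9` from below: floating-point error can push `-<u,v>`
#' slightly under 1 for near-coincident points, where the derivative diverges.
#'
#' @param u,v points on the hyperboloid (ambient coordinates, numeric or dual).
#' @param kappa negative curvature (numeric or dual scalar).
#' @return non-negative scalar distance.
#' @examples
#' u <- projectToHyperboloid(c(0, 0, 0))
#' v <- projectToHyperboloid(c(sinh(0.7), 0, 0))
#' hyperbolicDistance(u, v, -1)  # 0.7
#' @export
hyperbolicDistance <- function(u, v, kappa = -1) {
  .check_kappa(kappa)
  arg <- dClampMin(-lorentzInner(u, v), 1 + 1e-9)
  acosh(arg) / sqrt(-kappa)
}

#' Lift tangent coordinates onto the hyperboloid
#'
#' Maps unconstrained `z` in the tangent space at the origin to the
#' hyperboloid by setting the time coordinate `z0 = sqrt(1 + sum(z^2))` and
#' keeping the remaining coordinates. The constraint `<u,u> = -1` then holds
#' by construction, which is how all optimizers in this package parametrize
#' points.
#'
#' @param z numeric (or dual) vector of length `d`, or an `n x d` matrix
#'   (one row per point).
#' @return vector of length `d+1`, or an `n x (d+1)` matrix.
#' @examples
#' projectToHyperboloid(c(3, 4, 0))  # c(sqrt(26), 3, 4, 0)
#' @export
projectToHyperboloid <- function(z) {
  if (is.matrix(z)) {
    if (any(!is.finite(z))) stop("non-finite tangent coordinates")
    return(cbind(sqrt(1 + rowSums(z^2)), z, deparse.level = 0))
  }
  if (!isDual(z) && any(!is.finite(z))) stop("non-finite tangent coordinates")
  dcat(sqrt(1 + sum(z^2)), z)
}

#' Pairwise hyperbolic distance matrix
#'
#' Distances `D_ij = d_kappa(z_i, z_j)` between all embedded taxa: the
#' interface between the embedding geometry and tree decoding.
#'
#' @param locs a [HyperboloidEmbedding], or an `n x (d+1)` matrix of ambient
#'   coordinates.
#' @param kappa negative curvature.
#' @return symmetric `n x n` matrix with zero diagonal, labelled by taxon.
#' @export
pairwiseDistances <- function(locs, kappa = -1) {
  .check_kappa(kappa)
  if (is(locs, "HyperboloidEmbedding")) {
    pts <- embPoints(locs); labs <- embLabels(locs)
  } else {
    pts <- as.matrix(locs); labs <- rownames(pts)
  }
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points")
  # Gram matrix of Lorentz inner products, vectorized
  sgn <- c(-1, rep(1, ncol(pts) - 1))
  G <- pts %*% (t(pts) * sgn)
  arg <- pmax(-G, 1 + 1e-9)
  D <- acosh(arg) / sqrt(-kappa)
  diag(D) <- 0
  D <- (D + t(D)) / 2
  if (!is.null(labs)) dimnames(D) <- list(labs, labs)
  D
}

## --- internal: differentiable pairwise distances from flat tangent coords ---

# row-major taxon-major layout: coords of taxon i at (i-1)*d + 1:d
.pair_index <- function(n) {
  i <- rep(seq_len(n - 1), times = (n - 1):1)
  j <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
  cbind(i = i, j = j)
}

# returns dual/numeric vector of n(n-1)/2 distances in row-major
# upper-triangle order, for zflat of length n*d (dual or numeric)
.pairwise_dist_tangent <- function(zflat, n, d, kappa) {
  idx <- .pair_index(n)
  npair <- nrow(idx)
  # u0_i = sqrt(1 + sum_k z_ik^2)
  Ssq <- matrix(0, n, n * d)
  for (i in seq_len(n)) Ssq[i, (i - 1) * d + seq_len(d)] <- 1
  u0 <- sqrt(1 + dLinmap(Ssq, if (isDual(zflat)) zflat^2 else zflat^2))
  # dot products z_i . z_j for each pair
  ia <- as.vector(t(outer(idx[, 1] - 1, seq_len(d), function(a, k) a * d + k)))
  ib <- as.vector(t(outer(idx[, 2] - 1, seq_len(d), function(a, k) a * d + k)))
  prod <- dIndex(zflat, ia) * dIndex(zflat, ib)
  Agg <- matrix(0, npair, npair * d)
  for (f in seq_len(npair)) Agg[f, (f - 1) * d + seq_len(d)] <- 1
  dots <- dLinmap(Agg, prod)
  arg <- dIndex(u0, idx[, 1]) * dIndex(u0, idx[, 2]) - dots
  acosh(dClampMin(arg, 1 + 1e-9)) / sqrt(-kappa)
}

# assemble a full symmetric matrix from the upper-triangle vector
.unflatten_sym <- function(vals, n, labels = NULL) {
  D <- matrix(0, n, n)
  idx <- .pair_index(n)
  D[idx] <- vals
  D <- D + t(D)
  if (!is.null(labels)) dimnames(D) <- list(labels, labels)
  D
}
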