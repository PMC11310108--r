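#' Stress of a hyperbolic embedding
#'
#' Unweighted squared-error stress
#' `sum_{i<j} (d_kappa(z_i, z_j) - D_ij)^2`: zero iff the embedding
#' reproduces the target distances exactly.
#'
#' @param locs a [HyperboloidEmbedding].
#' @param D target distance matrix (taxon order must match `locs`).
#' @param kappa negative curvature.
#' @return non-negative scalar.
#' @export
embeddingStress <- function(locs, D, kappa = -1) {
  stopifnot(is(locs, "HyperboloidEmbedding"))
  .check_dist_matrix(D)
  if (nrow(D) != nrow(embPoints(locs))) stop("size mismatch between locs and D")
  E <- pairwiseDistances(locs, kappa)
  sum((E[upper.tri(E)] - D[upper.tri(D)])^2)
}

# stress and its gradient w.r.t. flat tangent coordinates (dual-powered)
.stress_grad <- function(zflat, n, d, kappa, Dtarget) {
  zd <- dualSeed(zflat)
  pd <- .pairwise_dist_tangent(zd, n, d, kappa)
  s <- sum((pd - Dtarget)^2)
  list(value = dualValue(s), grad = as.numeric(dualGrad(s)))
}

# stress value only (cheap, no derivative tracking)
.stress_value <- function(zflat, n, d, kappa, Dtarget) {
  sum((.pairwise_dist_tangent(zflat, n, d, kappa) - Dtarget)^2)
}

#' Embed a distance matrix into hyperbolic space
#'
#' Hyperbolic multidimensional scaling: places one point per taxon on the
#' `dim`-hyperboloid so that pairwise hyperbolic distances approximate `D`.
#' Initialization is spectral, from the eigendecomposition of
#' `cosh(sqrt(-kappa) * D)` (whose exact Lorentz-Gram structure the embedding
#' would satisfy at zero stress): the dominant eigenvector supplies the time
#' coordinates and the `dim` most negative eigenvalues supply spatial
#' directions; small seeded random tangent coordinates are used as a
#' fallback if the spectral construction degenerates. The embedding is then
#' refined by gradient descent on [embeddingStress] with backtracking line
#' search, so the stress never increases across iterations.
#'
#' @param D symmetric distance matrix (`n >= 3`).
#' @param dim embedding dimension `d >= 2` (default 3).
#' @param kappa negative curvature at which distances are measured.
#' @param maxIter quasi-Newton iterations per start.
#' @param seed seed for the random restarts (result is deterministic given it).
#' @param nStarts number of starts: the spectral initialization plus
#'   `nStarts - 1` seeded random configurations (stress is non-convex;
#'   restarting and keeping the lowest-stress solution is standard MDS
#'   practice).
#' @return a [HyperboloidEmbedding] of the `n` taxa, with attribute
#'   `stressTrace` (checkpointed stress values of the winning start,
#'   non-increasing) and attribute `stress` (final stress).
#' @export
embedDistances <- function(D, dim = 3, kappa = -1, maxIter = 500, seed = NULL,
                           nStarts = 4) {
  .check_dist_matrix(D)
  .check_kappa(kappa)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (dim < 2) stop("dim must be >= 2")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  sq <- sqrt(-kappa)
  A <- cosh(sq * D)
  e <- eigen(A, symmetric = TRUE)
  v1 <- e$vectors[, 1]
  if (sum(v1) < 0) v1 <- -v1
  spectral <- NULL
  if (e$values[1] > 0 && all(v1 > 0)) {
    u0 <- pmax(1, sqrt(e$values[1]) * v1)
    negidx <- order(e$values)[seq_len(min(dim, n - 1))]
    S <- sapply(negidx, function(k) sqrt(max(-e$values[k], 0)) * e$vectors[, k])
    if (!is.matrix(S)) S <- matrix(S, n)
    if (ncol(S) < dim) S <- cbind(S, matrix(0, n, dim - ncol(S)))
    # rescale each spatial vector radially so the point lies on the sheet
    nrm <- sqrt(rowSums(S^2))
    tgt <- sqrt(pmax(u0^2 - 1, 0))
    Z <- S * ifelse(nrm > 1e-12, tgt / nrm, 0)
    if (any(nrm <= 1e-12)) Z[nrm <= 1e-12, ] <- 0
    spectral <- as.vector(t(Z))
  }

  Dtarget <- D[.pair_index(n)]
  fn <- function(z) .stress_value(z, n, dim, kappa, Dtarget)
  gr <- function(z) .stress_grad(z, n, dim, kappa, Dtarget)$grad
  rsd <- 0.5 * mean(Dtarget) * sq / sqrt(dim)
  chunk <- 50L
  .with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, nStarts))) {
      z <- if (r == 1 && !is.null(spectral)) spectral else rnorm(n * dim, sd = rsd)
      trace <- fn(z)
      # chunked quasi-Newton refinement: each chunk restarts from the best
      # point so far, so the checkpointed stress sequence is non-increasing
      for (ch in seq_len(ceiling(maxIter / chunk))) {
        o <- stats::optim(z, fn, gr, method = "L-BFGS-B",
                          control = list(maxit = chunk, factr = 10))
        z <- o$par
        trace <- c(trace, min(o$value, trace[length(trace)]))
        if (o$convergence == 0) break
      }
      val <- trace[length(trace)]
      if (is.null(best) || val < best$val)
        best <- list(z = z, val = val, trace = trace)
    }
    out <- HyperboloidEmbedding(
      projectToHyperboloid(matrix(best$z, n, dim, byrow = TRUE)), labels)
    attr(out, "stress") <- best$val
    attr(out, "stressTrace") <- best$trace
    out
  })
}
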