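#' Optimizer configuration
#'
#' Settings shared by the gradient-based engines. Defaults follow the
#' reference schedule: 2000 epochs of Adam at learning rate 0.1 decayed by
#' `(t+1)^-0.5`, soft-NJ temperature `1e-5`, initial curvature -100, and a
#' 3-dimensional hyperboloid.
#'
#' @param epochs number of optimization epochs.
#' @param learningRate base Adam learning rate.
#' @param lrDecayExponent exponent of the `(t+1)^e` decay.
#' @param eta soft-NJ temperature (> 0).
#' @param seed integer seed controlling every stochastic step.
#' @param initCurvature starting curvature (negative).
#' @param dim embedding dimension.
#' @return a list of class `optimizerConfig`.
#' @export
optimizerConfig <- function(epochs = 2000, learningRate = 0.1,
                            lrDecayExponent = -0.5, eta = 1e-5, seed = 1L,
                            initCurvature = -100, dim = 3) {
  if (eta <= 0) stop("eta must be > 0")
  if (initCurvature >= 0) stop("initCurvature must be negative")
  if (epochs < 0) stop("epochs must be >= 0")
  structure(list(epochs = as.integer(epochs), learningRate = learningRate,
                 lrDecayExponent = lrDecayExponent, eta = eta,
                 seed = as.integer(seed), initCurvature = initCurvature,
                 dim = as.integer(dim)),
            class = "optimizerConfig")
}

# theta layout: [zflat (n*d) | c (1, kappa = -exp(c)) | wr (6) | wf (4)]
# the GTR block is present only when optimizeModel
.theta_meta <- function(n, d, optimizeModel) {
  nd <- n * d
  list(nd = nd, cidx = nd + 1L,
       widx = if (optimizeModel) nd + 1L + 1:10 else integer(0))
}

# evaluate the composite objective (and gradient when grad = TRUE) at theta
.composite_eval <- function(theta, n, d, ap, model, eta, optimizeModel,
                            grad = TRUE) {
  meta <- .theta_meta(n, d, optimizeModel)
  th <- if (grad) dualSeed(theta) else theta
  z <- dIndex(th, seq_len(meta$nd))
  cpar <- dIndex(th, meta$cidx)
  kappa <- -exp(cpar)
  if (optimizeModel) {
    wr <- theta[meta$widx[1:6]]; wf <- theta[meta$widx[7:10]]
    sm <- function(w) { e <- exp(w - max(w)); e / sum(e) }
    model <- GTR(sm(wr), sm(wf))
  }
  pairs <- .pairwise_dist_tangent(z, n, d, kappa)
  core <- .soft_nj_core(.flat_from_pairs(pairs, n), n, eta)
  out <- .assemble_phylo(core, ap$labels)
  if (modelKind(model) == "JC69") {
    tpfun <- .jc69_p16
    freqs <- rep(0.25, 4)
  } else {
    eig <- .gtr_eig(modelRates(model), modelFreqs(model))
    if (grad && optimizeModel) {
      p <- length(theta)
      tpfun <- function(t) {
        base <- .model_p16(model, t, eig)
        dmat <- .gtr_param_grads(wr, wf, dualValue(t))
        G <- matrix(0, p, 16)
        G[meta$widx, ] <- t(dmat)
        base + newDual(rep(0, 16), G)
      }
      fe <- exp(dIndex(th, meta$widx[7:10]))
      freqs <- fe / sum(fe)
    } else {
      tpfun <- function(t) .model_p16(model, t, eig)
      freqs <- modelFreqs(model)
    }
  }
  obj <- .loglik_core(out$tree, out$lengths, ap, tpfun, freqs)
  list(value = dualValue(obj),
       grad = if (grad) as.numeric(dualGrad(obj)) else NULL,
       tree = out$tree, kappa = dualValue(kappa), model = model)
}

#' Composite embedding-to-likelihood objective
#'
#' The full differentiable map optimized in maximum-likelihood mode: tangent
#' coordinates are lifted to the hyperboloid, converted to pairwise
#' hyperbolic distances at curvature `kappa`, decoded to a tree by soft-NJ at
#' temperature `eta`, and scored by the pruning log-likelihood. Because the
#' objective depends on the locations only through their distances it is
#' invariant under Lorentz isometries of the configuration.
#'
#' @param coords `n x d` matrix of tangent coordinates, rows ordered like the
#'   alignment's taxa.
#' @param kappa negative curvature.
#' @param model a [SubstModel].
#' @param aln `phyDat` alignment.
#' @param eta soft-NJ temperature.
#' @return scalar log-likelihood of the decoded tree.
#' @export
compositeObjective <- function(coords, kappa, model, aln, eta = 1e-5) {
  .check_kappa(kappa)
  coords <- as.matrix(coords)
  ap <- .aln_partials(aln)
  n <- nrow(coords)
  stopifnot(n == length(ap$labels))
  theta <- c(as.vector(t(coords)), log(-kappa))
  .composite_eval(theta, n, ncol(coords), ap, model, eta,
                  optimizeModel = FALSE, grad = FALSE)$value
}

#' @rdname compositeObjective
#' @return `compositeObjectiveGrad`: list with `value`, `coordGrad` (an
#'   `n x d` matrix), `curvatureGrad` (derivative w.r.t. the unconstrained
#'   curvature parameter `c` in `kappa = -exp(c)`), and the decoded `tree`.
#' @export
compositeObjectiveGrad <- function(coords, kappa, model, aln, eta = 1e-5) {
  .check_kappa(kappa)
  coords <- as.matrix(coords)
  ap <- .aln_partials(aln)
  n <- nrow(coords); d <- ncol(coords)
  theta <- c(as.vector(t(coords)), log(-kappa))
  ev <- .composite_eval(theta, n, d, ap, model, eta,
                        optimizeModel = FALSE, grad = TRUE)
  list(value = ev$value,
       coordGrad = matrix(ev$grad[seq_len(n * d)], n, d, byrow = TRUE),
       curvatureGrad = ev$grad[n * d + 1L],
       tree = ev$tree)
}

#' Maximum-likelihood inference over embedded trees
#'
#' Gradient ascent (Adam, with the `(t+1)^-0.5` learning-rate decay) on the
#' composite objective, jointly over embedding locations, the curvature
#' parameter and -- for a GTR model -- the substitution parameters through
#' softmax reparametrizations. The run starts from the hyperbolic MDS
#' embedding of the start tree's tip-tip distances (default start: classical
#' neighbour joining on JC-corrected alignment distances). The decoded tree
#' of the best epoch is returned.
#'
#' @param aln `phyDat` alignment (n >= 4 taxa).
#' @param startTree optional `phylo` start tree with branch lengths.
#' @param config an [optimizerConfig].
#' @param model a [SubstModel]; GTR parameters are optimized jointly.
#' @param optimizeModel optimize GTR rates/frequencies (default: yes for GTR)?
#' @return list of class `hypernjML`: `tree` (best decoded `phylo`), `model`,
#'   `trace` (one row per epoch: objective, curvature, gradient norm),
#'   `objective` (best value), `startObjective` (the decoded start
#'   embedding's objective, i.e. the NJ-start value), `embedding`, `config`.
#' @export
maximizeLikelihood <- function(aln, startTree = NULL,
                               config = optimizerConfig(),
                               model = JC69(),
                               optimizeModel = modelKind(model) == "GTR") {
  ap <- .aln_partials(aln)
  n <- length(ap$labels)
  if (n < 4) stop("need at least 4 taxa")
  d <- config$dim
  if (is.null(startTree)) {
    Dml <- as.matrix(phangorn::dist.ml(aln))
    startTree <- ape::nj(Dml)
  }
  startTree$edge.length <- pmax(startTree$edge.length, 1e-6)
  DT <- treePathDistances(startTree)[ap$labels, ap$labels]
  emb <- embedDistances(DT, dim = d, kappa = config$initCurvature,
                        seed = config$seed)
  theta <- c(as.vector(t(tangentCoords(emb))), log(-config$initCurvature))
  if (optimizeModel) {
    if (modelKind(model) != "GTR") stop("optimizeModel requires a GTR model")
    theta <- c(theta, log(modelRates(model)), log(modelFreqs(model)))
  }
  ev <- .composite_eval(theta, n, d, ap, model, config$eta, optimizeModel,
                        grad = config$epochs > 0)
  if (!is.finite(ev$value)) stop("non-finite objective at initialization")
  startObjective <- ev$value
  best <- list(value = ev$value, tree = ev$tree, model = ev$model,
               kappa = ev$kappa)
  trace <- data.frame(epoch = integer(0), objective = numeric(0),
                      curvature = numeric(0), gradNorm = numeric(0))
  if (config$epochs > 0) {
    madam <- vadam <- numeric(length(theta))
    b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
    for (t in seq_len(config$epochs)) {
      if (!is.finite(ev$value))
        stop("optimization diverged (non-finite objective) at epoch ", t - 1L)
      g <- ev$grad
      trace[t, ] <- list(t, ev$value, ev$kappa, sqrt(sum(g^2)))
      madam <- b1 * madam + (1 - b1) * g
      vadam <- b2 * vadam + (1 - b2) * g^2
      lr <- config$learningRate * t^config$lrDecayExponent
      theta <- theta + lr * (madam / (1 - b1^t)) /
        (sqrt(vadam / (1 - b2^t)) + aeps)
      ev <- .composite_eval(theta, n, d, ap, model, config$eta, optimizeModel,
                            grad = t < config$epochs)
      if (is.finite(ev$value) && ev$value > best$value)
        best <- list(value = ev$value, tree = ev$tree, model = ev$model,
                     kappa = ev$kappa)
    }
  }
  structure(list(tree = best$tree, model = best$model, trace = trace,
                 objective = best$value, startObjective = startObjective,
                 curvature = best$kappa, embedding = emb, config = config),
            class = "hypernjML")
}

#' @export
print.hypernjML <- function(x, ...) {
  cat(sprintf("hypernjML fit: %d tips, best log-likelihood %.4f (start %.4f), kappa %.3f\n",
              length(x$tree$tip.label), x$objective, x$startObjective,
              x$curvature))
  invisible(x)
}

#' Refine branch lengths at fixed topology
#'
#' Coordinate-wise refinement: each branch in turn is optimized by Brent's
#' method on the pruning log-likelihood, repeated for a few sweeps. Only
#' improving moves are accepted, so the returned tree's log-likelihood is
#' never lower than the input's.
#'
#' @param tree `phylo` (or `softNJTree`) with branch lengths.
#' @param aln `phyDat` alignment.
#' @param model a [SubstModel].
#' @param sweeps number of passes over all branches.
#' @return the input tree with refined branch lengths.
#' @export
refineBranchLengths <- function(tree, aln, model, sweeps = 3) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  cur <- treeLogLikelihood(tree, aln, model)
  for (s in seq_len(sweeps)) {
    improved <- FALSE
    for (e in seq_along(tree$edge.length)) {
      l0 <- tree$edge.length[e]
      f <- function(l) {
        tree$edge.length[e] <- l
        treeLogLikelihood(tree, aln, model)
      }
      opt <- optimize(f, interval = c(1e-9, max(1, 3 * l0 + 0.5)),
                      maximum = TRUE, tol = 1e-8)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  tree
}
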