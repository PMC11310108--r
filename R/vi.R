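#' @importFrom stats dnorm rnorm sd
NULL

#' Initialize a variational tree distribution
#'
#' Centres every mixture component's per-taxon tangent-space normal at the
#' embedding locations, with a global standard deviation set from the
#' smallest tip-tip distance via a coefficient of variation (`sigma =
#' min_{i<j} D_ij / cv`, default cv 20). Components beyond the first receive
#' a small seeded jitter so they can specialize; mixture weights start equal
#' (`alpha_k = 1/K`).
#'
#' @param locs a [HyperboloidEmbedding].
#' @param K number of mixture components (boosts).
#' @param cv coefficient of variation against the smallest tip-tip distance.
#' @param kappa negative curvature used when decoding draws (default: -1).
#' @param jitter per-component mean jitter, in units of sigma (0 = exact).
#' @param seed seed for the jitter.
#' @return a [VariationalParams].
#' @export
initVariational <- function(locs, K = 3, cv = 20, kappa = -1, jitter = 0.1,
                            seed = NULL) {
  stopifnot(is(locs, "HyperboloidEmbedding"))
  if (K < 1) stop("K must be >= 1")
  if (cv <= 0) stop("cv must be > 0")
  .check_kappa(kappa)
  K <- as.integer(K)
  D <- pairwiseDistances(locs, kappa)
  sigma <- min(D[upper.tri(D)]) / cv
  z <- tangentCoords(locs)
  n <- nrow(z); d <- ncol(z)
  mu <- array(0, c(K, n, d))
  .with_seed(seed, {
    for (k in seq_len(K)) {
      jit <- if (k == 1 || jitter == 0) 0 else
        matrix(rnorm(n * d, sd = jitter * sigma), n, d)
      mu[k, , ] <- z + jit
    }
  })
  new("VariationalParams", K = K, logits = rep(0, K), mean = mu,
      logSigma = array(log(sigma), c(K, n, d)), labels = embLabels(locs),
      kappa = kappa)
}

# flat parameter vector layout for optimization:
# [logits (K) | mu_1 (nd) | logsig_1 (nd) | mu_2 | logsig_2 | ...]
.vp_flatten <- function(vp) {
  n <- dim(vp@mean)[2]; d <- dim(vp@mean)[3]
  th <- vp@logits
  for (k in seq_len(vp@K))
    th <- c(th, as.vector(t(vp@mean[k, , ])), as.vector(t(vp@logSigma[k, , ])))
  th
}

.vp_unflatten <- function(th, vp) {
  n <- dim(vp@mean)[2]; d <- dim(vp@mean)[3]
  nd <- n * d
  vp@logits <- th[seq_len(vp@K)]
  for (k in seq_len(vp@K)) {
    off <- vp@K + (k - 1) * 2 * nd
    vp@mean[k, , ] <- matrix(th[off + seq_len(nd)], n, d, byrow = TRUE)
    vp@logSigma[k, , ] <- matrix(th[off + nd + seq_len(nd)], n, d, byrow = TRUE)
  }
  vp
}

# decode a tangent draw (numeric or dual flat vector) into a tree
.decode_draw <- function(zflat, vp, eta) {
  n <- dim(vp@mean)[2]; d <- dim(vp@mean)[3]
  pairs <- .pairwise_dist_tangent(zflat, n, d, vp@kappa)
  core <- .soft_nj_core(.flat_from_pairs(pairs, n), n, eta)
  .assemble_phylo(core, vp@labels)
}

# log mixture density of a tangent draw under the projected-normal mixture
.vp_log_mixture <- function(vp, zflat) {
  n <- dim(vp@mean)[2]; d <- dim(vp@mean)[3]
  alpha <- mixtureWeights(vp)
  comp <- vapply(seq_len(vp@K), function(k) {
    mu <- as.vector(t(vp@mean[k, , ]))
    sig <- exp(as.vector(t(vp@logSigma[k, , ])))
    sum(dnorm(zflat, mu, sig, log = TRUE))
  }, 0)
  logSumExp(log(alpha) + comp)
}

# log det (J J^T)^(1/2) correction for the tangent->branch-lengths map at a
# draw; J is assembled by the dual engine. Returns the 0.5*logdet term and,
# when hess = TRUE, its gradient w.r.t. the draw (via second-order duals).
.jacobian_correction <- function(vp, zflat, eta, grad = FALSE) {
  nd <- length(zflat)
  zd <- dualSeed(zflat, order = if (grad) 2 else 1)
  dec <- .decode_draw(zd, vp, eta)
  J <- t(dualGrad(dec$lengths)) # (2n-3) x nd
  M <- J %*% t(J)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  # rank loss (e.g. collinear configurations whose decoded star is pinned
  # at the branch floor) makes the tree-space density ill-defined
  if (min(ev) <= 0 || min(ev) / max(ev) < 1e-10 || !all(is.finite(ev)))
    stop("degenerate embedding configuration: singular soft-NJ Jacobian")
  out <- list(halfLogDet = 0.5 * sum(log(ev)), decode = dec, jacobian = J)
  if (grad) {
    Minv <- solve(M)
    h <- dec$lengths$h # (nd*nd) x (2n-3)
    gr <- numeric(nd)
    for (a in seq_len(nd)) {
      Ja <- t(h[a + (seq_len(nd) - 1) * nd, , drop = FALSE]) # dJ/dz_a
      gr[a] <- sum((Minv %*% Ja) * J)
    }
    out$grad <- gr
  }
  out
}

.match_prior <- function(prior) match.arg(prior, c("gammadirichlet", "exp10"))

# dual-aware log prior on a (dual) branch-length vector
.log_prior_lengths <- function(lengths, prior, n) {
  if (prior == "gammadirichlet") .log_prior_gd(lengths)
  else .log_prior_exp(lengths, rate = 10, n = n, includeTopology = TRUE)
}

#' Sample a tree from the variational distribution
#'
#' Draws a mixture component, a tangent-space normal deviate per taxon,
#' projects onto the hyperboloid, and decodes a tree via soft-NJ. The
#' returned log-density `log_q` is the mixture normal density of the draw
#' corrected by the generalized Jacobian of the tangent-to-branch-length
#' map, `- 1/2 log det(J J^T)`, so that it refers to tree space.
#'
#' @param params a [VariationalParams].
#' @param eta soft-NJ temperature.
#' @param seed integer seed (fixed seed gives an identical sample).
#' @param aln,model optional alignment and [SubstModel]; when supplied,
#'   `log_joint` (log-likelihood + log-prior) is computed.
#' @param prior `"gammadirichlet"` or `"exp10"`.
#' @return list with `tree` (phylo), `log_q`, `log_joint` (NA without data),
#'   `draw` (tangent coordinates), `component`.
#' @export
sampleTree <- function(params, eta = 1e-5, seed = NULL, aln = NULL,
                       model = JC69(), prior = "gammadirichlet") {
  stopifnot(is(params, "VariationalParams"))
  prior <- .match_prior(prior)
  n <- dim(params@mean)[2]; d <- dim(params@mean)[3]
  .with_seed(seed, {
    k <- if (params@K == 1L) 1L else
      sample.int(params@K, 1L, prob = mixtureWeights(params))
    mu <- as.vector(t(params@mean[k, , ]))
    sig <- exp(as.vector(t(params@logSigma[k, , ])))
    zflat <- mu + sig * rnorm(n * d)
    jc <- .jacobian_correction(params, zflat, eta)
    tree <- jc$decode$tree
    log_q <- .vp_log_mixture(params, zflat) - jc$halfLogDet
    log_joint <- NA_real_
    if (!is.null(aln)) {
      log_joint <- treeLogLikelihood(tree, aln, model) +
        .log_prior_lengths(tree$edge.length, prior, n) + logPriorGTR(model)
    }
    list(tree = tree, log_q = log_q, log_joint = log_joint,
         draw = matrix(zflat, n, d, byrow = TRUE), component = k)
  })
}

# one stratified draw for component k: returns everything needed for the
# SIWAE term and (optionally) its gradient w.r.t. the flat parameter vector
.siwae_term <- function(vp, k, aln_ap, model, eta, prior, grad = FALSE) {
  n <- dim(vp@mean)[2]; d <- dim(vp@mean)[3]
  nd <- n * d
  alpha <- mixtureWeights(vp)
  mu <- as.vector(t(vp@mean[k, , ]))
  sig <- exp(as.vector(t(vp@logSigma[k, , ])))
  epsd <- rnorm(nd)
  zflat <- mu + sig * epsd
  jc <- .jacobian_correction(vp, zflat, eta, grad = grad)
  lengths1 <- if (grad) newDual(jc$decode$lengths$v, jc$decode$lengths$g)
              else jc$decode$lengths
  tpfun <- if (modelKind(model) == "JC69") .jc69_p16 else {
    eig <- .gtr_eig(modelRates(model), modelFreqs(model))
    function(t) .model_p16(model, t, eig)
  }
  lj <- .loglik_core(jc$decode$tree, lengths1, aln_ap, tpfun,
                     modelFreqs(model)) +
    .log_prior_lengths(lengths1, prior, n) + logPriorGTR(model)
  logNk <- sum(dnorm(zflat, mu, sig, log = TRUE))
  tval <- log(alpha[k]) + dualValue(lj) - logNk + jc$halfLogDet
  out <- list(value = tval)
  if (grad) {
    gz <- as.numeric(dualGrad(lj)) + jc$grad # d/dz of (log joint + 1/2 logdet)
    gtheta <- numeric(vp@K + vp@K * 2 * nd)
    gtheta[seq_len(vp@K)] <- (seq_len(vp@K) == k) - alpha # d log alpha_k
    off <- vp@K + (k - 1) * 2 * nd
    gtheta[off + seq_len(nd)] <- gz                        # d/d mu_k
    gtheta[off + nd + seq_len(nd)] <- gz * sig * epsd + 1  # d/d logsigma_k
    out$grad <- gtheta
  }
  out
}

#' Stratified importance-weighted (SIWAE) objective
#'
#' One stochastic evaluation of the boosted variational bound
#' `log (1/M) sum_m sum_k alpha_k p(T, D) / q_k(T)` with one fresh draw per
#' `(m, k)` pair. With `K = 1, M = 1` this reduces to the standard
#' one-sample ELBO estimator `log p(T, D) - log q(T)`.
#'
#' @param params a [VariationalParams].
#' @param aln `phyDat` alignment.
#' @param model a [SubstModel] (held fixed during VI).
#' @param M importance samples per component.
#' @param seed integer seed.
#' @param eta soft-NJ temperature.
#' @param prior tree prior, `"gammadirichlet"` or `"exp10"`.
#' @return scalar stochastic bound estimate.
#' @export
siwaeObjective <- function(params, aln, model = JC69(), M = 1, seed = NULL,
                           eta = 1e-5, prior = "gammadirichlet") {
  stopifnot(is(params, "VariationalParams"), M >= 1)
  prior <- .match_prior(prior)
  ap <- .aln_partials(aln)
  .with_seed(seed, {
    tv <- numeric(0)
    for (m in seq_len(M))
      for (k in seq_len(params@K))
        tv <- c(tv, .siwae_term(params, k, ap, model, eta, prior)$value)
    logSumExp(tv) - log(M)
  })
}

#' Fit the variational distribution by stochastic gradient ascent
#'
#' Maximizes the SIWAE bound over component means, (log) standard
#' deviations and mixture logits with Adam under the `(t+1)^-0.5` decay
#' schedule, using reparametrized draws. Gradients of the generalized
#' Jacobian correction are propagated exactly through second-order duals;
#' the curvature is held fixed at its initialized value.
#'
#' @param aln `phyDat` alignment (n >= 4).
#' @param startTree optional start `phylo`; default: classical NJ on
#'   JC-corrected distances.
#' @param config an [optimizerConfig].
#' @param K mixture components (boosts).
#' @param M importance samples per component per epoch.
#' @param model fixed [SubstModel].
#' @param prior tree prior.
#' @param cv initialization coefficient of variation.
#' @return list of class `hypernjVI`: `params` (fitted
#'   [VariationalParams]), `trace` (per-epoch stochastic SIWAE), `config`.
#' @export
fitVariational <- function(aln, startTree = NULL, config = optimizerConfig(),
                           K = 3, M = 1, model = JC69(),
                           prior = "gammadirichlet", cv = 20) {
  prior <- .match_prior(prior)
  ap <- .aln_partials(aln)
  n <- length(ap$labels)
  if (n < 4) stop("need at least 4 taxa")
  if (is.null(startTree)) {
    Dml <- as.matrix(phangorn::dist.ml(aln))
    startTree <- ape::nj(Dml)
  }
  startTree$edge.length <- pmax(startTree$edge.length, 1e-6)
  DT <- treePathDistances(startTree)[ap$labels, ap$labels]
  emb <- embedDistances(DT, dim = config$dim, kappa = config$initCurvature,
                        seed = config$seed)
  vp <- initVariational(emb, K = K, cv = cv, kappa = config$initCurvature,
                        seed = config$seed)
  th <- .vp_flatten(vp)
  madam <- vadam <- numeric(length(th))
  b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
  trace <- data.frame(epoch = integer(0), objective = numeric(0))
  set.seed(config$seed)
  for (t in seq_len(config$epochs)) {
    vp <- .vp_unflatten(th, vp)
    terms <- list()
    for (m in seq_len(M))
      for (k in seq_len(vp@K))
        terms <- c(terms, list(.siwae_term(vp, k, ap, model, config$eta,
                                           prior, grad = TRUE)))
    tv <- vapply(terms, `[[`, 0, "value")
    obj <- logSumExp(tv) - log(M)
    if (!is.finite(obj))
      stop("non-finite SIWAE objective at epoch ", t)
    wts <- exp(tv - logSumExp(tv))
    g <- Reduce(`+`, Map(function(tm, w) w * tm$grad, terms, wts))
    trace[t, ] <- list(t, obj)
    madam <- b1 * madam + (1 - b1) * g
    vadam <- b2 * vadam + (1 - b2) * g^2
    lr <- config$learningRate * t^config$lrDecayExponent
    th <- th + lr * (madam / (1 - b1^t)) / (sqrt(vadam / (1 - b2^t)) + aeps)
  }
  vp <- .vp_unflatten(th, vp)
  structure(list(params = vp, trace = trace, config = config, model = model,
                 prior = prior, embedding = emb),
            class = "hypernjVI")
}

#' @export
print.hypernjVI <- function(x, ...) {
  cat(sprintf("hypernjVI fit: K = %d, %d epochs, final SIWAE %.4f\n",
              x$params@K, nrow(x$trace),
              if (nrow(x$trace)) x$trace$objective[nrow(x$trace)] else NA))
  invisible(x)
}

#' Importance-sampling evidence from log-weights
#'
#' Given log importance weights `log p(x_i) - log q(x_i)` for draws from
#' `q`, returns the log of their average (the marginal-likelihood estimate)
#' together with its Monte-Carlo standard error on the log scale (delta
#' method).
#'
#' @param logWeights numeric vector of log importance weights.
#' @return list with `logZ`, `se`, and `N`.
#' @export
importanceEvidence <- function(logWeights) {
  lw <- logWeights[is.finite(logWeights)]
  N <- length(lw)
  if (N == 0) stop("no finite log-weights")
  m <- max(lw)
  w <- exp(lw - m)
  logZ <- m + log(mean(w))
  se <- sd(w) / (sqrt(N) * mean(w))
  list(logZ = logZ, se = se, N = N)
}

#' Variational importance-sampling marginal likelihood
#'
#' Estimates `log p(D)` by importance sampling with the fitted variational
#' distribution as proposal: `p^(D) = (1/N) sum_i p(D | T_i) p(T_i) / q(T_i)`
#' with `T_i ~ q`, averaged in log space.
#'
#' @param params a [VariationalParams].
#' @param aln `phyDat` alignment.
#' @param model a [SubstModel].
#' @param N number of importance draws.
#' @param seed integer seed.
#' @param eta soft-NJ temperature.
#' @param prior tree prior.
#' @return list with `logZ` (log marginal likelihood), `se` (MC standard
#'   error), `N`.
#' @export
estimateMarginalLikelihood <- function(params, aln, model = JC69(), N = 1000,
                                       seed = NULL, eta = 1e-5,
                                       prior = "gammadirichlet") {
  stopifnot(N >= 1)
  prior <- .match_prior(prior)
  .with_seed(seed, {
    lw <- vapply(seq_len(N), function(i) {
      s <- sampleTree(params, eta = eta, aln = aln, model = model,
                      prior = prior)
      s$log_joint - s$log_q
    }, 0)
    importanceEvidence(lw)
  })
}
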