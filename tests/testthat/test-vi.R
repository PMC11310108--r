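# variational engine

viFixture <- function(n = 6, L = 200, seed = 71, kappa = -100, K = 1) {
  tr <- simulateTree(n, seed = seed)
  aln <- simulateAlignment(tr, JC69(), L, seed = seed)
  emb <- embedDistances(treePathDistances(tr), dim = 3, kappa = kappa,
                        seed = seed)
  vp <- initVariational(emb, K = K, cv = 20, kappa = kappa, seed = seed)
  list(tree = tr, aln = aln, emb = emb, vp = vp)
}

test_that("initialization follows the coefficient-of-variation rule", {
  fx <- viFixture(K = 3)
  D <- pairwiseDistances(fx$emb, -100)
  sigma <- min(D[upper.tri(D)]) / 20
  expect_equal(unique(as.vector(fx$vp@logSigma)), log(sigma))
  expect_equal(mixtureWeights(fx$vp), rep(1 / 3, 3))
  # jitter 0: every component mean reprojects to the input points
  vp0 <- initVariational(fx$emb, K = 3, cv = 20, kappa = -100, jitter = 0)
  for (k in 1:3) {
    lifted <- projectToHyperboloid(vp0@mean[k, , ])
    expect_equal(lifted, embPoints(fx$emb), tolerance = 1e-12)
  }
  # plain numbers: min distance 0.4 at cv 20 gives sigma 0.02
  ptsD <- matrix(c(0, .4, .5, .4, 0, .6, .5, .6, 0), 3, 3)
  rownames(ptsD) <- colnames(ptsD) <- c("a", "b", "c")
  e3 <- embedDistances(ptsD, dim = 2, kappa = -1, seed = 1)
  v3 <- initVariational(e3, K = 1, cv = 20, kappa = -1)
  Dhat <- pairwiseDistances(e3, -1)
  expect_equal(exp(v3@logSigma[1, 1, 1]), min(Dhat[upper.tri(Dhat)]) / 20)
})

test_that("tree sampling is deterministic, on-manifold, and degenerate at sigma 0", {
  fx <- viFixture()
  s1 <- sampleTree(fx$vp, seed = 5, aln = fx$aln)
  s2 <- sampleTree(fx$vp, seed = 5, aln = fx$aln)
  expect_identical(s1$log_q, s2$log_q)
  expect_identical(s1$draw, s2$draw)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_true(is.finite(s1$log_q) && is.finite(s1$log_joint))
  lifted <- projectToHyperboloid(s1$draw)
  expect_lt(max(abs(-lifted[, 1]^2 + rowSums(lifted[, -1]^2) + 1)), 1e-8)
  vp0 <- fx$vp
  vp0@logSigma[] <- log(1e-12)
  mean_tree <- hypernj:::.decode_draw(as.vector(t(fx$vp@mean[1, , ])),
                                      fx$vp, 1e-5)$tree
  st0 <- sampleTree(vp0, seed = 6)
  expect_equal(rfDist(st0$tree, mean_tree), 0)
  expect_equal(sort(st0$tree$edge.length), sort(mean_tree$edge.length),
               tolerance = 1e-9)
})

test_that("generalized Jacobian term matches an FD-assembled Jacobian", {
  # small toy: n = 4 taxa in d = 2, branches well away from the length
  # floor so the finite-difference oracle is valid everywhere
  tr <- ape::read.tree(text = "((A:0.2,B:0.3):0.15,(C:0.25,D:0.1):0);")
  emb <- embedDistances(treePathDistances(tr), dim = 2, kappa = -10, seed = 81)
  vp <- initVariational(emb, K = 1, kappa = -10)
  z0 <- as.vector(t(tangentCoords(emb)))
  jc <- hypernj:::.jacobian_correction(vp, z0, 1e-3)
  h <- 1e-6
  Jfd <- matrix(0, length(jc$decode$tree$edge.length), length(z0))
  for (a in seq_along(z0)) {
    zp <- z0; zm <- z0
    zp[a] <- zp[a] + h; zm[a] <- zm[a] - h
    lp <- dualValue(hypernj:::.decode_draw(zp, vp, 1e-3)$lengths)
    lm <- dualValue(hypernj:::.decode_draw(zm, vp, 1e-3)$lengths)
    Jfd[, a] <- (lp - lm) / (2 * h)
  }
  expect_equal(jc$jacobian, Jfd, tolerance = 1e-3)
  ldfd <- 0.5 * as.numeric(determinant(Jfd %*% t(Jfd), log = TRUE)$modulus)
  expect_equal(jc$halfLogDet, ldfd, tolerance = 1e-3)
})

test_that("collinear 1-D configurations are flagged as degenerate", {
  # in H^1 three points are always on one geodesic: one decoded branch is
  # pinned at the floor, the Jacobian loses rank, and sampling must error
  D <- matrix(c(0, .3, .7, .3, 0, .4, .7, .4, 0), 3, 3)
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  e1 <- embedDistances(D, dim = 2, kappa = -1, seed = 1)
  vp <- initVariational(e1, K = 1, kappa = -1)
  vp@mean <- vp@mean[, , 1, drop = FALSE]   # collapse to d = 1
  vp@logSigma <- vp@logSigma[, , 1, drop = FALSE]
  expect_error(sampleTree(vp, seed = 2), "degenerate|singular")
})

test_that("SIWAE with K = 1, M = 1 equals the one-sample ELBO", {
  fx <- viFixture(K = 1)
  s <- siwaeObjective(fx$vp, fx$aln, JC69(), M = 1, seed = 42)
  el <- sampleTree(fx$vp, seed = 42, aln = fx$aln, model = JC69())
  expect_equal(s, el$log_joint - el$log_q, tolerance = 1e-12)
})

test_that("importance evidence: exactness, SE, and reorder invariance", {
  # zero-variance weights (q equals the normalized posterior): exact at N = 1
  expect_equal(importanceEvidence(-1.234)$logZ, -1.234)
  expect_equal(importanceEvidence(rep(-1.234, 5))$se, 0)
  # conjugate Gaussian: prior N(0,1), likelihood N(x | theta, 1), x = 0.8
  x0 <- 0.8
  truth <- dnorm(x0, 0, sqrt(2), log = TRUE)
  set.seed(9)
  q_mu <- 0.1; q_sd <- 1.2 # deliberately not the posterior
  th <- rnorm(1000, q_mu, q_sd)
  lw <- dnorm(x0, th, 1, log = TRUE) + dnorm(th, 0, 1, log = TRUE) -
    dnorm(th, q_mu, q_sd, log = TRUE)
  est <- importanceEvidence(lw)
  expect_lt(abs(est$logZ - truth), 2 * est$se)
  perm <- sample(length(lw))
  expect_equal(importanceEvidence(lw[perm])$logZ, est$logZ)
  # zero-variance construction: q = exact posterior N(x/2, 1/sqrt(2))
  thz <- rnorm(50, x0 / 2, sqrt(1 / 2))
  lwz <- dnorm(x0, thz, 1, log = TRUE) + dnorm(thz, 0, 1, log = TRUE) -
    dnorm(thz, x0 / 2, sqrt(1 / 2), log = TRUE)
  expect_equal(max(lwz) - min(lwz), 0, tolerance = 1e-10)
  expect_equal(importanceEvidence(lwz[1])$logZ, truth, tolerance = 1e-10)
})

test_that("multi-sample importance bounds are monotone in M (toy posterior)", {
  # IWAE-style bound on the conjugate Gaussian toy, estimated by repetition
  x0 <- 0.8
  set.seed(11)
  bound <- function(M, reps = 4000) {
    mean(vapply(seq_len(reps), function(r) {
      th <- rnorm(M, 0.1, 1.2)
      lw <- dnorm(x0, th, 1, log = TRUE) + dnorm(th, 0, 1, log = TRUE) -
        dnorm(th, 0.1, 1.2, log = TRUE)
      hypernj:::logSumExp(lw) - log(M)
    }, 0))
  }
  b1 <- bound(1); b10 <- bound(10); b100 <- bound(100)
  expect_gt(b10, b1 - 0.02)
  expect_gt(b100, b10 - 0.02)
  expect_lt(b100, dnorm(x0, 0, sqrt(2), log = TRUE) + 0.02)
})

test_that("variational fit runs, is reproducible, and respects Jensen", {
  fx <- viFixture(n = 5, L = 150, seed = 72)
  cfg <- optimizerConfig(epochs = 25, seed = 3, initCurvature = -100)
  f1 <- fitVariational(fx$aln, config = cfg, K = 2, M = 1)
  f2 <- fitVariational(fx$aln, config = cfg, K = 2, M = 1)
  expect_identical(f1$trace, f2$trace)
  expect_true(all(is.finite(f1$trace$objective)))
  expect_equal(nrow(f1$trace), 25L)
  expect_s4_class(f1$params, "VariationalParams")
  # Jensen: mean SIWAE <= log evidence estimate, within MC error
  sw <- vapply(1:25, function(s)
    siwaeObjective(f1$params, fx$aln, JC69(), M = 1, seed = 100 + s), 0)
  ml <- estimateMarginalLikelihood(f1$params, fx$aln, JC69(), N = 300, seed = 7)
  expect_lte(mean(sw), ml$logZ + 2 * (stats::sd(sw) / 5 + ml$se))
})
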