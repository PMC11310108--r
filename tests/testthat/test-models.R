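# substitution models, pruning likelihood, priors

test_that("transition probabilities: limits and JC69/GTR agreement", {
  expect_equal(transitionProbs(JC69(), 0), diag(4), ignore_attr = TRUE)
  expect_equal(transitionProbs(JC69(), 500), matrix(0.25, 4, 4),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(transitionProbs(GTR(), 0.5), transitionProbs(JC69(), 0.5),
               tolerance = 1e-8)
  m <- GTR(c(1, 2, 3, 1, 4, 1), c(0.3, 0.2, 0.3, 0.2))
  P <- transitionProbs(m, 0.7)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
  # detailed balance pi_x P_xy = pi_y P_yx
  F <- modelFreqs(m) * P
  expect_equal(F, t(F), tolerance = 1e-12)
  expect_error(transitionProbs(JC69(), -0.1), ">= 0")
})

test_that("two identical single-site sequences at t = 0 give log(1/4)", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  aln <- phangorn::phyDat(matrix(c("a", "a"), 2, 1,
                                 dimnames = list(c("a", "b"), NULL)),
                          type = "DNA")
  expect_equal(treeLogLikelihood(tr, aln, JC69()), log(1 / 4))
})

test_that("pruning equals exhaustive summation over internal states", {
  fx <- simpleFixture(n = 4, L = 50, seed = 77)
  ll <- treeLogLikelihood(fx$tree, fx$aln, fx$model)
  expect_equal(ll, exhaustiveLogLik(fx$tree, fx$aln, fx$model),
               tolerance = 1e-8)
  m <- GTR(c(2, 1, 1, 3, 1, 1), c(0.4, 0.2, 0.2, 0.2))
  llg <- treeLogLikelihood(fx$tree, fx$aln, m)
  expect_equal(llg, exhaustiveLogLik(fx$tree, fx$aln, m), tolerance = 1e-8)
})

test_that("likelihood is invariant to rerooting and pattern compression", {
  fx <- simpleFixture(n = 6, L = 400, seed = 88)
  ll <- treeLogLikelihood(fx$tree, fx$aln, fx$model)
  for (og in c("t2", "t5")) {
    rr <- ape::root(fx$tree, outgroup = og, resolve.root = TRUE)
    expect_equal(treeLogLikelihood(rr, fx$aln, fx$model), ll,
                 tolerance = 1e-10)
  }
  # expand patterns back to full sites: identical likelihood
  chars <- as.character(fx$aln)
  shuffled <- phangorn::phyDat(chars[, sample(ncol(chars))], type = "DNA")
  expect_equal(treeLogLikelihood(fx$tree, shuffled, fx$model), ll,
               tolerance = 1e-10)
})

test_that("gaps and ambiguities act as missing data", {
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.1,(c:0.3,d:0.1):0);")
  chars <- rbind(a = c("a", "a"), b = c("c", "n"), c = c("g", "-"),
                 d = c("t", "?"))
  aln <- phangorn::phyDat(chars, type = "DNA")
  ll <- treeLogLikelihood(tr, aln, JC69())
  expect_true(is.finite(ll) && ll < 0)
  # a site of all-missing contributes nothing beyond the 'a' tip
  chars2 <- rbind(a = "a", b = "n", c = "-", d = "?")
  aln2 <- phangorn::phyDat(chars2, type = "DNA")
  expect_equal(treeLogLikelihood(tr, aln2, JC69()), log(0.25))
})

test_that("likelihood gradient w.r.t. branch lengths matches FD", {
  fx <- simpleFixture(n = 6, L = 200, seed = 99)
  ap <- hypernj:::.aln_partials(fx$aln)
  len0 <- fx$tree$edge.length
  f <- function(l) hypernj:::.loglik_core(fx$tree, l, ap, hypernj:::.jc69_p16,
                                          rep(0.25, 4))
  g <- f(dualSeed(len0))
  expect_equal(as.numeric(dualGrad(g)),
               fdGrad(function(l) f(l), len0, h = 1e-6), tolerance = 1e-4)
})

test_that("Gamma-Dirichlet prior: closed forms and MC normalization", {
  tr <- simulateTree(4, seed = 3) # 5 branches
  B <- length(tr$edge.length)
  # flat Dirichlet normalizer log((B-1)!) and Exponential(0.1) total term
  tr10 <- tr; tr10$edge.length <- rep(2, B) # total 10
  expect_equal(logPriorGammaDirichlet(tr10, 1, 0.1),
               log(0.1) - 1 + lgamma(B) - (B - 1) * log(10))
  tr0 <- tr; tr0$edge.length[2] <- 0
  expect_equal(logPriorGammaDirichlet(tr0), -Inf)
  # density integrates to one: importance sample from an exponential proposal
  set.seed(10)
  N <- 1e5
  prop <- matrix(rexp(N * B, rate = 0.4), N, B)
  lp <- apply(prop, 1, function(l) {
    tt <- tr; tt$edge.length <- l
    logPriorGammaDirichlet(tt)
  })
  lq <- rowSums(log(0.4) - 0.4 * prop)
  w <- exp(lp - lq)
  expect_equal(mean(w), 1, tolerance = 0.05)
})

test_that("exponential branch prior with uniform topology constant", {
  tr <- simulateTree(4, seed = 4)
  tr$edge.length <- rep(0.1, 5)
  # 5 branches at rate 10, plus log #topologies(4) = log 3
  expect_equal(logPriorExpBranches(tr, 10, includeTopology = FALSE),
               5 * (log(10) - 1))
  expect_equal(logPriorExpBranches(tr, 10, includeTopology = TRUE),
               5 * (log(10) - 1) - log(3))
  # independent density-function oracle on random trees
  for (s in 1:5) {
    trs <- simulateTree(6, seed = s)
    expect_equal(logPriorExpBranches(trs, 10, includeTopology = FALSE),
                 sum(stats::dexp(trs$edge.length, 10, log = TRUE)),
                 tolerance = 1e-12)
  }
})

test_that("GTR prior is the flat Dirichlet constant", {
  expect_equal(logPriorGTR(GTR()), log(120) + log(6))
  expect_equal(logPriorGTR(JC69()), 0)
  expect_error(new("SubstModel", kind = "GTR", rates = rep(0.3, 6),
                   freqs = rep(0.25, 4)), "simplex")
})
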