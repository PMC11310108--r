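# bespoke random-walk Metropolis-Hastings sampler over tree space, used as
# an independent posterior oracle at toy scale: mixes NNI topology moves
# (symmetric proposal) with log-normal multiplicative branch-length moves
mhTreeSampler <- function(aln, model = JC69(), prior = "gammadirichlet",
                          iters = 30000, thin = 10, seed = 1,
                          init = NULL, burnFrac = 0.2, moveSd = 0.3) {
  logPrior <- function(tr) {
    if (prior == "gammadirichlet") logPriorGammaDirichlet(tr)
    else logPriorExpBranches(tr, 10)
  }
  set.seed(seed)
  if (is.null(init)) {
    init <- ape::nj(as.matrix(phangorn::dist.ml(aln)))
    init$edge.length <- pmax(init$edge.length, 1e-4)
  }
  cur <- init
  curLp <- treeLogLikelihood(cur, aln, model) + logPrior(cur)
  lens <- numeric(0)
  nacc <- 0
  for (i in seq_len(iters)) {
    if (runif(1) < 0.2) { # topology move (NNI, symmetric)
      prop <- phangorn::rNNI(cur, moves = 1)
      lhast <- 0
    } else {              # branch move, log-normal multiplier
      prop <- cur
      e <- sample.int(length(prop$edge.length), 1)
      u <- rnorm(1, sd = moveSd)
      prop$edge.length[e] <- prop$edge.length[e] * exp(u)
      lhast <- u
    }
    propLp <- treeLogLikelihood(prop, aln, model) + logPrior(prop)
    if (is.finite(propLp) && log(runif(1)) < propLp - curLp + lhast) {
      cur <- prop; curLp <- propLp; nacc <- nacc + 1
    }
    if (i %% thin == 0) lens <- c(lens, sum(cur$edge.length))
  }
  keep <- lens[-seq_len(floor(length(lens) * burnFrac))]
  list(treeLength = keep, acceptance = nacc / iters,
       meanLength = mean(keep), sdLength = sd(keep))
}
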