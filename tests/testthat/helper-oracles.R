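# shared helpers: independent oracles and fixture builders

# random symmetric distance matrix with zero diagonal
randomDistMatrix <- function(n, seed, lo = 0.1, hi = 2) {
  set.seed(seed)
  M <- matrix(runif(n * n, lo, hi), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  rownames(M) <- colnames(M) <- paste0("t", seq_len(n))
  M
}

# independent classical NJ reference (ape's C implementation), with branch
# lengths floored like the soft decoder's output for comparability
hardNJ <- function(D, floor_eps = 1e-6) {
  tr <- ape::nj(D)
  tr$edge.length <- pmax(tr$edge.length, floor_eps)
  tr
}

rfDist <- function(a, b) {
  if (inherits(a, "softNJTree")) a <- a$tree
  if (inherits(b, "softNJTree")) b <- b$tree
  phangorn::RF.dist(ape::unroot(a), ape::unroot(b))
}

# branch lengths keyed by the split (tip set below the edge) so trees with
# identical topology can be compared edge by edge
splitLengths <- function(tree) {
  n <- length(tree$tip.label)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    tips <- if (ch <= n) ch else
      intersect(unlist(phangorn::Descendants(tree, ch, "tips")), seq_len(n))
    labs <- sort(tree$tip.label[tips])
    if (length(labs) > n / 2 ||
        (length(labs) == n / 2 && !(tree$tip.label[1] %in% labs)))
      labs <- sort(setdiff(tree$tip.label, labs))
    key <- paste(labs, collapse = "|")
    out[[key]] <- c(out[[key]], tree$edge.length[e])
  }
  vapply(out, sum, 0)[order(names(out))]
}

# exhaustive phylogenetic likelihood: sum over all internal-state
# assignments (oracle for Felsenstein pruning)
exhaustiveLogLik <- function(tree, aln, model) {
  n <- length(tree$tip.label)
  chars <- as.character(aln)[tree$tip.label, , drop = FALSE]
  L <- ncol(chars)
  states <- match(tolower(chars), c("a", "c", "g", "t"))
  dim(states) <- dim(chars)
  root <- setdiff(unique(tree$edge[, 1]), tree$edge[, 2])
  internals <- sort(unique(tree$edge[, 1]))
  ni <- length(internals)
  freqs <- modelFreqs(model)
  Plist <- lapply(seq_len(nrow(tree$edge)),
                  function(e) transitionProbs(model, tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), ni)))
  ll <- 0
  for (site in seq_len(L)) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      asg <- integer(max(tree$edge))
      asg[seq_len(n)] <- states[, site]
      asg[internals] <- grid[g, ]
      p <- freqs[asg[root]]
      for (e in seq_len(nrow(tree$edge)))
        p <- p * Plist[[e]][asg[tree$edge[e, 1]], asg[tree$edge[e, 2]]]
      tot <- tot + p
    }
    ll <- ll + log(tot)
  }
  ll
}

# central finite-difference gradient of a scalar function
fdGrad <- function(f, x, h = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
    (f(xp) - f(xm)) / (2 * h)
  }, 0)
}

simpleFixture <- function(n = 6, L = 300, seed = 301, model = JC69()) {
  tr <- simulateTree(n, seed = seed)
  aln <- simulateAlignment(tr, model, L, seed = seed)
  list(tree = tr, aln = aln, model = model)
}
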