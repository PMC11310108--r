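# run expr with a temporarily seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a random unrooted bifurcating tree
#'
#' Topology drawn uniformly over unrooted binary labelled topologies, with
#' branch lengths i.i.d. Exponential(`rate`). The default rate of 10 (mean
#' branch length 0.1 substitutions/site) matches the exponential prior used
#' for Bayesian runs.
#'
#' @param n number of taxa (>= 3).
#' @param rate rate of the exponential branch-length distribution.
#' @param seed integer seed (draws are deterministic given it).
#' @return an unrooted `phylo` with `2n - 3` branches, tips `t1..tn`.
#' @export
simulateTree <- function(n, rate = 10, seed = NULL) {
  if (!is.numeric(n) || n < 3) stop("need n >= 3 taxa")
  n <- as.integer(n)
  .with_seed(seed, {
    phy <- ape::rtopology(n, rooted = FALSE, tip.label = paste0("t", seq_len(n)))
    phy$edge.length <- rexp(nrow(phy$edge), rate)
    phy
  })
}

#' Tip-to-tip path distance matrix of a tree
#'
#' Sums of branch lengths along tip-tip paths: an additive metric satisfying
#' the four-point condition exactly, i.e. the tree's faithful distance-matrix
#' encoding.
#'
#' @param tree a `phylo` with branch lengths.
#' @return symmetric matrix in `tree$tip.label` order.
#' @export
treePathDistances <- function(tree) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"))
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Simulate an alignment along a tree
#'
#' Forward simulation of nucleotide sites under the substitution model: the
#' root state is drawn from the equilibrium frequencies and states propagate
#' along each branch with [transitionProbs]. Sites are i.i.d.
#'
#' @param tree `phylo` with branch lengths.
#' @param model a [SubstModel].
#' @param L number of sites.
#' @param seed integer seed.
#' @return alignment of class `phyDat` (site patterns compressed).
#' @export
simulateAlignment <- function(tree, model, L, seed = NULL) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"), is(model, "SubstModel"), L >= 1)
  L <- as.integer(L)
  n <- length(tree$tip.label)
  freqs <- modelFreqs(model)
  po <- .postorder_edges(tree)
  preorder <- rev(po$order)
  .with_seed(seed, {
    states <- matrix(0L, max(tree$edge), L)
    states[po$root, ] <- sample.int(4L, L, replace = TRUE, prob = freqs)
    for (e in preorder) {
      par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      P <- transitionProbs(model, tree$edge.length[e])
      for (x in 1:4) {
        sel <- which(states[par, ] == x)
        if (length(sel))
          states[ch, sel] <- sample.int(4L, length(sel), replace = TRUE, prob = P[x, ])
      }
    }
    chars <- matrix(c("a", "c", "g", "t")[states[seq_len(n), , drop = FALSE]], n, L)
    rownames(chars) <- tree$tip.label
    phangorn::phyDat(chars, type = "DNA")
  })
}
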