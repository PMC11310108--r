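#' @importFrom stats dgamma optimize rbinom
NULL

## --- transition probabilities ----------------------------------------------

# JC69 closed form as a flat row-major 16-vector; t may be numeric or dual
.jc69_p16 <- function(t) {
  e <- exp(-4 / 3 * t)
  coefs <- as.vector(t(matrix(-1 / 4, 4, 4) + diag(1, 4)))
  0.25 + e * coefs
}

# symmetrized eigendecomposition of the (mean-rate-1 normalized) GTR
# generator: P(t) = sum_k A_k exp(lambda_k t), A built from eigenvectors
.gtr_eig <- function(rates, freqs) {
  S <- matrix(0, 4, 4)
  S[lower.tri(S)] <- 0 # filled symmetric below
  S[1, 2] <- S[2, 1] <- rates[1] # AC
  S[1, 3] <- S[3, 1] <- rates[2] # AG
  S[1, 4] <- S[4, 1] <- rates[3] # AT
  S[2, 3] <- S[3, 2] <- rates[4] # CG
  S[2, 4] <- S[4, 2] <- rates[5] # CT
  S[3, 4] <- S[4, 3] <- rates[6] # GT
  Q <- S * rep(freqs, each = 4) # Q_xy = s_xy * pi_y, x != y
  diag(Q) <- -rowSums(Q)
  beta <- -sum(freqs * diag(Q))
  Q <- Q / beta
  sq <- sqrt(freqs)
  B <- Q * outer(sq, 1 / sq) # D^1/2 Q D^-1/2, symmetric
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  # A_k[x, y] = (1/sq_x) U[x,k] U[y,k] sq_y, flattened row-major in rows of Amat
  Amat <- matrix(0, 16, 4)
  for (k in 1:4) {
    Ak <- outer(e$vectors[, k] / sq, e$vectors[, k] * sq)
    Amat[, k] <- as.vector(t(Ak))
  }
  list(lambda = e$values, Amat = Amat, Q = Q)
}

# flat row-major P(t) for a model; t numeric or dual
.model_p16 <- function(model, t, eig = NULL) {
  if (modelKind(model) == "JC69") return(.jc69_p16(t))
  if (is.null(eig)) eig <- .gtr_eig(modelRates(model), modelFreqs(model))
  E <- exp(eig$lambda * t)
  dLinmap(eig$Amat, E)
}

#' Transition probability matrix
#'
#' `P(t)` for one branch of length `t` under the substitution model: the JC69
#' closed form, or for GTR the matrix exponential of the mean-rate-one
#' normalized reversible generator, computed through its symmetrized
#' eigendecomposition. Rows sum to one; `P(0)` is the identity; a GTR model
#' satisfies detailed balance with respect to its equilibrium frequencies.
#'
#' @param model a [SubstModel].
#' @param t branch length, `>= 0` (expected substitutions per site).
#' @return a `4 x 4` row-stochastic matrix (states A, C, G, T).
#' @examples
#' transitionProbs(JC69(), 0.5)
#' @export
transitionProbs <- function(model, t) {
  stopifnot(is(model, "SubstModel"))
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t) || t < 0)
    stop("branch length t must be a finite scalar >= 0")
  P <- matrix(.model_p16(model, t), 4, 4, byrow = TRUE)
  dimnames(P) <- list(c("a", "c", "g", "t"), c("a", "c", "g", "t"))
  P
}

# exchangeability rate index for each off-diagonal entry (AC AG AT CG CT GT)
.gtr_pair_of <- matrix(c(0, 1, 2, 3,  1, 0, 4, 5,  2, 4, 0, 6,  3, 5, 6, 0), 4, 4)

# analytic dP16/dw for the 10 unconstrained GTR logits (6 rate logits then 4
# frequency logits) at numeric branch length t: Frechet derivative of the
# matrix exponential through the symmetric eigendecomposition, with divided
# differences (robust to degenerate eigenvalues)
.gtr_param_grads <- function(wr, wf, t) {
  sm <- function(w) { e <- exp(w - max(w)); e / sum(e) }
  rates <- sm(wr); pi <- sm(wf)
  S <- matrix(0, 4, 4)
  S[.gtr_pair_of > 0] <- rates[.gtr_pair_of[.gtr_pair_of > 0]]
  beta <- sum(S * outer(pi, pi)) # = 2 sum_{x<y} s_xy pi_x pi_y (diag of S is 0)
  sq <- sqrt(pi)
  B <- S * outer(sq, sq) / beta
  diag(B) <- -(S %*% pi) / beta
  e <- eigen(B, symmetric = TRUE)
  U <- e$vectors; lam <- e$values
  elam <- exp(lam * t)
  dl <- outer(lam, lam, `-`)
  F <- ifelse(abs(dl) > 1e-9, outer(elam, elam, `-`) / dl,
              t * exp(outer(lam, lam, `+`) / 2 * t))
  E <- U %*% diag(elam) %*% t(U) # e^{Bt}, symmetric
  out <- matrix(0, 16, 10)
  for (u in 1:10) {
    if (u <= 6) {
      dS <- matrix(0, 4, 4)
      dS[.gtr_pair_of > 0] <-
        rates[.gtr_pair_of[.gtr_pair_of > 0]] *
          ((.gtr_pair_of[.gtr_pair_of > 0] == u) - rates[u])
      dpi <- rep(0, 4)
    } else {
      dS <- matrix(0, 4, 4)
      dpi <- pi * ((seq_len(4) == (u - 6)) - pi[u - 6])
    }
    dbeta <- sum(dS * outer(pi, pi)) + 2 * sum(S * outer(dpi, pi))
    dsq <- 0.5 * dpi / sq
    dB <- (dS * outer(sq, sq) + S * (outer(dsq, sq) + outer(sq, dsq))) / beta -
      B * (dbeta / beta)
    # diagonal separately: B_xx = -(S pi)_x / beta
    diag(dB) <- as.numeric(-(dS %*% pi + S %*% dpi) / beta) +
      (as.numeric(S %*% pi) / beta) * (dbeta / beta)
    dE <- U %*% (F * (t(U) %*% dB %*% U)) %*% t(U)
    # P = D^-1/2 E D^1/2; D = diag(pi)
    dDm <- -0.5 * dpi / pi^1.5  # d(pi^-1/2)
    dDp <- 0.5 * dpi / sq       # d(pi^1/2)
    dP <- outer(dDm, sq) * E + outer(1 / sq, sq) * dE + outer(1 / sq, dDp) * E
    out[, u] <- as.vector(t(dP))
  }
  out
}

## --- alignments --------------------------------------------------------------

# tip partial-likelihood rows from a phyDat object: list per taxon of
# (npattern x 4) matrices (ambiguity codes resolved by the contrast matrix),
# plus pattern weights
.aln_partials <- function(aln) {
  stopifnot(inherits(aln, "phyDat"))
  contrast <- attr(aln, "contrast")
  w <- attr(aln, "weight")
  tp <- lapply(aln, function(codes) contrast[codes, , drop = FALSE])
  list(tip = tp, weight = w, labels = names(aln), npat = length(w))
}

.postorder_edges <- function(phy) {
  n <- length(phy$tip.label)
  root <- setdiff(unique(phy$edge[, 1]), phy$edge[, 2])
  kids <- split(seq_len(nrow(phy$edge)), phy$edge[, 1])
  out <- integer(nrow(phy$edge))
  k <- 0L
  visit <- function(node) {
    for (e in kids[[as.character(node)]]) {
      ch <- phy$edge[e, 2]
      if (ch > n) visit(ch)
      k <<- k + 1L
      out[k] <<- e
    }
  }
  visit(root)
  list(order = out, root = root)
}

# Felsenstein pruning in the flat (state-block, pattern-fast) layout with
# per-node rescaling; `lengths` numeric or dual (phy$edge order), `tpfun(t)`
# returns a flat row-major 16-vector P(t), `freqs` numeric or dual length 4
.loglik_core <- function(phy, lengths, ap, tpfun, freqs) {
  n <- length(phy$tip.label)
  P <- ap$npat
  po <- .postorder_edges(phy)
  partial <- vector("list", max(phy$edge))
  tipmap <- match(phy$tip.label, ap$labels)
  for (i in seq_len(n)) partial[[i]] <- as.vector(ap$tip[[tipmap[i]]]) # P x 4 flat
  logscale <- 0
  pending <- lapply(seq_len(max(phy$edge)), function(i) NULL)
  for (e in po$order) {
    par <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    p16 <- tpfun(dIndex(lengths, e))
    old <- partial[[ch]]
    blocks <- vector("list", 4)
    for (x in 1:4) {
      acc <- dIndex(p16, (x - 1) * 4 + 1) * dIndex(old, seq_len(P))
      for (y in 2:4)
        acc <- acc + dIndex(p16, (x - 1) * 4 + y) * dIndex(old, (y - 1) * P + seq_len(P))
      blocks[[x]] <- acc
    }
    msg <- do.call(dcat, blocks)
    partial[[par]] <- if (is.null(partial[[par]])) msg else {
      comb <- partial[[par]] * msg
      vm <- matrix(dualValue(comb), P, 4)
      sc <- pmax(apply(vm, 1, max), 1e-300)
      logscale <- logscale + sum(ap$weight * log(sc))
      comb / rep(sc, 4)
    }
  }
  pr <- partial[[po$root]]
  lik <- dIndex(freqs, 1) * dIndex(pr, seq_len(P))
  for (x in 2:4)
    lik <- lik + dIndex(freqs, x) * dIndex(pr, (x - 1) * P + seq_len(P))
  sum(log(lik) * ap$weight) + logscale
}

#' Phylogenetic log-likelihood by Felsenstein pruning
#'
#' Log-probability of an aligned set of sequences given an unrooted tree and
#' a substitution model, computed by the pruning algorithm over compressed
#' site patterns with per-node rescaling (stable for long alignments). Gaps
#' and ambiguity codes contribute partial-likelihood rows from the alignment
#' contrast matrix (fully missing characters are vectors of ones). The value
#' is invariant to the (arbitrary) rooting of the input tree.
#'
#' @param tree `phylo` with branch lengths (or a `softNJTree`).
#' @param aln alignment of class `phyDat` (see [readAlignment],
#'   [simulateAlignment]); tip labels must match the tree's.
#' @param model a [SubstModel].
#' @return scalar log-likelihood.
#' @export
treeLogLikelihood <- function(tree, aln, model) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  stopifnot(inherits(tree, "phylo"), is(model, "SubstModel"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be >= 0")
  ap <- .aln_partials(aln)
  if (!setequal(tree$tip.label, ap$labels))
    stop("taxon labels of tree and alignment do not match")
  eig <- if (modelKind(model) == "GTR")
    .gtr_eig(modelRates(model), modelFreqs(model)) else NULL
  .loglik_core(tree, tree$edge.length, ap,
               function(t) .model_p16(model, t, eig), modelFreqs(model))
}

## --- priors ------------------------------------------------------------------

# dual-aware Gamma-Dirichlet log prior given a vector of branch lengths
.log_prior_gd <- function(lengths, shape = 1, rate = 0.1) {
  B <- length(dualValue(lengths))
  tot <- sum(lengths)
  shape * log(rate) - lgamma(shape) + (shape - 1) * log(tot) - rate * tot +
    lgamma(B) - (B - 1) * log(tot)
}

#' Gamma-Dirichlet prior on branch lengths
#'
#' The compound prior used for Bayesian runs: a Gamma(shape, rate)
#' distribution over the total tree length, split into individual branches by
#' a flat (equally weighted) Dirichlet over branch proportions, including the
#' Jacobian of the (total, proportions) reparametrization. With the defaults
#' (shape 1, rate 0.1) the total length is Exponential(0.1).
#'
#' @param tree `phylo` (or `softNJTree`) with positive branch lengths.
#' @param shape,rate Gamma parameters for the total tree length.
#' @return scalar log-density (`-Inf` if any branch length is not positive).
#' @export
logPriorGammaDirichlet <- function(tree, shape = 1, rate = 0.1) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  len <- tree$edge.length
  if (any(len <= 0)) return(-Inf)
  .log_prior_gd(len, shape, rate)
}

.n_unrooted_topologies_log <- function(n) {
  if (n < 4) return(0)
  sum(log(seq(3, 2 * n - 5, by = 2)))
}

.log_prior_exp <- function(lengths, rate = 10, n = NULL, includeTopology = TRUE) {
  B <- length(dualValue(lengths))
  out <- B * log(rate) - rate * sum(lengths)
  if (includeTopology && !is.null(n)) out <- out - .n_unrooted_topologies_log(n)
  out
}

#' Exponential branch-length prior with uniform topology
#'
#' Independent Exponential(rate) densities on every branch, optionally with
#' the uniform-topology normalizer `-log((2n-5)!!)` over unrooted binary
#' topologies (a constant during optimization, but part of the normalized
#' density used by the marginal-likelihood estimator).
#'
#' @param tree `phylo` (or `softNJTree`).
#' @param rate exponential rate (default 10).
#' @param includeTopology include the topology-count constant?
#' @return scalar log-density.
#' @export
logPriorExpBranches <- function(tree, rate = 10, includeTopology = TRUE) {
  if (inherits(tree, "softNJTree")) tree <- tree$tree
  len <- tree$edge.length
  if (any(len < 0)) return(-Inf)
  .log_prior_exp(len, rate, n = length(tree$tip.label),
                 includeTopology = includeTopology)
}

#' Flat Dirichlet priors on GTR parameters
#'
#' Flat Dirichlet over the six exchangeabilities and flat Dirichlet over the
#' four equilibrium frequencies: `log(5!) + log(3!)`, a constant on the
#' simplex. JC69 has no free parameters and returns 0.
#'
#' @param model a [SubstModel].
#' @return scalar log-density.
#' @export
logPriorGTR <- function(model) {
  stopifnot(is(model, "SubstModel"))
  if (modelKind(model) == "JC69") return(0)
  log(120) + log(6)
}
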