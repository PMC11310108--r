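#' @importFrom stats rexp rnorm runif setNames
NULL

.check_dist_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (any(!is.finite(D))) stop("D contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-8) stop("D must be symmetric")
  if (any(diag(D) != 0)) stop("D must have a zero diagonal")
  if (any(D < 0)) stop("D must be non-negative")
  invisible(D)
}

#' Soft-sort relaxed permutation matrix
#'
#' Continuous relaxation of arg-sort: `P = softmax(-|sort(x) 1' - 1 x'| / eta)`
#' row-wise, with `sort` in decreasing order, so row `i` of `P` soft-selects
#' the `i`-th largest entry of `x` and the last row soft-selects the minimum.
#' Each row is a probability vector; as `eta -> 0` with distinct entries `P`
#' converges to the hard sorting permutation.
#'
#' @param x numeric (or dual) vector.
#' @param eta temperature, > 0.
#' @return for numeric `x`, an `m x m` row-stochastic matrix; for dual `x`, a
#'   dual vector of the `m^2` entries in row-major order.
#' @examples
#' round(softSortPermutation(c(3, 1, 2), 1e-6))  # rows pick 3, 2, 1
#' @export
softSortPermutation <- function(x, eta) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) stop("eta must be > 0")
  xv <- dualValue(x)
  if (any(!is.finite(xv))) stop("x must be finite")
  m <- length(xv)
  s <- dIndex(x, order(xv, decreasing = TRUE))
  sfull <- dIndex(s, rep(seq_len(m), each = m))
  xfull <- dIndex(x, rep.int(seq_len(m), m))
  sc <- -abs(sfull - xfull)
  # row-wise softmax at temperature eta (softmax is shift-invariant per row)
  rowmax <- vapply(seq_len(m), function(i) max(dualValue(sc)[(i - 1) * m + seq_len(m)]), 0)
  e <- exp((sc - rowmax[rep(seq_len(m), each = m)]) / eta)
  Rs <- matrix(0, m, m * m)
  for (i in seq_len(m)) Rs[i, (i - 1) * m + seq_len(m)] <- 1
  rs <- dLinmap(Rs, e)
  P <- e / dIndex(rs, rep(seq_len(m), each = m))
  if (isDual(P)) P else matrix(dualValue(P), m, m, byrow = TRUE)
}

# core soft arg-min over an upper-triangle flattened vector Qu (row-major
# pair order given by idx). Two-pass soft-sort with cumulative-sum
# tie-breaking: the first minimal entry (in flattened order) is selected.
.soft_argmin_flat <- function(Qu, eta, idx, m) {
  Pl <- dSoftmax(-Qu, eta)           # last soft-sort row: soft arg-min
  C <- dCumsum(Pl)
  s <- dSoftmax(Pl * (2 - C), eta)   # tie-break toward the first minimum
  npair <- nrow(idx)
  Ri <- matrix(0, m, npair); Rj <- matrix(0, m, npair)
  Ri[cbind(idx[, 1], seq_len(npair))] <- 1
  Rj[cbind(idx[, 2], seq_len(npair))] <- 1
  list(s = s, row = dLinmap(Ri, s), col = dLinmap(Rj, s))
}

#' Differentiable soft arg-min of a join-criterion matrix
#'
#' Relaxed selection of the minimal off-diagonal entry of a square matrix
#' `Q`, considering the upper triangle in row-major flattened order. Exact
#' ties are broken differentiably toward the first tied position via a
#' cumulative-sum weighting of the soft-sort output. At cold temperatures
#' the returned weights are numerically one-hot.
#'
#' @param Q square numeric matrix (m >= 2); only the off-diagonal upper
#'   triangle participates.
#' @param eta temperature, > 0.
#' @return list with `row_weights` and `col_weights`, non-negative vectors of
#'   length `m` each summing to one.
#' @export
softArgmin <- function(Q, eta) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) stop("eta must be > 0")
  if (!is.matrix(Q) || nrow(Q) != ncol(Q)) stop("Q must be a square matrix")
  m <- nrow(Q)
  if (m < 2) stop("Q must be at least 2 x 2")
  idx <- .pair_index(m)
  Qu <- Q[idx]
  if (any(!is.finite(Qu))) stop("upper triangle of Q must be finite")
  sel <- .soft_argmin_flat(Qu, eta, idx, m)
  list(row_weights = dualValue(sel$row), col_weights = dualValue(sel$col))
}

#' Neighbour-joining Q criterion
#'
#' The Studier-Keppler join criterion
#' `Q_ij = (m - 2) D_ij - sum_k D_ik - sum_k D_jk`, whose minimal entry
#' identifies the canonical pair to join. The diagonal is set to `+Inf`.
#'
#' @param D square distance matrix over the `m >= 3` active nodes.
#' @return `m x m` matrix with `+Inf` diagonal.
#' @export
njQMatrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be square")
  m <- nrow(D)
  if (m < 3) stop("need at least 3 active nodes")
  r <- rowSums(D)
  Q <- (m - 2) * D - outer(r, rep(1, m)) - outer(rep(1, m), r)
  diag(Q) <- Inf
  Q
}

# scatter an upper-triangle pair vector (row-major order) into the full
# flat (row-major) symmetric matrix with zero diagonal; dual-aware
.flat_from_pairs <- function(pairs, n) {
  idx <- .pair_index(n)
  tix <- matrix(0L, n, n)
  tix[idx] <- seq_len(nrow(idx))
  tix <- tix + t(tix)
  src <- dcat(pairs, 0)
  tflat <- as.vector(t(tix))
  tflat[tflat == 0L] <- nrow(idx) + 1L
  dIndex(src, tflat)
}

## --- the decoder ------------------------------------------------------------

# Dflat: full m0 x m0 distance matrix flattened row-major (dual or numeric).
# Returns edges (parent > n are internal), lengths aligned to edges, n.
.soft_nj_core <- function(Dflat, n, eta, floor_eps = 1e-6) {
  ids <- seq_len(n)        # active node ids (tips 1..n, internals n+1..)
  nextid <- n + 1L
  m <- n
  Dcur <- Dflat
  ep <- integer(0); ec <- integer(0)
  lens <- list()
  while (m > 3) {
    rs_map <- matrix(0, m, m * m)
    for (i in seq_len(m)) rs_map[i, (i - 1) * m + seq_len(m)] <- 1
    r <- dLinmap(rs_map, Dcur)
    idx <- .pair_index(m)
    fidx <- (idx[, 1] - 1) * m + idx[, 2]
    Q <- (m - 2) * dIndex(Dcur, fidx) - dIndex(r, idx[, 1]) - dIndex(r, idx[, 2])
    sel <- .soft_argmin_flat(Q, eta, idx, m)
    fstar <- which.max(dualValue(sel$s))
    istar <- idx[fstar, 1]; jstar <- idx[fstar, 2]
    w <- sel$row; cw <- sel$col
    wfull <- dIndex(w, rep(seq_len(m), each = m))    # weights by row index
    cfull <- dIndex(cw, rep.int(seq_len(m), m))      # weights by col index
    d_pair <- sum(Dcur * wfull * cfull)
    r_w <- sum(w * r); r_c <- sum(cw * r)
    li <- 0.5 * d_pair + (r_w - r_c) / (2 * (m - 2))
    lj <- d_pair - li
    # soft-agglomerated distances from the merged node to every active node
    cs_map <- matrix(0, m, m * m)
    for (k in seq_len(m)) cs_map[k, (seq_len(m) - 1) * m + k] <- 1
    Dw <- dLinmap(cs_map, Dcur * wfull)
    Dc <- dLinmap(cs_map, Dcur * dIndex(cw, rep(seq_len(m), each = m)))
    Dnew <- 0.5 * (Dw + Dc - d_pair)
    # bookkeeping is hard: drop the argmax pair, append the merged node
    ep <- c(ep, nextid, nextid)
    ec <- c(ec, ids[istar], ids[jstar])
    lens <- c(lens, list(li, lj))
    keep <- setdiff(seq_len(m), c(istar, jstar))
    m2 <- m - 1L
    oldpos <- as.vector(t(outer(keep, keep, function(a, b) (a - 1) * m + b)))
    src <- dcat(dIndex(Dcur, oldpos), dIndex(Dnew, keep), 0)
    nold <- (m2 - 1)^2
    tix <- integer(m2 * m2)
    for (a in seq_len(m2 - 1)) {
      tix[(a - 1) * m2 + seq_len(m2 - 1)] <- (a - 1) * (m2 - 1) + seq_len(m2 - 1)
      tix[(a - 1) * m2 + m2] <- nold + a                 # new column
      tix[(m2 - 1) * m2 + a] <- nold + a                 # new row
    }
    tix[m2 * m2] <- nold + m2                            # the zero diagonal
    Dcur <- dIndex(src, tix)
    ids <- c(ids[keep], nextid)
    nextid <- nextid + 1L
    m <- m2
  }
  # terminal 3-star: three-point formulas around a final hub
  f <- function(i, j) (i - 1) * 3 + j
  D12 <- dIndex(Dcur, f(1, 2)); D13 <- dIndex(Dcur, f(1, 3)); D23 <- dIndex(Dcur, f(2, 3))
  hub <- nextid
  ep <- c(ep, hub, hub, hub)
  ec <- c(ec, ids[1], ids[2], ids[3])
  lens <- c(lens, list(0.5 * (D12 + D13 - D23),
                       0.5 * (D12 + D23 - D13),
                       0.5 * (D13 + D23 - D12)))
  lengths <- dSmoothFloor(do.call(dcat, lens), eps = floor_eps)
  list(parent = ep, child = ec, lengths = lengths, n = n, hub = hub)
}

# convert the join record into an ape::phylo (hub = trifurcating root);
# returns the tree plus the permutation mapping phylo edges -> record edges
.assemble_phylo <- function(core, labels) {
  n <- core$n
  kids <- split(seq_along(core$parent), core$parent) # edge indices by parent
  nnode <- core$hub - n
  newid <- integer(core$hub)
  newid[seq_len(n)] <- seq_len(n)
  # preorder DFS from the hub, renumbering internal nodes n+1, n+2, ...
  cnt <- n
  edge <- matrix(0L, length(core$parent), 2)
  eorder <- integer(length(core$parent))
  k <- 0L
  visit <- function(node) {
    cnt <<- cnt + 1L
    newid[node] <<- cnt
    for (e in kids[[as.character(node)]]) {
      ch <- core$child[e]
      k <<- k + 1L
      eorder[k] <<- e
      if (ch > n) visit(ch)
    }
  }
  visit(core$hub)
  for (k2 in seq_along(eorder)) {
    e <- eorder[k2]
    edge[k2, ] <- c(newid[core$parent[e]], newid[core$child[e]])
  }
  lengths <- dIndex(core$lengths, eorder)
  phy <- list(edge = edge, edge.length = dualValue(lengths),
              tip.label = labels, Nnode = nnode)
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  list(tree = phy, lengths = lengths)
}

#' Decode a tree from a distance matrix by soft neighbour joining
#'
#' A differentiable relaxation of neighbour joining. At every agglomeration
#' step the pair to join is chosen by a temperature-`eta` soft arg-min of the
#' Q criterion ([njQMatrix]); the selected row/column are consumed as soft
#' weight vectors, so the joined pair's branch lengths (Saitou-Nei formulas)
#' and the merged node's distance row are weighted combinations of all active
#' rows. Gradients therefore flow from every entry of `D` into every branch
#' length. At `eta = 1e-5` the output coincides numerically with classical
#' neighbour joining (up to the branch-length floor); negative branch lengths
#' are clamped to `1e-6` through a smooth maximum.
#'
#' @param D symmetric non-negative distance matrix (`n >= 3`), zero diagonal.
#' @param eta temperature, > 0 (default `1e-5`: numerically hard selection).
#' @param labels taxon labels (default: `rownames(D)` or `t1..tn`).
#' @return object of class `softNJTree`: a list with `tree` (an unrooted
#'   `ape::phylo` with branch lengths, arbitrarily rooted at the final
#'   trifurcation) and `lengths` (branch lengths in `tree$edge` order).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
#' D <- ape::cophenetic.phylo(tr)
#' fit <- softNJDecode(D)
#' ape::write.tree(fit$tree)
#' @export
softNJDecode <- function(D, eta = 1e-5, labels = NULL) {
  if (!is.numeric(eta) || length(eta) != 1 || eta <= 0) stop("eta must be > 0")
  .check_dist_matrix(D)
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  core <- .soft_nj_core(as.vector(t(D)), n, eta)
  out <- .assemble_phylo(core, labels)
  structure(list(tree = out$tree, lengths = out$lengths, labels = labels,
                 eta = eta), class = "softNJTree")
}

#' @export
print.softNJTree <- function(x, ...) {
  cat(sprintf("softNJTree: %d tips, eta = %g\n", length(x$labels), x$eta))
  cat(ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Jacobian of soft-NJ branch lengths
#'
#' Decodes `D` with derivative tracking seeded at the upper-triangle entries
#' of `D`, returning the decoded tree and the Jacobian of its branch lengths
#' with respect to those entries.
#'
#' @inheritParams softNJDecode
#' @return list with `tree` (phylo), `lengths`, and `jacobian`, a
#'   `(2n-3) x (n(n-1)/2)` matrix (rows follow `tree$edge`; columns follow
#'   row-major upper-triangle order of `D`).
#' @export
softNJJacobian <- function(D, eta = 1e-5, labels = NULL) {
  .check_dist_matrix(D)
  n <- nrow(D)
  if (is.null(labels)) labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  idx <- .pair_index(n)
  Du <- dualSeed(D[idx])
  core <- .soft_nj_core(.flat_from_pairs(Du, n), n, eta)
  out <- .assemble_phylo(core, labels)
  list(tree = out$tree, lengths = dualValue(out$lengths),
       jacobian = t(dualGrad(out$lengths)))
}
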