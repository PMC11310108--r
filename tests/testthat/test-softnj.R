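# the differentiable neighbour-joining decoder

test_that("soft-sort permutation converges to the hard sort", {
  P <- softSortPermutation(c(3, 1, 2), 1e-6)
  expect_equal(P, rbind(c(1, 0, 0), c(0, 0, 1), c(0, 1, 0)), tolerance = 1e-8)
  # constant vector: every row uniform
  Pc <- softSortPermutation(c(2, 2, 2, 2), 0.1)
  expect_equal(Pc, matrix(0.25, 4, 4))
  # rows sum to one at any temperature
  set.seed(1)
  for (eta in c(1e-5, 0.1, 3)) {
    Pr <- softSortPermutation(rnorm(6), eta)
    expect_equal(rowSums(Pr), rep(1, 6), tolerance = 1e-9)
  }
  expect_error(softSortPermutation(c(1, 2), 0), "eta")
})

test_that("soft arg-min finds the minimum and breaks ties to the first", {
  Q <- matrix(Inf, 3, 3)
  Q[1, 2] <- 5; Q[1, 3] <- 2; Q[2, 3] <- 1
  sel <- softArgmin(Q, 1e-6)
  expect_equal(sel$row_weights, c(0, 1, 0), tolerance = 1e-4)
  expect_equal(sel$col_weights, c(0, 0, 1), tolerance = 1e-4)
  expect_equal(sum(sel$row_weights), 1, tolerance = 1e-6)
  expect_equal(sum(sel$col_weights), 1, tolerance = 1e-6)
  # exact ties at (1,3) and (2,3): first in row-major flattened order wins
  Qt <- matrix(0, 3, 3)
  Qt[1, 2] <- 5; Qt[1, 3] <- 1; Qt[2, 3] <- 1
  selt <- softArgmin(Qt, 1e-6)
  expect_equal(selt$row_weights, c(1, 0, 0), tolerance = 1e-4)
  expect_equal(selt$col_weights, c(0, 0, 1), tolerance = 1e-4)
  # permuting the tied entries moves the selection predictably
  Qt2 <- matrix(0, 3, 3)
  Qt2[1, 2] <- 1; Qt2[1, 3] <- 5; Qt2[2, 3] <- 1
  selt2 <- softArgmin(Qt2, 1e-6)
  expect_equal(selt2$row_weights, c(1, 0, 0), tolerance = 1e-4)
  expect_equal(selt2$col_weights, c(0, 1, 0), tolerance = 1e-4)
  expect_error(softArgmin(matrix(1), 0.1), "2 x 2")
})

test_that("soft arg-min weights are differentiable w.r.t. Q", {
  set.seed(7)
  n <- 4
  idx <- hypernj:::.pair_index(n)
  qv <- runif(nrow(idx), 0.5, 2)
  a <- rnorm(n); b <- rnorm(n)
  f <- function(q) {
    sel <- hypernj:::.soft_argmin_flat(q, 0.1, idx, n)
    sum(sel$row * a) + sum(sel$col * b)
  }
  g <- f(dualSeed(qv))
  expect_equal(as.numeric(dualGrad(g)),
               fdGrad(function(q) dualValue(f(q)), qv, h = 1e-6),
               tolerance = 1e-3)
})

test_that("Q criterion matches the brute-force double loop", {
  # m = 3: all off-diagonal entries equal
  D3 <- randomDistMatrix(3, seed = 2)
  Q3 <- njQMatrix(D3)
  off <- Q3[upper.tri(Q3)]
  expect_equal(max(off) - min(off), 0, tolerance = 1e-12)
  # 4-taxon additive matrix: arg-min pairs cherries
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D4 <- treePathDistances(tr)
  Q4 <- njQMatrix(D4)
  best <- which(Q4 == min(Q4), arr.ind = TRUE)
  pairs <- apply(best, 1, function(r) paste(sort(rownames(D4)[r]), collapse = ""))
  expect_true(all(pairs %in% c("AB", "CD")))
  # random m = 6 vs loop oracle
  D6 <- randomDistMatrix(6, seed = 3)
  Q6 <- njQMatrix(D6)
  for (i in 1:6) for (j in 1:6) {
    if (i == j) expect_equal(Q6[i, j], Inf) else
      expect_equal(Q6[i, j],
                   4 * D6[i, j] - sum(D6[i, ]) - sum(D6[j, ]), tolerance = 1e-12)
  }
})

test_that("decoding an additive metric recovers the generating tree exactly", {
  tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  D <- treePathDistances(tr)
  fit <- softNJDecode(D)
  expect_equal(rfDist(fit, tr), 0)
  expect_equal(sort(fit$tree$edge.length), c(1, 1, 2, 3, 4), tolerance = 1e-5)
  # n = 3: three-point formulas
  D3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  f3 <- softNJDecode(D3)
  bl <- setNames(f3$tree$edge.length,
                 f3$tree$tip.label[f3$tree$edge[, 2]])
  expect_equal(bl[["A"]], (2 + 3 - 4) / 2, tolerance = 1e-7)
  expect_equal(bl[["B"]], (2 + 4 - 3) / 2, tolerance = 1e-7)
  expect_equal(bl[["C"]], (3 + 4 - 2) / 2, tolerance = 1e-7)
  expect_error(softNJDecode(matrix(c(0, NA, NA, 0), 2, 2)), "finite")
})

test_that("cold-temperature soft-NJ equals independent classical NJ", {
  for (s in 1:20) {
    n <- 4 + (s %% 9)
    D <- randomDistMatrix(n, seed = 400 + s)
    fit <- softNJDecode(D, eta = 1e-5)
    ref <- hardNJ(D)
    expect_equal(rfDist(fit, ref), 0)
    expect_equal(splitLengths(fit$tree), splitLengths(ref), tolerance = 1e-6)
  }
})

test_that("branch-length Jacobian through soft-NJ matches finite differences", {
  n <- 5
  D <- randomDistMatrix(n, seed = 11, lo = 0.5, hi = 2)
  J <- softNJJacobian(D, eta = 0.1)
  idx <- hypernj:::.pair_index(n)
  h <- 1e-6
  for (f in seq_len(nrow(idx))) {
    Dp <- D; Dm <- D
    i <- idx[f, 1]; j <- idx[f, 2]
    Dp[i, j] <- Dp[j, i] <- Dp[i, j] + h
    Dm[i, j] <- Dm[j, i] <- Dm[i, j] - h
    fd <- (softNJDecode(Dp, eta = 0.1)$tree$edge.length -
             softNJDecode(Dm, eta = 0.1)$tree$edge.length) / (2 * h)
    expect_equal(J$jacobian[, f], fd, tolerance = 1e-3)
  }
})

test_that("gradients flow from distances into branch lengths at cold eta", {
  D <- treePathDistances(simulateTree(6, seed = 5))
  J <- softNJJacobian(D, eta = 1e-5)
  expect_gt(max(abs(J$jacobian)), 0.4) # nontrivial derivatives survive
  expect_true(all(is.finite(J$jacobian)))
})
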