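#' @title Forward-mode dual numbers
#'
#' @description
#' The package's automatic-differentiation engine. A `dual` carries a numeric
#' value vector together with its Jacobian with respect to a fixed set of
#' `p` seed variables, and (optionally) all second derivatives. Every
#' arithmetic operation propagates derivatives by the chain rule, so any
#' computation written in ordinary R arithmetic on duals yields exact
#' derivatives of its result -- this is what lets gradients flow from
#' embedding coordinates through soft-NJ into branch lengths and the
#' likelihood.
#'
#' Internals: `v` is the value (length `n`), `g` is a `p x n` matrix with
#' `g[a, i] = d v[i] / d seed[a]`, and `h` (second order only) is a
#' `(p*p) x n` matrix with `h[a + (b-1)*p, i] = d^2 v[i] / d seed[a] d seed[b]`.
#'
#' @param v numeric vector of values at which to seed.
#' @param order 1 for first derivatives only, 2 to also propagate Hessians.
#' @return `dualSeed` returns a `dual` whose seed variables are the elements
#'   of `v` themselves (identity Jacobian).
#' @examples
#' x <- dualSeed(c(1, 2))
#' y <- sum(x^2)
#' dualValue(y)  # 5
#' dualGrad(y)   # c(2, 4)
#' @export
dualSeed <- function(v, order = 1) {
  stopifnot(is.numeric(v), length(v) >= 1L, order %in% c(1, 2))
  p <- length(v)
  g <- diag(1, p, p)
  h <- if (order == 2) matrix(0, p * p, p) else NULL
  newDual(as.numeric(v), g, h)
}

newDual <- function(v, g, h = NULL) {
  structure(list(v = v, g = g, h = h), class = "dual")
}

isDual <- function(x) inherits(x, "dual")

#' @rdname dualSeed
#' @param x a `dual` (or plain numeric, returned unchanged by `dualValue`).
#' @export
dualValue <- function(x) if (isDual(x)) x$v else x

#' @rdname dualSeed
#' @details `dualGrad` returns the `p x n` matrix of first derivatives
#'   (seed variables in rows, elements of `x` in columns); for a vector-valued
#'   `x` its transpose is the usual Jacobian.
#' @export
dualGrad <- function(x) {
  stopifnot(isDual(x))
  x$g
}

#' @rdname dualSeed
#' @param i element index whose `p x p` Hessian to extract.
#' @export
dualHessian <- function(x, i = 1L) {
  stopifnot(isDual(x), !is.null(x$h))
  p <- nrow(x$g)
  matrix(x$h[, i], p, p)
}

#' @export
length.dual <- function(x) length(x$v)

#' @export
print.dual <- function(x, ...) {
  cat(sprintf("<dual> length %d, %d seed(s), order %d\n",
              length(x$v), nrow(x$g), if (is.null(x$h)) 1L else 2L))
  cat("values: ", paste(signif(utils::head(x$v, 8), 6), collapse = " "),
      if (length(x$v) > 8) "...", "\n")
  invisible(x)
}

#' @export
`[.dual` <- function(x, i) {
  newDual(x$v[i], x$g[, i, drop = FALSE],
          if (!is.null(x$h)) x$h[, i, drop = FALSE])
}

## --- internal helpers -------------------------------------------------------

# recycle a dual of length 1 to length n
.d_expand <- function(x, n) {
  if (length(x$v) == n) return(x)
  stopifnot(length(x$v) == 1L)
  newDual(rep.int(x$v, n), x$g[, rep.int(1L, n), drop = FALSE],
          if (!is.null(x$h)) x$h[, rep.int(1L, n), drop = FALSE])
}

# elementwise outer product term: out[a + (b-1)p, i] = ga[a,i] * gb[b,i]
.d_outer <- function(ga, gb) {
  p <- nrow(ga)
  ga[rep.int(seq_len(p), p), , drop = FALSE] *
    gb[rep(seq_len(p), each = p), , drop = FALSE]
}

# scale rows of g (p x n) by value vector v (length n)
.d_rowscale <- function(g, v) g * rep(v, each = nrow(g))

## --- arithmetic -------------------------------------------------------------

#' @export
Ops.dual <- function(e1, e2) {
  if (missing(e2)) { # unary + / -
    if (.Generic == "+") return(e1)
    if (.Generic == "-")
      return(newDual(-e1$v, -e1$g, if (!is.null(e1$h)) -e1$h))
    stop("unsupported unary operator for dual: ", .Generic)
  }
  if (.Generic %in% c("==", "!=", "<", "<=", ">", ">="))
    return(get(.Generic)(dualValue(e1), dualValue(e2)))

  d1 <- isDual(e1); d2 <- isDual(e2)
  n <- max(if (d1) length(e1$v) else length(e1),
           if (d2) length(e2$v) else length(e2))
  if (d1) e1 <- .d_expand(e1, n) else e1 <- rep_len(as.numeric(e1), n)
  if (d2) e2 <- .d_expand(e2, n) else e2 <- rep_len(as.numeric(e2), n)

  switch(.Generic,
    "+" = {
      if (d1 && d2) newDual(e1$v + e2$v, e1$g + e2$g,
                            if (!is.null(e1$h) && !is.null(e2$h)) e1$h + e2$h)
      else if (d1) newDual(e1$v + e2, e1$g, e1$h)
      else         newDual(e1 + e2$v, e2$g, e2$h)
    },
    "-" = {
      if (d1 && d2) newDual(e1$v - e2$v, e1$g - e2$g,
                            if (!is.null(e1$h) && !is.null(e2$h)) e1$h - e2$h)
      else if (d1) newDual(e1$v - e2, e1$g, e1$h)
      else         newDual(e1 - e2$v, -e2$g, if (!is.null(e2$h)) -e2$h)
    },
    "*" = {
      if (d1 && d2) {
        h <- if (!is.null(e1$h) && !is.null(e2$h))
          .d_rowscale(e1$h, e2$v) + .d_rowscale(e2$h, e1$v) +
            .d_outer(e1$g, e2$g) + .d_outer(e2$g, e1$g)
        newDual(e1$v * e2$v,
                .d_rowscale(e1$g, e2$v) + .d_rowscale(e2$g, e1$v), h)
      } else if (d1) {
        newDual(e1$v * e2, .d_rowscale(e1$g, e2),
                if (!is.null(e1$h)) .d_rowscale(e1$h, e2))
      } else {
        newDual(e1 * e2$v, .d_rowscale(e2$g, e1),
                if (!is.null(e2$h)) .d_rowscale(e2$h, e1))
      }
    },
    "/" = {
      if (d2) e1 * .d_recip(e2)
      else newDual(e1$v / e2, .d_rowscale(e1$g, 1 / e2),
                   if (!is.null(e1$h)) .d_rowscale(e1$h, 1 / e2))
    },
    "^" = {
      if (d1 && !d2) {
        if (length(unique(e2)) == 1L) .d_pow(e1, e2[1L])
        else exp(e2 * log(e1))
      } else exp(e2 * log(e1))
    },
    stop("unsupported operator for dual: ", .Generic)
  )
}

# unary smooth function: v -> f(v) with derivatives fp, fpp (functions of v)
.d_unary <- function(x, f, fp, fpp = NULL) {
  v <- x$v
  fv <- f(v); fpv <- fp(v)
  g <- .d_rowscale(x$g, fpv)
  h <- NULL
  if (!is.null(x$h)) {
    stopifnot(!is.null(fpp))
    h <- .d_rowscale(x$h, fpv) + .d_rowscale(.d_outer(x$g, x$g), fpp(v))
  }
  newDual(fv, g, h)
}

.d_recip <- function(x)
  .d_unary(x, function(v) 1 / v, function(v) -1 / v^2, function(v) 2 / v^3)

.d_pow <- function(x, k) {
  if (k == 2)
    return(.d_unary(x, function(v) v^2, function(v) 2 * v, function(v) rep(2, length(v))))
  .d_unary(x, function(v) v^k, function(v) k * v^(k - 1),
           function(v) k * (k - 1) * v^(k - 2))
}

#' @export
Math.dual <- function(x, ...) {
  switch(.Generic,
    exp   = .d_unary(x, exp, exp, exp),
    log   = .d_unary(x, log, function(v) 1 / v, function(v) -1 / v^2),
    log1p = .d_unary(x, log1p, function(v) 1 / (1 + v), function(v) -1 / (1 + v)^2),
    sqrt  = .d_unary(x, sqrt, function(v) 0.5 / sqrt(v),
                     function(v) -0.25 / v^1.5),
    cosh  = .d_unary(x, cosh, sinh, cosh),
    sinh  = .d_unary(x, sinh, cosh, sinh),
    tanh  = .d_unary(x, tanh, function(v) 1 / cosh(v)^2,
                     function(v) -2 * tanh(v) / cosh(v)^2),
    acosh = .d_unary(x, acosh, function(v) 1 / sqrt(v^2 - 1),
                     function(v) -v / (v^2 - 1)^1.5),
    abs   = .d_unary(x, abs, sign, function(v) rep(0, length(v))),
    stop("unsupported math function for dual: ", .Generic)
  )
}

#' @export
Summary.dual <- function(..., na.rm = FALSE) {
  xs <- list(...)
  stopifnot(length(xs) == 1L)
  x <- xs[[1L]]
  switch(.Generic,
    sum = newDual(sum(x$v), as.matrix(rowSums(x$g)),
                  if (!is.null(x$h)) as.matrix(rowSums(x$h))),
    max = x[which.max(x$v)],
    min = x[which.min(x$v)],
    stop("unsupported summary function for dual: ", .Generic)
  )
}

## --- vector utilities used throughout the pipeline --------------------------

# concatenate duals and numerics into one dual (numerics get zero derivatives)
dcat <- function(...) {
  xs <- list(...)
  dx <- Filter(isDual, xs)
  if (length(dx) == 0L) return(unlist(xs))
  p <- nrow(dx[[1L]]$g)
  ord2 <- !is.null(dx[[1L]]$h)
  vs <- lapply(xs, dualValue)
  gs <- lapply(xs, function(x) if (isDual(x)) x$g else matrix(0, p, length(x)))
  h <- NULL
  if (ord2) {
    hs <- lapply(xs, function(x) if (isDual(x)) x$h else matrix(0, p * p, length(x)))
    h <- do.call(cbind, hs)
  }
  newDual(unlist(vs, use.names = FALSE), do.call(cbind, gs), h)
}

# linear map y = A %*% x for dual or numeric x (A numeric)
dLinmap <- function(A, x) {
  if (!isDual(x)) return(as.numeric(A %*% x))
  newDual(as.numeric(A %*% x$v), tcrossprod(x$g, A),
          if (!is.null(x$h)) tcrossprod(x$h, A))
}

dCumsum <- function(x) {
  if (!isDual(x)) return(cumsum(x))
  n <- length(x$v)
  newDual(cumsum(x$v), t(apply(x$g, 1L, cumsum)),
          if (!is.null(x$h)) t(apply(x$h, 1L, cumsum)))
}

dIndex <- function(x, i) if (isDual(x)) x[i] else x[i]

# hard lower clamp: values below `lo` are pinned (zero derivative there)
dClampMin <- function(x, lo) {
  if (!isDual(x)) return(pmax(x, lo))
  low <- x$v < lo
  if (!any(low)) return(x)
  v <- x$v; v[low] <- lo
  g <- x$g; g[, low] <- 0
  h <- x$h
  if (!is.null(h)) h[, low] <- 0
  newDual(v, g, h)
}

# smooth maximum with a floor: ~ max(x, eps), C^inf, distortion O(delta)
dSmoothFloor <- function(x, eps = 1e-6, delta = 1e-16) {
  0.5 * (x + eps + sqrt((x - eps)^2 + delta))
}

# temperature softmax, invariant shift by the (hard) max value
dSoftmax <- function(x, eta) {
  m <- max(dualValue(x))
  e <- exp((x - m) / eta)
  e / sum(e)
}

# log-sum-exp for numeric vectors
logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
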