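# Reverse-mode automatic differentiation on dense matrices.
#
# Every value is a numeric matrix; a node is an environment holding the
# forward value, an accumulated gradient, its parent nodes and a backward
# function that distributes the incoming gradient to the parents.  Nodes are
# recorded on a tape in creation order, so the reverse of the tape is a valid
# topological order for backpropagation.  Parameters (`ag_param`) live off
# the tape and persist across training steps; their gradients accumulate
# until the optimizer clears them.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$n <- 0L

#' Start a fresh autodiff tape
#'
#' Clears the graph recorded by subsequent tensor operations.  Call once per
#' forward pass; parameters created with [ag_param()] survive resets.
#'
#' @return Invisibly, `NULL`.
#' @keywords internal
ag_reset <- function() {
  .ag$tape <- vector("list", 256L)
  .ag$n <- 0L
  invisible(NULL)
}

ag_record <- function(node) {
  n <- .ag$n + 1L
  if (n > length(.ag$tape)) {
    .ag$tape <- c(.ag$tape, vector("list", length(.ag$tape)))
  }
  .ag$tape[[n]] <- node
  .ag$n <- n
  node
}

new_ag_node <- function(val, parents = list(), backfn = NULL, tracked = FALSE) {
  node <- new.env(parent = emptyenv())
  node$val <- val
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$tracked <- tracked
  class(node) <- "ag_node"
  if (tracked && !is.null(backfn)) ag_record(node)
  node
}

#' Create a trainable parameter
#'
#' @param val Numeric matrix (or vector, coerced to a 1-row matrix).
#' @return An `ag_node` marked as tracked, living off the tape.
#' @keywords internal
ag_param <- function(val) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  new_ag_node(val, tracked = TRUE)
}

#' Wrap a constant (non-differentiated) value
#' @param val Numeric matrix or vector.
#' @return An untracked `ag_node`.
#' @keywords internal
ag_const <- function(val) {
  if (!is.matrix(val)) val <- matrix(val, nrow = 1L)
  new_ag_node(val, tracked = FALSE)
}

ag_is <- function(x) inherits(x, "ag_node")

ag_acc <- function(node, g) {
  if (!isTRUE(node$tracked)) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ag_tracked_any <- function(...) {
  for (p in list(...)) if (isTRUE(p$tracked)) return(TRUE)
  FALSE
}

#' Backpropagate from a scalar loss node
#'
#' @param loss An `ag_node` holding a 1x1 matrix.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(ag_is(loss), length(loss$val) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  if (.ag$n == 0L) return(invisible(NULL))
  for (i in seq(.ag$n, 1L)) {
    node <- .ag$tape[[i]]
    if (!is.null(node$grad) && !is.null(node$backfn)) {
      node$backfn(node$grad)
    }
  }
  invisible(NULL)
}

# ---- primitive operations ---------------------------------------------------

ag_mm <- function(a, b) {
  val <- a$val %*% b$val
  new_ag_node(val, list(a, b), tracked = ag_tracked_any(a, b),
              backfn = function(g) {
                ag_acc(a, g %*% t(b$val))
                ag_acc(b, crossprod(a$val, g))
              })
}

# a %*% t(b)
ag_mm_t <- function(a, b) {
  val <- tcrossprod(a$val, b$val)
  new_ag_node(val, list(a, b), tracked = ag_tracked_any(a, b),
              backfn = function(g) {
                ag_acc(a, g %*% b$val)
                ag_acc(b, crossprod(g, a$val))
              })
}

# Addition with row-vector (bias) or 1x1 broadcast on either side.
ag_add <- function(a, b) {
  av <- a$val; bv <- b$val
  val <- if (identical(dim(av), dim(bv))) {
    av + bv
  } else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) {
    sweep(av, 2L, as.vector(bv), "+")
  } else if (length(bv) == 1L) {
    av + as.vector(bv)
  } else if (nrow(av) == 1L && ncol(av) == ncol(bv)) {
    sweep(bv, 2L, as.vector(av), "+")
  } else if (length(av) == 1L) {
    bv + as.vector(av)
  } else stop("ag_add: incompatible shapes")
  new_ag_node(val, list(a, b), tracked = ag_tracked_any(a, b),
              backfn = function(g) {
                for (p in list(a, b)) {
                  pv <- p$val
                  if (identical(dim(pv), dim(g))) ag_acc(p, g)
                  else if (length(pv) == 1L) ag_acc(p, matrix(sum(g), 1L, 1L))
                  else ag_acc(p, matrix(colSums(g), 1L))
                }
              })
}

ag_sub <- function(a, b) ag_add(a, ag_scale(b, -1))

# Elementwise product; b may be same shape, a 1-column vector broadcast
# across columns of a, or a 1x1 scalar.
ag_mul <- function(a, b) {
  av <- a$val; bv <- b$val
  mode <- if (identical(dim(av), dim(bv))) "same"
          else if (ncol(bv) == 1L && nrow(bv) == nrow(av)) "col"
          else if (length(bv) == 1L) "scalar"
          else stop("ag_mul: incompatible shapes")
  val <- switch(mode,
                same = av * bv,
                col = av * as.vector(bv),
                scalar = av * as.vector(bv))
  new_ag_node(val, list(a, b), tracked = ag_tracked_any(a, b),
              backfn = function(g) {
                if (mode == "same") {
                  ag_acc(a, g * bv); ag_acc(b, g * av)
                } else if (mode == "col") {
                  ag_acc(a, g * as.vector(bv))
                  ag_acc(b, matrix(rowSums(g * av), ncol = 1L))
                } else {
                  ag_acc(a, g * as.vector(bv))
                  ag_acc(b, matrix(sum(g * av), 1L, 1L))
                }
              })
}

ag_scale <- function(a, k) {
  new_ag_node(a$val * k, list(a), tracked = a$tracked,
              backfn = function(g) ag_acc(a, g * k))
}

ag_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-a$val))
  new_ag_node(s, list(a), tracked = a$tracked,
              backfn = function(g) ag_acc(a, g * s * (1 - s)))
}

ag_tanh <- function(a) {
  s <- tanh(a$val)
  new_ag_node(s, list(a), tracked = a$tracked,
              backfn = function(g) ag_acc(a, g * (1 - s * s)))
}

ag_relu <- function(a) {
  s <- a$val
  mask <- s > 0
  s[!mask] <- 0
  new_ag_node(s, list(a), tracked = a$tracked,
              backfn = function(g) ag_acc(a, g * mask))
}

# Row-wise softmax.
ag_softmax_rows <- function(a) {
  x <- a$val
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  s <- e / rowSums(e)
  new_ag_node(s, list(a), tracked = a$tracked,
              backfn = function(g) {
                ag_acc(a, s * (g - rowSums(g * s)))
              })
}

# Row-wise log-softmax.
ag_log_softmax_rows <- function(a) {
  x <- a$val
  m <- apply(x, 1L, max)
  lse <- m + log(rowSums(exp(x - m)))
  val <- x - lse
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                ag_acc(a, g - exp(val) * rowSums(g))
              })
}

# Summed cross-entropy of target ids under row logits (fused with softmax).
ag_ce_rows <- function(logits, targets) {
  x <- logits$val
  n <- nrow(x)
  stopifnot(length(targets) == n)
  m <- apply(x, 1L, max)
  lse <- m + log(rowSums(exp(x - m)))
  logp <- x - lse
  val <- matrix(-sum(logp[cbind(seq_len(n), targets)]), 1L, 1L)
  new_ag_node(val, list(logits), tracked = logits$tracked,
              backfn = function(g) {
                P <- exp(logp)
                P[cbind(seq_len(n), targets)] <-
                  P[cbind(seq_len(n), targets)] - 1
                ag_acc(logits, P * as.vector(g))
              })
}

# Row gather; idx == 0 yields a zero row (used for zero padding).
ag_rows <- function(a, idx) {
  av <- a$val
  val <- matrix(0, length(idx), ncol(av))
  sel <- idx > 0L
  if (any(sel)) val[sel, ] <- av[idx[sel], , drop = FALSE]
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                if (!any(sel)) return(invisible(NULL))
                agg <- rowsum(g[sel, , drop = FALSE], group = idx[sel])
                out <- matrix(0, nrow(av), ncol(av))
                out[as.integer(rownames(agg)), ] <- agg
                ag_acc(a, out)
              })
}

# Column selection.
ag_cols <- function(a, idx) {
  av <- a$val
  val <- av[, idx, drop = FALSE]
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                out <- matrix(0, nrow(av), ncol(av))
                out[, idx] <- out[, idx] + g
                ag_acc(a, out)
              })
}

ag_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  val <- do.call(cbind, vals)
  ncols <- vapply(vals, ncol, 1L)
  ends <- cumsum(ncols)
  starts <- ends - ncols + 1L
  tracked <- any(vapply(nodes, function(n) isTRUE(n$tracked), TRUE))
  new_ag_node(val, nodes, tracked = tracked,
              backfn = function(g) {
                for (i in seq_along(nodes)) {
                  ag_acc(nodes[[i]], g[, starts[i]:ends[i], drop = FALSE])
                }
              })
}

ag_rbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$val)
  val <- do.call(rbind, vals)
  nrows <- vapply(vals, nrow, 1L)
  ends <- cumsum(nrows)
  starts <- ends - nrows + 1L
  tracked <- any(vapply(nodes, function(n) isTRUE(n$tracked), TRUE))
  new_ag_node(val, nodes, tracked = tracked,
              backfn = function(g) {
                for (i in seq_along(nodes)) {
                  ag_acc(nodes[[i]], g[starts[i]:ends[i], , drop = FALSE])
                }
              })
}

# (B*N, 1) sample-major column -> (B, N) matrix, one row per sample.
ag_regroup <- function(a, N) {
  v <- as.vector(a$val)
  B <- length(v) %/% N
  val <- t(matrix(v, nrow = N, ncol = B))
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                ag_acc(a, matrix(as.vector(t(g)), ncol = 1L))
              })
}

# (B, N) matrix -> (B*N, 1) sample-major column; inverse of ag_regroup.
ag_flatten_rows <- function(a) {
  val <- matrix(as.vector(t(a$val)), ncol = 1L)
  N <- ncol(a$val); B <- nrow(a$val)
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                ag_acc(a, t(matrix(as.vector(g), nrow = N, ncol = B)))
              })
}

ag_sum_nodes <- function(nodes) {
  val <- Reduce(`+`, lapply(nodes, function(n) n$val))
  tracked <- any(vapply(nodes, function(n) isTRUE(n$tracked), TRUE))
  new_ag_node(val, nodes, tracked = tracked,
              backfn = function(g) for (n in nodes) ag_acc(n, g))
}

# Row-wise layer normalization with learned gain/offset (1 x d each).
ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  x <- a$val
  d <- ncol(x)
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  val <- sweep(xhat * rep(as.vector(gamma$val), each = nrow(x)), 2L,
               as.vector(beta$val), "+")
  new_ag_node(val, list(a, gamma, beta),
              tracked = ag_tracked_any(a, gamma, beta),
              backfn = function(g) {
                ag_acc(beta, matrix(colSums(g), 1L))
                ag_acc(gamma, matrix(colSums(g * xhat), 1L))
                dxhat <- g * rep(as.vector(gamma$val), each = nrow(g))
                dx <- (dxhat - rowMeans(dxhat) -
                         xhat * rowMeans(dxhat * xhat)) * inv
                ag_acc(a, dx)
              })
}

# Inverted dropout; identity when training = FALSE or p = 0.
ag_dropout <- function(a, p, training) {
  if (!training || p <= 0) return(a)
  mask <- matrix(stats::rbinom(length(a$val), 1L, 1 - p), nrow(a$val)) /
    (1 - p)
  new_ag_node(a$val * mask, list(a), tracked = a$tracked,
              backfn = function(g) ag_acc(a, g * mask))
}

# Column-wise maximum: (n, k) -> (1, k); gradient flows to the first
# maximizing row of each column.
ag_max_cols <- function(a) {
  x <- a$val
  am <- apply(x, 2L, which.max)
  val <- matrix(x[cbind(am, seq_len(ncol(x)))], 1L)
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                out <- x * 0
                out[cbind(am, seq_len(ncol(x)))] <- as.vector(g)
                ag_acc(a, out)
              })
}

# Row-major vectorization: (n, m) -> (1, n*m).
ag_vec_row <- function(a) {
  n <- nrow(a$val); m <- ncol(a$val)
  val <- matrix(as.vector(t(a$val)), 1L)
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                ag_acc(a, t(matrix(as.vector(g), m, n)))
              })
}

# Column-wise log-sum-exp: (n, k) -> (1, k).  Smooth maximum over rows,
# used for multi-instance pooling of per-location logits.
ag_logsumexp_cols <- function(a) {
  x <- a$val
  m <- apply(x, 2L, max)
  val <- matrix(m + log(colSums(exp(sweep(x, 2L, m)))), 1L)
  new_ag_node(val, list(a), tracked = a$tracked,
              backfn = function(g) {
                sm <- exp(sweep(x, 2L, as.vector(val)))
                ag_acc(a, sweep(sm, 2L, as.vector(g), "*"))
              })
}

# Summed binary cross-entropy with logits against a 0/1 target matrix.
ag_bce_logits <- function(logits, targets) {
  x <- logits$val
  val <- matrix(sum(pmax(x, 0) - x * targets + log1p(exp(-abs(x)))), 1L, 1L)
  new_ag_node(val, list(logits), tracked = logits$tracked,
              backfn = function(g) {
                ag_acc(logits, (1 / (1 + exp(-x)) - targets) * as.vector(g))
              })
}

# ---- optimizer --------------------------------------------------------------

#' Initialize Adam optimizer state for a list of parameters
#' @param params Named list of `ag_node` parameters.
#' @keywords internal
ag_adam_init <- function(params) {
  st <- list(t = 0L,
             m = lapply(params, function(p) p$val * 0),
             v = lapply(params, function(p) p$val * 0))
  st
}

#' One Adam update step with optional global-norm gradient clipping
#'
#' @param params Named list of parameters (gradients accumulated in-place).
#' @param state State from [ag_adam_init()].
#' @param lr Learning rate.
#' @param clip Global gradient-norm threshold; gradients whose joint norm
#'   exceeds it are rescaled.  `NULL` disables clipping; `0` zeroes all
#'   gradients (parameters then never move).
#' @param beta1,beta2,eps Adam moment decays and stabilizer.
#' @keywords internal
ag_adam_step <- function(params, state, lr, clip = NULL,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  grads <- lapply(params, function(p) {
    if (is.null(p$grad)) p$val * 0 else p$grad
  })
  if (!is.null(clip)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
    if (gn > clip) {
      sc <- if (gn > 0) clip / gn else 0
      grads <- lapply(grads, function(g) g * sc)
    }
  }
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in seq_along(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g * g
    mhat <- state$m[[k]] / b1t
    vhat <- state$v[[k]] / b2t
    params[[k]]$val <- params[[k]]$val - lr * mhat / (sqrt(vhat) + eps)
    params[[k]]$grad <- NULL
  }
  state
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Glorot-uniform initial weights.
ag_init_w <- function(nin, nout, rng_sd = NULL) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
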