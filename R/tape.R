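# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Every value on the tape is a base-R matrix (scalars are 1x1). An operation
# pushes a node holding its value, the ids of its parents and a closure that
# maps the incoming gradient to per-parent gradients. `tape_backward()` walks
# the tape once in reverse topological (= insertion) order. This is all the
# machinery the message-passing encoder and the task heads need; graphs at
# desk scale are small enough that dense aggregation matrices are faster in R
# than sparse ones.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- vector("list", 512L)
  tp$parents <- vector("list", 512L)
  tp$backfn <- vector("list", 512L)
  tp$pmap <- list()
  tp
}

.tp_push <- function(tp, value, parents = integer(0), backfn = NULL) {
  id <- tp$n + 1L
  tp$n <- id
  tp$vals[[id]] <- value
  tp$parents[[id]] <- parents
  if (!is.null(backfn)) tp$backfn[[id]] <- backfn
  id
}

tp_value <- function(tp, id) tp$vals[[id]]

tp_const <- function(tp, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  .tp_push(tp, value)
}

tp_param <- function(tp, name, value) {
  if (!is.matrix(value)) value <- matrix(value, nrow = 1L)
  id <- .tp_push(tp, value)
  tp$pmap[[name]] <- id
  id
}

tp_mm <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tp_push(tp, A %*% B, c(a, b), function(g) list(g %*% t(B), crossprod(A, g)))
}

# Multiply by a constant (non-differentiated) matrix on the left: S %*% X.
# This is the neighborhood aggregation primitive.
tp_agg <- function(tp, S, x) {
  force(x)
  X <- tp$vals[[x]]
  .tp_push(tp, S %*% X, x, function(g) list(crossprod(S, g)))
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tp_push(tp, A + B, c(a, b), function(g) list(g, g))
}

# matrix (n x d) + bias (1 x d), broadcast over rows
tp_add_bias <- function(tp, a, bias) {
  force(a); force(bias)
  A <- tp$vals[[a]]; B <- tp$vals[[bias]]
  .tp_push(tp, sweep(A, 2L, as.vector(B), "+"), c(a, bias),
           function(g) list(g, matrix(colSums(g), 1L)))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tp_push(tp, A - B, c(a, b), function(g) list(g, -g))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tp_push(tp, A * B, c(a, b), function(g) list(g * B, g * A))
}

tp_div <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  .tp_push(tp, A / B, c(a, b), function(g) list(g / B, -g * A / (B * B)))
}

tp_scale <- function(tp, a, k) {
  force(a)
  A <- tp$vals[[a]]
  .tp_push(tp, A * k, a, function(g) list(g * k))
}

tp_gather <- function(tp, x, idx) {
  force(x)
  X <- tp$vals[[x]]
  n <- nrow(X)
  .tp_push(tp, X[idx, , drop = FALSE], x, function(g) {
    Z <- matrix(0, n, ncol(g))
    acc <- rowsum(g, group = idx)
    Z[as.integer(rownames(acc)), ] <- acc
    list(Z)
  })
}

tp_concat <- function(tp, ids) {
  force(ids)
  vals <- lapply(ids, function(i) tp$vals[[i]])
  widths <- vapply(vals, ncol, integer(1))
  .tp_push(tp, do.call(cbind, vals), as.integer(ids), function(g) {
    out <- vector("list", length(widths))
    at <- 0L
    for (k in seq_along(widths)) {
      out[[k]] <- g[, at + seq_len(widths[k]), drop = FALSE]
      at <- at + widths[k]
    }
    out
  })
}

tp_transpose <- function(tp, a) {
  force(a)
  .tp_push(tp, t(tp$vals[[a]]), a, function(g) list(t(g)))
}

tp_leaky_relu <- function(tp, a, alpha = 0.01) {
  force(a)
  A <- tp$vals[[a]]
  slope <- ifelse(A > 0, 1, alpha)
  .tp_push(tp, A * slope, a, function(g) list(g * slope))
}

tp_tanh <- function(tp, a) {
  force(a)
  V <- tanh(tp$vals[[a]])
  .tp_push(tp, V, a, function(g) list(g * (1 - V * V)))
}

tp_sigmoid <- function(tp, a) {
  force(a)
  V <- 1 / (1 + exp(-tp$vals[[a]]))
  .tp_push(tp, V, a, function(g) list(g * V * (1 - V)))
}

tp_exp <- function(tp, a) {
  force(a)
  V <- exp(tp$vals[[a]])
  .tp_push(tp, V, a, function(g) list(g * V))
}

tp_square <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tp_push(tp, A * A, a, function(g) list(2 * g * A))
}

# log(1 + exp(x)), computed stably; gradient is sigmoid(x)
tp_softplus <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  V <- ifelse(A > 30, A, log1p(exp(pmin(A, 30))))
  .tp_push(tp, V, a, function(g) list(g / (1 + exp(-A))))
}

tp_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  .tp_push(tp, matrix(sum(A), 1L, 1L), a,
           function(g) list(matrix(g[1L], nrow(A), ncol(A))))
}

tp_mean <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  n <- length(A)
  .tp_push(tp, matrix(mean(A), 1L, 1L), a,
           function(g) list(matrix(g[1L] / n, nrow(A), ncol(A))))
}

# column-wise maximum over rows -> 1 x d (global max pooling)
tp_colmax <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  which_row <- max.col(t(A), ties.method = "first")
  V <- matrix(A[cbind(which_row, seq_len(ncol(A)))], 1L)
  .tp_push(tp, V, a, function(g) {
    Z <- matrix(0, nrow(A), ncol(A))
    Z[cbind(which_row, seq_len(ncol(A)))] <- as.vector(g)
    list(Z)
  })
}

# Inverted dropout with a fixed Bernoulli mask; identity when not training.
tp_dropout <- function(tp, a, p, training) {
  force(a)
  if (!training || p <= 0) return(a)
  A <- tp$vals[[a]]
  mask <- matrix(stats::rbinom(length(A), 1L, 1 - p), nrow(A)) / (1 - p)
  .tp_push(tp, A * mask, a, function(g) list(g * mask))
}

# Reverse sweep from `out_id` (a scalar loss unless seed gradient given).
# Returns gradients for every registered parameter (zero-shaped NULLs are
# filled with zeros so optimizer code can rely on the full set), and the
# full per-node gradient list when `all_nodes = TRUE`.
tape_backward <- function(tp, out_id, all_nodes = FALSE) {
  grads <- vector("list", tp$n)
  v <- tp$vals[[out_id]]
  grads[[out_id]] <- matrix(1, nrow(v), ncol(v))
  for (id in seq(tp$n, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    bf <- tp$backfn[[id]]
    if (is.null(bf)) next
    pg <- bf(g)
    ps <- tp$parents[[id]]
    for (k in seq_along(ps)) {
      if (is.null(pg[[k]])) next
      pid <- ps[k]
      grads[[pid]] <- if (is.null(grads[[pid]])) pg[[k]] else grads[[pid]] + pg[[k]]
    }
  }
  if (all_nodes) return(grads)
  out <- vector("list", length(tp$pmap))
  names(out) <- names(tp$pmap)
  for (nm in names(tp$pmap)) {
    id <- tp$pmap[[nm]]
    g <- grads[[id]]
    if (is.null(g)) {
      val <- tp$vals[[id]]
      g <- matrix(0, nrow(val), ncol(val))
    }
    out[[nm]] <- g
  }
  out
}
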