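# Minimal tape-based reverse-mode automatic differentiation.
#
# Every differentiable quantity is a node on a tape; ops append nodes whose
# parents always carry smaller ids, so the reverse sweep is a simple
# backwards loop. Values are dense base-R matrices or numeric vectors; ops
# are matrix-level (BLAS-backed), so tapes stay short (~10^2 nodes per
# training step) and the engine overhead is negligible next to the matmuls.
# Internal API: not exported.

tp_new <- function(prealloc = 256L) {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$vals <- vector("list", prealloc)
  tp$backfns <- vector("list", prealloc)
  tp$parents <- vector("list", prealloc)
  tp
}

tp_push <- function(tp, value, parents = NULL, backfn = NULL) {
  # force args before claiming an id: nested op calls in an argument
  # position would otherwise push nodes under this node's id
  force(value); force(parents); force(backfn)
  i <- tp$n + 1L
  if (i > length(tp$vals)) {
    grow <- length(tp$vals)
    tp$vals <- c(tp$vals, vector("list", grow))
    tp$backfns <- c(tp$backfns, vector("list", grow))
    tp$parents <- c(tp$parents, vector("list", grow))
  }
  tp$vals[[i]] <- value
  tp$parents[[i]] <- parents
  tp$backfns[[i]] <- backfn
  tp$n <- i
  i
}

tp_val <- function(tp, id) tp$vals[[id]]

# leaf: parameter or input constant
tp_leaf <- function(tp, value) tp_push(tp, value)

# Push a (possibly nested) named list of numeric arrays as leaves; returns a
# structure of node ids mirroring the input.
tp_leaves <- function(tp, plist) {
  lapply(plist, function(x) {
    if (is.list(x)) tp_leaves(tp, x) else tp_leaf(tp, x)
  })
}

## ---- ops -------------------------------------------------------------

tp_matmul <- function(tp, a, b, transa = FALSE, transb = FALSE) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  val <- if (!transa && !transb) A %*% B
  else if (transa && !transb) crossprod(A, B)
  else tcrossprod(A, B)
  stopifnot(!(transa && transb))
  tp_push(tp, val, c(a, b), function(g, tp) {
    A <- tp$vals[[a]]; B <- tp$vals[[b]]
    if (!transa && !transb) list(tcrossprod(g, B), crossprod(A, g))
    else if (transa && !transb) list(tcrossprod(B, g), A %*% g)
    else list(g %*% B, crossprod(g, A))
  })
}

tp_add <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g, tp) list(g, g))
}

tp_sub <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g, tp) list(g, -g))
}

tp_mul <- function(tp, a, b) {
  force(a); force(b)
  tp_push(tp, tp$vals[[a]] * tp$vals[[b]], c(a, b), function(g, tp)
    list(g * tp$vals[[b]], g * tp$vals[[a]]))
}

tp_scale <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp$vals[[a]] * k, a, function(g, tp) list(g * k))
}

tp_addc <- function(tp, a, k) {
  force(a)
  tp_push(tp, tp$vals[[a]] + k, a, function(g, tp) list(g))
}

# elementwise product with a constant (dropout masks etc.)
tp_mulc <- function(tp, a, m) {
  force(a)
  tp_push(tp, tp$vals[[a]] * m, a, function(g, tp) list(g * m))
}

# A (n x F) + row vector v (length F), broadcast over rows
tp_add_rowvec <- function(tp, a, v) {
  force(a); force(v)
  A <- tp$vals[[a]]; V <- tp$vals[[v]]
  tp_push(tp, sweep(A, 2L, V, "+"), c(a, v), function(g, tp)
    list(g, colSums(g)))
}

tp_mul_rowvec <- function(tp, a, v) {
  force(a); force(v)
  A <- tp$vals[[a]]; V <- tp$vals[[v]]
  tp_push(tp, sweep(A, 2L, V, "*"), c(a, v), function(g, tp)
    list(sweep(g, 2L, tp$vals[[v]], "*"), colSums(g * tp$vals[[a]])))
}

tp_div_rowvec <- function(tp, a, v) {
  force(a); force(v)
  A <- tp$vals[[a]]; V <- tp$vals[[v]]
  val <- sweep(A, 2L, V, "/")
  tp_push(tp, val, c(a, v), function(g, tp) {
    V <- tp$vals[[v]]
    list(sweep(g, 2L, V, "/"), -colSums(g * val) / V)
  })
}

# rows of A scaled by per-row weights w (length nrow(A))
tp_mul_colvec <- function(tp, a, w) {
  force(a); force(w)
  A <- tp$vals[[a]]; W <- tp$vals[[w]]
  tp_push(tp, A * W, c(a, w), function(g, tp)
    list(g * tp$vals[[w]], rowSums(g * tp$vals[[a]])))
}

tp_tanh <- function(tp, a) {
  force(a)
  val <- tanh(tp$vals[[a]])
  tp_push(tp, val, a, function(g, tp) list(g * (1 - val * val)))
}

tp_relu <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  keep <- A > 0
  tp_push(tp, A * keep, a, function(g, tp) list(g * keep))
}

tp_exp <- function(tp, a) {
  force(a)
  val <- exp(tp$vals[[a]])
  tp_push(tp, val, a, function(g, tp) list(g * val))
}

tp_log <- function(tp, a) {
  force(a)
  tp_push(tp, log(tp$vals[[a]]), a, function(g, tp)
    list(g / tp$vals[[a]]))
}

tp_sqrt <- function(tp, a) {
  force(a)
  val <- sqrt(tp$vals[[a]])
  tp_push(tp, val, a, function(g, tp) list(g * 0.5 / val))
}

tp_sum <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  tp_push(tp, sum(A), a, function(g, tp)
    list(if (is.null(dim(A))) rep(g, length(A)) else array(g, dim(A))))
}

tp_mean <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  n <- length(A)
  tp_push(tp, sum(A) / n, a, function(g, tp)
    list(if (is.null(dim(A))) rep(g / n, n) else array(g / n, dim(A))))
}

tp_colsums <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A)
  tp_push(tp, colSums(A), a, function(g, tp)
    list(matrix(g, nrow = nr, ncol = length(g), byrow = TRUE)))
}

tp_rowsums <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  nc <- ncol(A)
  tp_push(tp, rowSums(A), a, function(g, tp)
    list(matrix(g, nrow = length(g), ncol = nc)))
}

# embedding lookup: rows idx of table a (gradient scatter-adds)
tp_rows <- function(tp, a, idx) {
  force(a)
  A <- tp$vals[[a]]
  nr <- nrow(A); nc <- ncol(A)
  tp_push(tp, A[idx, , drop = FALSE], a, function(g, tp) {
    out <- matrix(0, nr, nc)
    r <- rowsum(g, group = idx)
    out[as.integer(rownames(r)), ] <- r
    list(out)
  })
}

tp_vcat <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  na <- nrow(A)
  tp_push(tp, rbind(A, B), c(a, b), function(g, tp)
    list(g[seq_len(na), , drop = FALSE],
         g[-seq_len(na), , drop = FALSE]))
}

# softmax of a vector within groups (token attention per cell)
tp_group_softmax <- function(tp, a, group) {
  force(a)
  s <- tp$vals[[a]]
  m <- stats::ave(s, group, FUN = max)
  e <- exp(s - m)
  z <- stats::ave(e, group, FUN = sum)
  p <- e / z
  tp_push(tp, p, a, function(g, tp) {
    dot <- stats::ave(g * p, group, FUN = sum)
    list(p * (g - dot))
  })
}

# sum rows of A within groups -> ngroups x ncol matrix (empty groups -> 0)
tp_rowsum_group <- function(tp, a, group, ngroups) {
  force(a)
  A <- tp$vals[[a]]
  out <- matrix(0, ngroups, ncol(A))
  if (nrow(A) > 0) {
    r <- rowsum(A, group = group)
    out[as.integer(rownames(r)), ] <- r
  }
  tp_push(tp, out, a, function(g, tp)
    list(g[group, , drop = FALSE]))
}

tp_softmax_rows <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  e <- exp(A - m)
  p <- e / rowSums(e)
  tp_push(tp, p, a, function(g, tp) {
    list(p * (g - rowSums(g * p)))
  })
}

tp_logsumexp_rows <- function(tp, a) {
  force(a)
  A <- tp$vals[[a]]
  m <- A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]
  e <- exp(A - m)
  se <- rowSums(e)
  tp_push(tp, m + log(se), a, function(g, tp)
    list((e / se) * as.vector(g)))
}

# extract entries a[ij] (2-column index matrix; positions must be unique)
tp_extract <- function(tp, a, ij) {
  force(a)
  A <- tp$vals[[a]]
  stopifnot(anyDuplicated(ij) == 0L)
  tp_push(tp, A[ij], a, function(g, tp) {
    out <- matrix(0, nrow(A), ncol(A))
    out[ij] <- g
    list(out)
  })
}

# vector -> row matrix (1 x length)
tp_reshape_row <- function(tp, a) {
  force(a)
  v <- tp$vals[[a]]
  tp_push(tp, matrix(v, nrow = 1L), a, function(g, tp) list(as.vector(g)))
}

# column-bind two matrices with equal row counts
tp_hcat <- function(tp, a, b) {
  force(a); force(b)
  A <- tp$vals[[a]]; B <- tp$vals[[b]]
  na <- ncol(A)
  tp_push(tp, cbind(A, B), c(a, b), function(g, tp)
    list(g[, seq_len(na), drop = FALSE], g[, -seq_len(na), drop = FALSE]))
}

# vector -> column matrix (length x 1)
tp_reshape_col <- function(tp, a) {
  force(a)
  v <- tp$vals[[a]]
  tp_push(tp, matrix(v, ncol = 1L), a, function(g, tp) list(as.vector(g)))
}

# n x 1 matrix -> vector
tp_as_vector <- function(tp, a) {
  force(a)
  v <- tp$vals[[a]]
  tp_push(tp, as.vector(v), a, function(g, tp)
    list(matrix(g, ncol = 1L)))
}

# subset of a vector (idx need not be unique; gradient scatter-adds)
tp_subset <- function(tp, a, idx) {
  force(a)
  v <- tp$vals[[a]]
  tp_push(tp, v[idx], a, function(g, tp) {
    out <- numeric(length(v))
    acc <- rowsum(as.vector(g), group = idx)
    out[as.integer(rownames(acc))] <- acc
    list(out)
  })
}

tp_l2norm_rows <- function(tp, a, eps = 1e-12) {
  force(a)
  A <- tp$vals[[a]]
  nrm <- sqrt(rowSums(A * A)) + eps
  V <- A / nrm
  tp_push(tp, V, a, function(g, tp) {
    list((g - V * rowSums(g * V)) / nrm)
  })
}

## ---- reverse sweep ---------------------------------------------------

# Returns the list of gradients (indexed by node id); nodes the loss does
# not depend on stay NULL.
tp_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  lv <- tp$vals[[loss_id]]
  grads[[loss_id]] <- if (is.null(dim(lv))) rep(1, length(lv)) else array(1, dim(lv))
  for (id in seq(loss_id, 1L)) {
    g <- grads[[id]]
    fn <- tp$backfns[[id]]
    if (is.null(g) || is.null(fn)) next
    pg <- fn(g, tp)
    ps <- tp$parents[[id]]
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[j]] else grads[[p]] + pg[[j]]
    }
  }
  grads
}

# Collect gradients for a (nested) id structure made by tp_leaves; missing
# gradients come back as zeros of the parameter's shape.
tp_collect <- function(tp, grads, ids, plist) {
  out <- vector("list", length(plist))
  names(out) <- names(plist)
  for (nm in names(plist)) {
    if (is.list(plist[[nm]])) {
      out[[nm]] <- tp_collect(tp, grads, ids[[nm]], plist[[nm]])
    } else {
      g <- grads[[ids[[nm]]]]
      if (is.null(g)) g <- array(0, dim(plist[[nm]]) %||% length(plist[[nm]]))
      out[[nm]] <- g
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
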