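# Reverse-mode automatic differentiation on dense matrices.
#
# Every tensor is a plain R matrix wrapped in an environment node. Operations
# executed inside ag_record() append nodes to a tape; ag_backward() walks the
# tape in reverse, calling each node's pullback. Raw matrices passed to ops are
# treated as constants and receive no gradient. All pullbacks are exercised by
# central-finite-difference checks in the test suite.

.ag <- new.env(parent = emptyenv())
.ag$tape <- NULL
.ag$recording <- FALSE
.ag$training <- FALSE

#' Create a learnable tensor
#'
#' Wraps a numeric matrix as an autodiff leaf whose gradient is accumulated by
#' [ag_backward()]. Plain matrices passed to `ag_*` ops are constants.
#'
#' @param value numeric matrix (vectors are promoted to 1-column matrices).
#' @param name optional label used in optimizer state and checkpoints.
#' @return an `ag_tensor` environment with fields `value` and `grad`.
#' @export
ag_tensor <- function(value, name = "") {
  if (!is.matrix(value)) value <- matrix(value, ncol = 1L)
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- list()
  node$bw <- NULL
  node$name <- name
  class(node) <- "ag_tensor"
  node
}

is_ag <- function(x) inherits(x, "ag_tensor")

ag_value <- function(x) if (is_ag(x)) x$value else x

#' @export
print.ag_tensor <- function(x, ...) {
  cat(sprintf("<ag_tensor %s [%d x %d]>\n", x$name, nrow(x$value), ncol(x$value)))
  invisible(x)
}

# Register an op result on the tape. `bw` maps the upstream gradient to a list
# of gradients aligned with `parents` (NULL entries for constants).
ag_op <- function(value, parents, bw) {
  node <- ag_tensor(value)
  if (isTRUE(.ag$recording)) {
    keep <- vapply(parents, is_ag, logical(1))
    if (any(keep)) {
      node$parents <- parents
      node$bw <- bw
      .ag$tape[[length(.ag$tape) + 1L]] <- node
    }
  }
  node
}

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

#' Record a computation for differentiation
#'
#' Evaluates `expr` with taping enabled; `training` toggles stochastic layers
#' (dropout) and batch-statistics mode in batch normalization.
#'
#' @param expr expression building `ag_*` ops.
#' @param training logical; training-mode forward pass.
#' @return the value of `expr`.
#' @export
ag_record <- function(expr, training = FALSE) {
  old_tape <- .ag$tape; old_rec <- .ag$recording; old_tr <- .ag$training
  .ag$tape <- list(); .ag$recording <- TRUE; .ag$training <- training
  on.exit({ .ag$tape <- old_tape; .ag$recording <- old_rec; .ag$training <- old_tr })
  res <- force(expr)
  attr(res, "ag_tape") <- .ag$tape
  .ag$last_tape <- .ag$tape  # reachable when the recorded expr returns a list
  res
}

#' Run a forward pass without taping
#' @param expr expression building `ag_*` ops.
#' @param training logical, passed through to stochastic layers.
#' @return the value of `expr`.
#' @export
ag_no_grad <- function(expr, training = FALSE) {
  old_rec <- .ag$recording; old_tr <- .ag$training
  .ag$recording <- FALSE; .ag$training <- training
  on.exit({ .ag$recording <- old_rec; .ag$training <- old_tr })
  force(expr)
}

#' Backpropagate through a recorded scalar
#'
#' Seeds the output node with gradient 1 and walks its tape in reverse,
#' accumulating gradients into every `ag_tensor` leaf reached.
#'
#' @param loss an `ag_tensor` holding a 1x1 value, as returned inside
#'   [ag_record()].
#' @export
ag_backward <- function(loss) {
  tape <- attr(loss, "ag_tape")
  if (is.null(tape)) tape <- .ag$last_tape
  if (is.null(tape)) stop("ag_backward: loss was not produced under ag_record()")
  if (length(ag_value(loss)) != 1L) stop("ag_backward: loss must be scalar")
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_along(tape))) {
    node <- tape[[i]]
    if (is.null(node$grad) || is.null(node$bw)) next
    gs <- node$bw(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (is_ag(p) && !is.null(gs[[j]])) ag_accum(p, gs[[j]])
    }
    node$grad <- NULL  # free intermediate gradients early
  }
  invisible(loss)
}

#' Zero the gradients of a list of tensors
#' @param params list of `ag_tensor`s.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

## ---- primitive operations ---------------------------------------------------

#' Matrix product of two tensors
#' @param a,b tensors or constant matrices, conformable for `%*%`.
#' @return tensor `a %*% b`.
#' @export
ag_mm <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av %*% bv, list(a, b), function(g) {
    list(if (is_ag(a)) g %*% t(bv) else NULL,
         if (is_ag(b)) crossprod(av, g) else NULL)
  })
}

#' Matrix product with transposed right factor, `a %*% t(b)`
#' @param a,b tensors or matrices with equal column counts.
#' @export
ag_mm_bt <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(tcrossprod(av, bv), list(a, b), function(g) {
    list(if (is_ag(a)) g %*% bv else NULL,
         if (is_ag(b)) crossprod(g, av) else NULL)
  })
}

#' Sparse-constant times dense-tensor product
#'
#' `A %*% h` where `A` is a constant sparse adjacency-style matrix. Used for
#' batched neighborhood sums in graph layers.
#' @param A constant `Matrix` sparse matrix.
#' @param h tensor.
#' @param At optional pre-transposed `A` (defaults to `t(A)`; pass `A` itself
#'   when symmetric).
#' @export
ag_spmm <- function(A, h, At = NULL) {
  hv <- ag_value(h)
  if (is.null(At)) At <- Matrix::t(A)
  ag_op(as.matrix(A %*% hv), list(h), function(g) {
    list(if (is_ag(h)) as.matrix(At %*% g) else NULL)
  })
}

#' Elementwise sum of two same-shape tensors
#' @param a,b tensors or matrices of identical dimension.
#' @export
ag_add <- function(a, b) {
  ag_op(ag_value(a) + ag_value(b), list(a, b), function(g) {
    list(if (is_ag(a)) g else NULL, if (is_ag(b)) g else NULL)
  })
}

#' Add a 1-row bias to every row
#' @param a tensor (n x c); @param bias tensor (1 x c).
#' @export
ag_add_bias <- function(a, bias) {
  av <- ag_value(a); bv <- ag_value(bias)
  stopifnot(ncol(av) == ncol(bv), nrow(bv) == 1L)
  ag_op(sweep(av, 2L, as.numeric(bv), "+"), list(a, bias), function(g) {
    list(if (is_ag(a)) g else NULL,
         if (is_ag(bias)) matrix(colSums(g), 1L) else NULL)
  })
}

#' Multiply a tensor by a fixed scalar
#' @param a tensor; @param k numeric scalar constant.
#' @export
ag_scale <- function(a, k) {
  ag_op(ag_value(a) * k, list(a), function(g) list(if (is_ag(a)) g * k else NULL))
}

#' Elementwise product
#' @param a,b tensors or matrices of identical dimension (either may be a
#'   constant, e.g. a 0/1 mask).
#' @export
ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_op(av * bv, list(a, b), function(g) {
    list(if (is_ag(a)) g * bv else NULL, if (is_ag(b)) g * av else NULL)
  })
}

#' Multiply every entry by a learnable 1x1 scalar tensor
#' @param a tensor; @param s 1x1 tensor.
#' @export
ag_mul_scalar <- function(a, s) {
  av <- ag_value(a); sv <- as.numeric(ag_value(s))
  ag_op(av * sv, list(a, s), function(g) {
    list(if (is_ag(a)) g * sv else NULL,
         if (is_ag(s)) matrix(sum(g * av), 1L, 1L) else NULL)
  })
}

#' Scale each row by a column-vector tensor (broadcast over columns)
#' @param a tensor (n x c); @param v tensor (n x 1).
#' @export
ag_mul_colvec <- function(a, v) {
  av <- ag_value(a); vv <- as.numeric(ag_value(v))
  stopifnot(length(vv) == nrow(av))
  ag_op(av * vv, list(a, v), function(g) {
    list(if (is_ag(a)) g * vv else NULL,
         if (is_ag(v)) matrix(rowSums(g * av), ncol = 1L) else NULL)
  })
}

#' Rectified linear unit
#' @param a tensor.
#' @export
ag_relu <- function(a) {
  av <- ag_value(a)
  out <- av * (av > 0)
  ag_op(out, list(a), function(g) list(if (is_ag(a)) g * (av > 0) else NULL))
}

#' Logistic sigmoid
#' @param a tensor.
#' @export
ag_sigmoid <- function(a) {
  s <- stats::plogis(ag_value(a))
  ag_op(s, list(a), function(g) list(if (is_ag(a)) g * s * (1 - s) else NULL))
}

#' Row-wise softmax with optional key masking
#'
#' Masked columns (mask FALSE) receive zero weight and take no part in the
#' normalization; rows whose mask is entirely FALSE come back as all zeros.
#'
#' @param a tensor of logits (n x m).
#' @param mask optional constant logical matrix (n x m) or logical vector of
#'   length m recycled to all rows; TRUE marks admissible keys.
#' @export
ag_softmax_rows <- function(a, mask = NULL) {
  av <- ag_value(a)
  if (!is.null(mask)) {
    if (is.vector(mask)) mask <- matrix(mask, nrow(av), ncol(av), byrow = TRUE)
    av <- ifelse(mask, av, -Inf)
  }
  mx <- apply(av, 1L, max)
  mx[!is.finite(mx)] <- 0
  e <- exp(av - mx)
  e[!is.finite(e)] <- 0
  z <- rowSums(e)
  s <- e / ifelse(z > 0, z, 1)
  ag_op(s, list(a), function(g) {
    list(if (is_ag(a)) (g - rowSums(g * s)) * s else NULL)
  })
}

#' Gather rows, with 0 denoting an all-zero row
#'
#' Returns `a[idx, ]` where `idx == 0` yields a zero row. The pullback
#' scatter-adds gradients back onto the source rows, so repeated indices
#' accumulate (used for embedding lookups and shifted convolution taps).
#'
#' @param a tensor (n x c); @param idx integer vector with values in 0..n.
#' @export
ag_rows <- function(a, idx) {
  av <- ag_value(a)
  out <- matrix(0, length(idx), ncol(av))
  sel <- idx > 0L
  if (any(sel)) out[sel, ] <- av[idx[sel], , drop = FALSE]
  ag_op(out, list(a), function(g) {
    if (!is_ag(a)) return(list(NULL))
    ga <- matrix(0, nrow(av), ncol(av))
    if (any(sel)) {
      acc <- rowsum(g[sel, , drop = FALSE], group = idx[sel])
      ga[as.integer(rownames(acc)), ] <- acc
    }
    list(ga)
  })
}

#' Select columns
#' @param a tensor; @param idx integer column indices.
#' @export
ag_cols <- function(a, idx) {
  av <- ag_value(a)
  ag_op(av[, idx, drop = FALSE], list(a), function(g) {
    if (!is_ag(a)) return(list(NULL))
    ga <- matrix(0, nrow(av), ncol(av))
    ga[, idx] <- ga[, idx] + g
    list(ga)
  })
}

#' Concatenate tensors column-wise
#' @param xs list of tensors/matrices with equal row counts.
#' @export
ag_cbind <- function(xs) {
  vs <- lapply(xs, ag_value)
  widths <- vapply(vs, ncol, integer(1))
  ends <- cumsum(widths); starts <- ends - widths + 1L
  ag_op(do.call(cbind, vs), xs, function(g) {
    lapply(seq_along(xs), function(j) {
      if (is_ag(xs[[j]])) g[, starts[j]:ends[j], drop = FALSE] else NULL
    })
  })
}

#' Stack tensors row-wise
#' @param xs list of tensors/matrices with equal column counts.
#' @export
ag_rbind <- function(xs) {
  vs <- lapply(xs, ag_value)
  heights <- vapply(vs, nrow, integer(1))
  ends <- cumsum(heights); starts <- ends - heights + 1L
  ag_op(do.call(rbind, vs), xs, function(g) {
    lapply(seq_along(xs), function(j) {
      if (is_ag(xs[[j]])) g[starts[j]:ends[j], , drop = FALSE] else NULL
    })
  })
}

#' Sum of all entries
#' @param a tensor.
#' @return 1x1 tensor.
#' @export
ag_sum <- function(a) {
  av <- ag_value(a)
  ag_op(matrix(sum(av), 1L, 1L), list(a), function(g) {
    list(if (is_ag(a)) matrix(as.numeric(g), nrow(av), ncol(av)) else NULL)
  })
}

#' Non-overlapping max pooling over rows
#'
#' Rows are grouped into consecutive blocks of `window` (the final block may be
#' shorter); each output row is the per-column maximum of its block.
#'
#' @param a tensor (n x c); @param window positive integer block size.
#' @export
ag_maxpool_rows <- function(a, window) {
  av <- ag_value(a)
  n <- nrow(av); cgrp <- ncol(av)
  n_out <- ceiling(n / window)
  blk <- rep(seq_len(n_out), each = window)[seq_len(n)]
  out <- matrix(-Inf, n_out, cgrp)
  argr <- matrix(0L, n_out, cgrp)
  for (b in seq_len(n_out)) {
    rows <- which(blk == b)
    sub <- av[rows, , drop = FALSE]
    w <- max.col(t(sub), ties.method = "first")
    argr[b, ] <- rows[w]
    out[b, ] <- sub[cbind(w, seq_len(cgrp))]
  }
  ag_op(out, list(a), function(g) {
    if (!is_ag(a)) return(list(NULL))
    ga <- matrix(0, n, cgrp)
    ij <- cbind(as.vector(argr), rep(seq_len(cgrp), each = n_out))
    ga[ij] <- ga[ij] + as.vector(g)
    list(ga)
  })
}

#' Dropout (active only in training mode)
#' @param a tensor; @param p drop probability in `[0, 1)`.
#' @export
ag_dropout <- function(a, p) {
  if (!isTRUE(.ag$training) || p <= 0) return(a)
  av <- ag_value(a)
  keep <- matrix(stats::runif(length(av)) >= p, nrow(av), ncol(av)) / (1 - p)
  ag_op(av * keep, list(a), function(g) list(if (is_ag(a)) g * keep else NULL))
}

#' Mean binary cross-entropy from logits
#'
#' Numerically stable `mean(softplus(z) - y * z)`; the pullback is
#' `(sigmoid(z) - y) / n`.
#'
#' @param z tensor of logits (n x 1); @param y constant 0/1 vector of length n.
#' @return 1x1 tensor.
#' @export
ag_bce_logits <- function(z, y) {
  zv <- ag_value(z)
  y <- matrix(as.numeric(y), ncol = 1L)
  stopifnot(nrow(zv) == nrow(y))
  n <- nrow(zv)
  softplus <- ifelse(zv > 30, zv, log1p(exp(pmin(zv, 30))))
  loss <- sum(softplus - y * zv) / n
  ag_op(matrix(loss, 1L, 1L), list(z), function(g) {
    list(if (is_ag(z)) as.numeric(g) * (stats::plogis(zv) - y) / n else NULL)
  })
}

#' Batch normalization with mask-aware statistics
#'
#' In training mode, per-column mean and (population) variance are computed
#' over `rows` only — the real, non-padding rows — so padded rows never
#' influence the statistics, and running estimates in `state` are updated with
#' exponential `momentum`. In evaluation mode the running estimates are used,
#' making single-sample inference independent of batch composition.
#'
#' @param a tensor (n x c).
#' @param gamma,beta 1 x c tensors (scale and shift).
#' @param state environment holding `running_mean`/`running_var`, created by
#'   [nn_bn_state()].
#' @param rows integer indices of real rows (NULL = all rows).
#' @param momentum running-average update weight.
#' @param eps variance floor.
#' @export
ag_batchnorm <- function(a, gamma, beta, state, rows = NULL,
                         momentum = 0.1, eps = 1e-5) {
  av <- ag_value(a)
  gv <- as.numeric(ag_value(gamma)); bv <- as.numeric(ag_value(beta))
  n <- nrow(av); cc <- ncol(av)
  if (is.null(rows)) rows <- seq_len(n)
  training <- isTRUE(.ag$training)
  if (training) {
    sub <- av[rows, , drop = FALSE]
    m <- colMeans(sub)
    v <- colMeans(sweep(sub, 2L, m)^2)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * m
    state$running_var <- (1 - momentum) * state$running_var + momentum * v
  } else {
    m <- state$running_mean; v <- state$running_var
  }
  sd_ <- sqrt(v + eps)
  xhat <- sweep(sweep(av, 2L, m), 2L, sd_, "/")
  out <- sweep(sweep(xhat, 2L, gv, "*"), 2L, bv, "+")
  ag_op(out, list(a, gamma, beta), function(g) {
    gg <- if (is_ag(gamma)) matrix(colSums(g * xhat), 1L) else NULL
    gb <- if (is_ag(beta)) matrix(colSums(g), 1L) else NULL
    ga <- NULL
    if (is_ag(a)) {
      ga <- sweep(g, 2L, gv / sd_, "*")
      if (training) {
        # statistics depend on real rows only, but every output row (real or
        # padded) uses them, so the correction sums gradients over all rows
        # and distributes over the real-row count
        m_r <- length(rows)
        mg <- colSums(g) / m_r
        mgx <- colSums(g * xhat) / m_r
        corr <- sweep(xhat[rows, , drop = FALSE], 2L, mgx, "*")
        corr <- sweep(corr, 2L, mg, "+")
        ga[rows, ] <- ga[rows, ] - sweep(corr, 2L, gv / sd_, "*")
      }
    }
    list(ga, gg, gb)
  })
}

#' Fresh batch-normalization running-state
#' @param width number of channels.
#' @return environment with zero running mean and unit running variance.
#' @export
nn_bn_state <- function(width) {
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(width)
  st$running_var <- rep(1, width)
  st
}
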