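# Parameter initialization, the 1-D convolution composite, and Adam.

#' He-scaled Gaussian weight matrix
#' @param fan_in,fan_out dimensions.
#' @param name tensor label.
#' @return `ag_tensor` of shape fan_in x fan_out.
#' @export
nn_init_weight <- function(fan_in, fan_out, name = "") {
  ag_tensor(matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)),
                   fan_in, fan_out), name = name)
}

#' Zero bias row
#' @param width number of units.
#' @param name tensor label.
#' @export
nn_init_bias <- function(width, name = "") {
  ag_tensor(matrix(0, 1L, width), name = name)
}

#' Row-shift index vector for stacked, equal-length sequences
#'
#' For `n_seq` sequences of `len` rows stacked vertically, returns for each
#' output row the source row shifted by `offset` within its own sequence, with
#' 0 (the zero-row sentinel of [ag_rows()]) where the tap falls outside the
#' sequence — i.e. zero same-padding that never crosses sequence boundaries.
#'
#' @param len padded length of each sequence.
#' @param n_seq number of stacked sequences.
#' @param offset integer shift (negative = look left).
#' @export
nn_shift_index <- function(len, n_seq, offset) {
  pos <- seq_len(len) + offset
  pos[pos < 1L | pos > len] <- NA_integer_
  base <- rep((seq_len(n_seq) - 1L) * len, each = len)
  idx <- rep(pos, n_seq) + base
  idx[is.na(idx)] <- 0L
  as.integer(idx)
}

#' Same-padded 1-D convolution over stacked sequences
#'
#' Computes, for every position t of every sequence, `sum_j x[t + j - 1 - pad] W_j + b`
#' where `W` stores the `width` taps as stacked `c_in x c_out` blocks. Sequence
#' length is preserved (zero padding, `pad = floor((width - 1) / 2)`, so even
#' widths pad one extra position on the right), and windows never leak across
#' the boundaries of the stacked sequences.
#'
#' @param x tensor (n_seq * len) x c_in.
#' @param W tensor (width * c_in) x c_out; @param b 1 x c_out tensor.
#' @param width kernel width; @param len per-sequence padded length;
#' @param n_seq number of stacked sequences.
#' @export
nn_conv1d <- function(x, W, b, width, len, n_seq) {
  c_in <- ncol(ag_value(x))
  stopifnot(nrow(ag_value(W)) == width * c_in)
  pad <- (width - 1L) %/% 2L
  out <- NULL
  for (j in seq_len(width)) {
    idx <- nn_shift_index(len, n_seq, j - 1L - pad)
    chunk <- ((j - 1L) * c_in + 1L):(j * c_in)
    term <- ag_mm(ag_rows(x, idx), ag_rows(W, chunk))
    out <- if (is.null(out)) term else ag_add(out, term)
  }
  ag_add_bias(out, b)
}

#' Adam optimizer state
#' @param params named list of `ag_tensor`s.
#' @param lr learning rate; @param beta1,beta2 moment decays; @param eps stabilizer.
#' @return an environment; pass to [adam_step()].
#' @export
adam_init <- function(params, lr = 1e-5, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt <- new.env(parent = emptyenv())
  opt$params <- params
  opt$lr <- lr; opt$beta1 <- beta1; opt$beta2 <- beta2; opt$eps <- eps
  opt$t <- 0L
  opt$m <- lapply(params, function(p) p$value * 0)
  opt$v <- lapply(params, function(p) p$value * 0)
  opt
}

#' One Adam update over all parameters with non-NULL gradients
#' @param opt state from [adam_init()].
#' @param clip optional global gradient-norm clip (NULL = off).
#' @export
adam_step <- function(opt, clip = 5) {
  if (!is.null(clip)) {
    sq <- 0
    for (p in opt$params) if (!is.null(p$grad)) sq <- sq + sum(p$grad^2)
    gnorm <- sqrt(sq)
    if (is.finite(gnorm) && gnorm > clip) {
      sc <- clip / gnorm
      for (p in opt$params) if (!is.null(p$grad)) p$grad <- p$grad * sc
    }
  }
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$beta1^opt$t
  bc2 <- 1 - opt$beta2^opt$t
  for (k in seq_along(opt$params)) {
    p <- opt$params[[k]]
    if (is.null(p$grad)) next
    opt$m[[k]] <- opt$beta1 * opt$m[[k]] + (1 - opt$beta1) * p$grad
    opt$v[[k]] <- opt$beta2 * opt$v[[k]] + (1 - opt$beta2) * p$grad^2
    mhat <- opt$m[[k]] / bc1
    vhat <- opt$v[[k]] / bc2
    p$value <- p$value - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  invisible(opt)
}

# Evaluate f() with the RNG locally seeded, restoring the caller's RNG state.
with_seed <- function(seed, f) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  f()
}
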