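# Protein encoder: learnable 25-token embedding, linear projection, and
# residual 1-D convolution blocks. Each block stacks same-padded convolutions
# with kernel widths 3 -> 6 -> 9 (batch normalization, ReLU, dropout between),
# and adds a dimension-matching linear shortcut before the final activation:
# Y = ReLU(F(X) + G(X)). A plain-CNN variant with the shortcut removed is
# selectable for the residual-connection ablation.

#' Initialize protein-encoder parameters
#'
#' @param d_model latent width D_p.
#' @param n_blocks number of residual blocks (default 2).
#' @param kernel_sizes convolution widths stacked in series within each block
#'   (default `c(3, 6, 9)`).
#' @param dropout dropout rate between convolutions (training only).
#' @param use_residual FALSE removes the shortcut (plain-CNN ablation).
#' @return a `protein_encoder` parameter set: embedding table `X_V` (25 x D_p),
#'   projection `W0`/`b0`, and per block conv weights, batchnorm and shortcut.
#' @export
protein_encoder_params <- function(d_model, n_blocks = 2L,
                                   kernel_sizes = c(3L, 6L, 9L),
                                   dropout = 0.1, use_residual = TRUE) {
  p <- list(
    "prot.X_V" = ag_tensor(matrix(stats::rnorm(25 * d_model, 0, 0.1), 25, d_model),
                           "prot.X_V"),
    "prot.W0" = nn_init_weight(d_model, d_model, "prot.W0"),
    "prot.b0" = nn_init_bias(d_model, "prot.b0"))
  states <- list()
  for (b in seq_len(n_blocks)) {
    for (c_i in seq_along(kernel_sizes)) {
      w <- kernel_sizes[c_i]
      nm <- function(s) sprintf("prot.b%d.c%d.%s", b, c_i, s)
      p[[nm("W")]] <- nn_init_weight(w * d_model, d_model, nm("W"))
      p[[nm("b")]] <- nn_init_bias(d_model, nm("b"))
      p[[nm("gamma")]] <- ag_tensor(matrix(1, 1, d_model), nm("gamma"))
      p[[nm("beta")]] <- nn_init_bias(d_model, nm("beta"))
      states[[sprintf("prot.b%d.c%d.bn", b, c_i)]] <- nn_bn_state(d_model)
    }
    if (use_residual) {
      nm <- function(s) sprintf("prot.b%d.%s", b, s)
      p[[nm("Wg")]] <- nn_init_weight(d_model, d_model, nm("Wg"))
      p[[nm("bg")]] <- nn_init_bias(d_model, nm("bg"))
    }
  }
  structure(list(params = p, bn_states = states, d_model = d_model,
                 n_blocks = n_blocks, kernel_sizes = as.integer(kernel_sizes),
                 dropout = dropout, use_residual = use_residual),
            class = "protein_encoder")
}

#' Embed and project protein tokens
#'
#' Looks up each residue in the learnable 25 x D_p embedding table and applies
#' a linear projection with ReLU, giving the dense residue matrix
#' X_p (length x D_p).
#'
#' @param tokens a `protein_tokens` object, or an integer index vector in
#'   1..25 (0 allowed as a padding sentinel yielding a zero row).
#' @param encoder a `protein_encoder`.
#' @return tensor (length x D_p).
#' @export
embed_and_project <- function(tokens, encoder) {
  idx <- if (inherits(tokens, "protein_tokens")) tokens$indices else as.integer(tokens)
  if (any(idx > 25L | idx < 0L))
    stop("embed_and_project: token index outside 0..25")
  emb <- ag_rows(encoder$params[["prot.X_V"]], idx)
  ag_relu(ag_add_bias(ag_mm(emb, encoder$params[["prot.W0"]]), encoder$params[["prot.b0"]]))
}

block_slot <- function(enc, b, c_i) {
  nm <- function(s) sprintf("prot.b%d.c%d.%s", b, c_i, s)
  list(W = enc$params[[nm("W")]], b = enc$params[[nm("b")]],
       gamma = enc$params[[nm("gamma")]], beta = enc$params[[nm("beta")]],
       bn = enc$bn_states[[sprintf("prot.b%d.c%d.bn", b, c_i)]])
}

#' One residual convolution block
#'
#' `Y = ReLU(F(X) + G(X))` where F stacks the block's same-padded
#' convolutions (each followed by batchnorm, ReLU and dropout except after the
#' last convolution, which is batch-normalized and left pre-activation) and G
#' is a linear shortcut. Sequence length is always preserved. With the
#' residual ablation active, `Y = ReLU(F(X))`.
#'
#' @param Xin tensor ((n_seq * len) x D_p).
#' @param encoder a `protein_encoder`; @param block_id which block's weights.
#' @param len per-sequence padded length; @param n_seq number of stacked
#'   sequences; @param mask logical real-position marker (NULL = all real).
#' @return tensor of the same shape as `Xin`.
#' @export
residual_block <- function(Xin, encoder, block_id, len, n_seq = 1L, mask = NULL) {
  rows <- if (is.null(mask)) NULL else which(mask)
  H <- Xin
  n_conv <- length(encoder$kernel_sizes)
  for (c_i in seq_len(n_conv)) {
    sl <- block_slot(encoder, block_id, c_i)
    H <- nn_conv1d(H, sl$W, sl$b, encoder$kernel_sizes[c_i], len, n_seq)
    H <- ag_batchnorm(H, sl$gamma, sl$beta, sl$bn, rows = rows)
    if (c_i < n_conv) {
      H <- ag_relu(H)
      if (!is.null(mask)) H <- mask_rows_const(H, mask)
      H <- ag_dropout(H, encoder$dropout)
    }
  }
  if (encoder$use_residual) {
    nm <- function(s) sprintf("prot.b%d.%s", block_id, s)
    G <- ag_add_bias(ag_mm(Xin, encoder$params[[nm("Wg")]]),
                     encoder$params[[nm("bg")]])
    H <- ag_add(H, G)
  }
  out <- ag_relu(H)
  if (!is.null(mask)) out <- mask_rows_const(out, mask)
  out
}

#' Encode a protein sequence into residue-level embeddings
#'
#' [embed_and_project()] followed by the encoder's residual blocks; residue
#' count is preserved end to end.
#'
#' @param tokens `protein_tokens` (or index vector; 0 = padding).
#' @param encoder a `protein_encoder`.
#' @param training logical; enables dropout and batch-statistics mode
#'   (NULL = inherit the ambient mode).
#' @return list with tensors `X_p` (post-projection) and `Y` (block output),
#'   both (length x D_p).
#' @export
encode_protein <- function(tokens, encoder, training = NULL) {
  if (is.null(training)) training <- isTRUE(.ag$training)
  idx <- if (inherits(tokens, "protein_tokens")) tokens$indices else as.integer(tokens)
  run <- function() {
    X_p <- embed_and_project(idx, encoder)
    Y <- X_p
    for (b in seq_len(encoder$n_blocks)) {
      Y <- residual_block(Y, encoder, b, len = length(idx), n_seq = 1L)
    }
    list(X_p = X_p, Y = Y)
  }
  if (isTRUE(.ag$recording)) run() else ag_no_grad(run(), training = training)
}
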