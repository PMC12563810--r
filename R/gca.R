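# Gated cross-attention fusion. One modality queries the other with scaled
# dot-product multi-head attention (scale 1/sqrt(d_h), d_h = D_H / h); the
# attended context A is mixed with the projected query by a gate:
#   H = alpha * A + (1 - alpha) * Proj(Q),    alpha in (0, 1).
# The gate is fixed (static), 0.5 (averaged), or predicted per token by a
# small network on [A; Proj(Q)] (dynamic). Gated token outputs are max-pooled
# (window = pooling size) and averaged into a fixed-width summary; in
# bidirectional mode both directions run with their own weights and the two
# summaries are concatenated.

#' Initialize gated cross-attention parameters
#'
#' @param d_q,d_kv input widths of the query and key/value modalities.
#' @param d_hidden attention hidden width D_H (divisible by `n_heads`).
#' @param n_heads head count h.
#' @param gating_mode `"dynamic"`, `"static"` or `"averaged"`.
#' @param alpha fixed gate value for static mode (in (0, 1)).
#' @param prefix parameter-name prefix.
#' @return a `gca_params` list with query/key/value projections, output
#'   projection, query shortcut `Proj`, and the gate network (zero-initialized,
#'   so training starts at alpha = 0.5).
#' @export
gca_params <- function(d_q, d_kv, d_hidden, n_heads = 4L,
                       gating_mode = c("dynamic", "static", "averaged"),
                       alpha = 0.5, prefix = "gca") {
  gating_mode <- match.arg(gating_mode)
  if (d_hidden %% n_heads != 0L)
    stop(sprintf("gca_params: D_H = %d not divisible by %d heads",
                 d_hidden, n_heads))
  if (gating_mode == "static" && (alpha <= 0 || alpha >= 1))
    stop("gca_params: static alpha must lie strictly in (0, 1)")
  nm <- function(s) paste0(prefix, ".", s)
  p <- list()
  p[[nm("WQ")]] <- nn_init_weight(d_q, d_hidden, nm("WQ"))
  p[[nm("WK")]] <- nn_init_weight(d_kv, d_hidden, nm("WK"))
  p[[nm("WV")]] <- nn_init_weight(d_kv, d_hidden, nm("WV"))
  p[[nm("WO")]] <- nn_init_weight(d_hidden, d_hidden, nm("WO"))
  p[[nm("bO")]] <- nn_init_bias(d_hidden, nm("bO"))
  p[[nm("Wproj")]] <- nn_init_weight(d_q, d_hidden, nm("Wproj"))
  p[[nm("bproj")]] <- nn_init_bias(d_hidden, nm("bproj"))
  p[[nm("Wfc")]] <- ag_tensor(matrix(0, 2 * d_hidden, 1), nm("Wfc"))
  p[[nm("bfc")]] <- ag_tensor(matrix(0, 1, 1), nm("bfc"))
  structure(list(params = p, d_hidden = d_hidden, n_heads = n_heads,
                 gating_mode = gating_mode, alpha = alpha, prefix = prefix),
            class = "gca_params")
}

gca_slot <- function(gca, s) gca$params[[paste0(gca$prefix, ".", s)]]

#' Multi-head scaled dot-product attention
#'
#' Projects Q, K, V to the hidden width, splits into heads, applies
#' `softmax(Q'K'^T / sqrt(d_h)) V'` per head, concatenates and linearly maps
#' the result. Masked key positions receive exactly zero weight.
#'
#' @param Q tensor (L_q x d_q); @param K,V tensors with equal row counts.
#' @param gca a `gca_params`.
#' @param key_mask optional logical vector (length L_k); FALSE = padded key.
#' @return list with `A` (tensor, L_q x D_H) and `att_map` (list of h
#'   numeric matrices L_q x L_k of attention weights).
#' @export
multi_head_attention <- function(Q, K, V, gca, key_mask = NULL) {
  if (nrow(ag_value(K)) != nrow(ag_value(V)))
    stop("multi_head_attention: K and V must have equal token counts")
  h <- gca$n_heads
  d_h <- gca$d_hidden / h
  Qp <- ag_mm(Q, gca_slot(gca, "WQ"))
  Kp <- ag_mm(K, gca_slot(gca, "WK"))
  Vp <- ag_mm(V, gca_slot(gca, "WV"))
  heads <- vector("list", h)
  att_map <- vector("list", h)
  for (i in seq_len(h)) {
    cols <- ((i - 1L) * d_h + 1L):(i * d_h)
    Qh <- ag_cols(Qp, cols); Kh <- ag_cols(Kp, cols); Vh <- ag_cols(Vp, cols)
    logits <- ag_scale(ag_mm_bt(Qh, Kh), 1 / sqrt(d_h))
    W <- ag_softmax_rows(logits, mask = key_mask)
    att_map[[i]] <- ag_value(W)
    heads[[i]] <- ag_mm(W, Vh)
  }
  A <- ag_add_bias(ag_mm(ag_cbind(heads), gca_slot(gca, "WO")),
                   gca_slot(gca, "bO"))
  list(A = A, att_map = att_map)
}

#' Project the query to the fusion width
#' @param Q tensor (L_q x d_q); @param gca a `gca_params`.
#' @return tensor (L_q x D_H).
#' @export
gca_proj_query <- function(Q, gca) {
  ag_add_bias(ag_mm(Q, gca_slot(gca, "Wproj")), gca_slot(gca, "bproj"))
}

#' Token-level dynamic gate
#'
#' `alpha = sigmoid(FcNet([A; Proj(Q)]))`, one value per query token, always
#' strictly inside (0, 1). A zero-weight gate network yields alpha = 0.5.
#'
#' @param A attended tensor (L_q x D_H); @param Q_projected tensor (L_q x D_H).
#' @param gca a `gca_params` (supplies the gate network weights).
#' @return tensor (L_q x 1).
#' @export
dynamic_alpha <- function(A, Q_projected, gca) {
  z <- ag_add_bias(ag_mm(ag_cbind(list(A, Q_projected)), gca_slot(gca, "Wfc")),
                   gca_slot(gca, "bfc"))
  # smooth rescaling keeps alpha strictly interior even when sigmoid saturates
  # in floating point: alpha = eps + (1 - 2 eps) sigmoid(z)
  eps <- 1e-7
  ag_add(ag_scale(ag_sigmoid(z), 1 - 2 * eps),
         matrix(eps, nrow(ag_value(z)), 1L))
}

#' Gated convex fusion of attended context and projected query
#'
#' `H = alpha * A + (1 - alpha) * Proj(Q)`. `alpha` may be a scalar (static /
#' averaged gating) or a per-token column tensor (dynamic gating).
#'
#' @param A tensor (L_q x D_H); @param Q_projected tensor (L_q x D_H).
#' @param alpha numeric scalar in (0, 1) or tensor (L_q x 1).
#' @return tensor (L_q x D_H).
#' @export
gated_fuse <- function(A, Q_projected, alpha) {
  if (is.numeric(alpha) && length(alpha) == 1L) {
    if (alpha < 0 || alpha > 1)
      stop("gated_fuse: static alpha must lie in [0, 1]")
    return(ag_add(ag_scale(A, alpha), ag_scale(Q_projected, 1 - alpha)))
  }
  one_minus <- ag_add(ag_scale(alpha, -1), matrix(1, nrow(ag_value(alpha)), 1))
  ag_add(ag_mul_colvec(A, alpha), ag_mul_colvec(Q_projected, one_minus))
}

#' Pool gated token outputs into a fixed-width summary
#'
#' Non-overlapping 1-D max pooling over the token axis (window = `pool_size`)
#' followed by the mean over pooled positions.
#'
#' @param H tensor (L x D_H); @param pool_size pooling window (default 3).
#' @return tensor (1 x D_H).
#' @export
gca_pool <- function(H, pool_size = 3L) {
  P <- ag_maxpool_rows(H, pool_size)
  n_out <- nrow(ag_value(P))
  ag_mm(matrix(1 / n_out, 1L, n_out), P)
}

gca_one_direction <- function(Q, K, V, gca, key_mask = NULL, pool_size = 3L) {
  mha <- multi_head_attention(Q, K, V, gca, key_mask = key_mask)
  PQ <- gca_proj_query(Q, gca)
  alpha <- switch(gca$gating_mode,
    dynamic = dynamic_alpha(mha$A, PQ, gca),
    static = gca$alpha,
    averaged = 0.5)
  H <- gated_fuse(mha$A, PQ, alpha)
  list(H = H, pooled = gca_pool(H, pool_size), att_map = mha$att_map,
       alpha = if (is.numeric(alpha)) alpha else ag_value(alpha))
}

#' Full gated cross-attention fusion of a drug-protein pair
#'
#' Protein residues query drug atoms (Q = X_p, K = V = X_d); in bidirectional
#' mode the reverse direction runs with its own parameter set and both pooled
#' summaries are concatenated. Padded atoms/residues are masked out of every
#' softmax. With `use_gca = FALSE` (fusion ablation) attention is bypassed
#' entirely and the masked token means of both modalities are concatenated.
#'
#' @param drug_tokens tensor (N x D_d) of atom embeddings.
#' @param protein_tokens tensor (L x D_p) of residue embeddings.
#' @param fusion list with `p2d` (and optionally `d2p`) `gca_params`, plus
#'   `bidirectional`, `pool_size`, `use_gca` flags.
#' @param drug_mask,protein_mask logical vectors marking real positions
#'   (NULL = all real).
#' @return list with `f` (tensor, 1 x fused width), `att_maps` (named list:
#'   `p2d` = list of per-head residue x atom matrices; `d2p` if
#'   bidirectional), `alpha` (per direction), `H` (gated token tensors).
#' @export
gca_forward <- function(drug_tokens, protein_tokens, fusion,
                        drug_mask = NULL, protein_mask = NULL) {
  if (!isTRUE(fusion$use_gca)) {
    dmean <- masked_mean(drug_tokens, drug_mask)
    pmean <- masked_mean(protein_tokens, protein_mask)
    return(list(f = ag_cbind(list(pmean, dmean)), att_maps = list(),
                alpha = list(), H = list()))
  }
  p2d <- gca_one_direction(protein_tokens, drug_tokens, drug_tokens,
                           fusion$p2d, key_mask = drug_mask,
                           pool_size = fusion$pool_size)
  parts <- list(p2d$pooled)
  att_maps <- list(p2d = p2d$att_map)
  alpha <- list(p2d = p2d$alpha)
  H <- list(p2d = p2d$H)
  if (isTRUE(fusion$bidirectional)) {
    d2p <- gca_one_direction(drug_tokens, protein_tokens, protein_tokens,
                             fusion$d2p, key_mask = protein_mask,
                             pool_size = fusion$pool_size)
    parts <- c(parts, list(d2p$pooled))
    att_maps$d2p <- d2p$att_map
    alpha$d2p <- d2p$alpha
    H$d2p <- d2p$H
  }
  list(f = ag_cbind(parts), att_maps = att_maps, alpha = alpha, H = H)
}

masked_mean <- function(x, mask = NULL) {
  n <- nrow(ag_value(x))
  w <- if (is.null(mask)) rep(1, n) else as.numeric(mask)
  ag_mm(matrix(w / sum(w), 1L, n), x)
}
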