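# Drug encoder: linear projection of raw atom features, stacked GIN layers
# (sum aggregation with (1 + eps) self-weight and a 2-layer MLP, then
# mask-aware batch normalization and ReLU), and Jumping-Knowledge aggregation
# concatenating all layer outputs and projecting back to the latent width.
# A GCN drop-in (degree-normalized mean aggregation) is selectable for
# ablation.

mask_rows_const <- function(x, mask) {
  ag_mul(x, matrix(as.numeric(mask), length(mask), ncol(ag_value(x))))
}

#' Initialize drug-encoder parameters
#'
#' @param d_model latent width D_d.
#' @param n_layers number of GIN layers K.
#' @param variant `"gin"` (sum aggregation, learnable eps) or `"gcn"`
#'   (mean aggregation drop-in used by the encoder ablation).
#' @param d_in raw feature width (74).
#' @return named list: `W0` (74 x D_d, no bias so dummy rows stay zero),
#'   per-layer MLP weights, `eps` scalars (init 0, learnable), batchnorm
#'   scale/shift + running state, and `W_JK` ((K*D_d) x D_d).
#' @export
drug_encoder_params <- function(d_model, n_layers = 4L, variant = c("gin", "gcn"),
                                d_in = atom_feature_dim()) {
  variant <- match.arg(variant)
  p <- list("drug.W0" = nn_init_weight(d_in, d_model, "drug.W0"))
  states <- list()
  for (k in seq_len(n_layers)) {
    nm <- function(s) sprintf("drug.l%d.%s", k, s)
    if (variant == "gin") {
      p[[nm("W1")]] <- nn_init_weight(d_model, d_model, nm("W1"))
      p[[nm("b1")]] <- nn_init_bias(d_model, nm("b1"))
      p[[nm("W2")]] <- nn_init_weight(d_model, d_model, nm("W2"))
      p[[nm("b2")]] <- nn_init_bias(d_model, nm("b2"))
      p[[nm("eps")]] <- ag_tensor(matrix(0, 1, 1), nm("eps"))
    } else {
      p[[nm("W1")]] <- nn_init_weight(d_model, d_model, nm("W1"))
      p[[nm("b1")]] <- nn_init_bias(d_model, nm("b1"))
    }
    p[[nm("gamma")]] <- ag_tensor(matrix(1, 1, d_model), nm("gamma"))
    p[[nm("beta")]] <- nn_init_bias(d_model, nm("beta"))
    states[[sprintf("drug.l%d.bn", k)]] <- nn_bn_state(d_model)
  }
  p[["drug.W_JK"]] <- nn_init_weight(n_layers * d_model, d_model, "drug.W_JK")
  structure(list(params = p, bn_states = states, n_layers = n_layers,
                 d_model = d_model, variant = variant), class = "drug_encoder")
}

#' Initial linear projection of raw atom features
#'
#' `H0 = ReLU(X W0)`; with all-zero dummy rows in, all-zero dummy rows out
#' (no bias term).
#'
#' @param X tensor or matrix, N x 74.
#' @param W0 74 x D_d weight tensor.
#' @return tensor N x D_d.
#' @export
project_initial <- function(X, W0) {
  if (ncol(ag_value(X)) != nrow(ag_value(W0)))
    stop(sprintf("project_initial: X has %d columns but W0 expects %d",
                 ncol(ag_value(X)), nrow(ag_value(W0))))
  ag_relu(ag_mm(X, W0))
}

#' One GIN layer
#'
#' Pre-activation update `MLP((1 + eps) h_v + sum_{u in N(v)} h_u)` computed
#' for all nodes at once via a sparse adjacency product, followed by
#' batch normalization over the real rows and ReLU, with dummy rows re-zeroed.
#'
#' @param H node tensor (rows = nodes).
#' @param adjacency constant sparse symmetric adjacency (both directions of
#'   every undirected edge).
#' @param layer list with `W1`, `b1`, `W2`, `b2`, `eps`, `gamma`, `beta`
#'   tensors and `bn` state.
#' @param mask logical vector marking real rows (NULL = all real).
#' @param bn apply batch normalization + ReLU (set FALSE to inspect the raw
#'   Eq.-level update).
#' @return node tensor of the same shape as `H`.
#' @export
gin_layer <- function(H, adjacency, layer, mask = NULL, bn = TRUE) {
  S <- ag_spmm(adjacency, H, At = adjacency)  # symmetric
  one_plus_eps <- ag_add(layer$eps, matrix(1, 1, 1))
  u <- ag_add(ag_mul_scalar(H, one_plus_eps), S)
  hidden <- ag_relu(ag_add_bias(ag_mm(u, layer$W1), layer$b1))
  out <- ag_add_bias(ag_mm(hidden, layer$W2), layer$b2)
  if (!bn) return(out)
  rows <- if (is.null(mask)) NULL else which(mask)
  out <- ag_batchnorm(out, layer$gamma, layer$beta, layer$bn, rows = rows)
  out <- ag_relu(out)
  if (!is.null(mask)) out <- mask_rows_const(out, mask)
  out
}

#' One GCN layer (ablation drop-in)
#'
#' Mean aggregation over the closed neighborhood (self loop included) with a
#' single linear map, then batch normalization and ReLU.
#'
#' @inheritParams gin_layer
#' @param norm_adj constant sparse row-normalized adjacency `D^-1 (A + I)`.
#' @export
gcn_layer <- function(H, norm_adj, layer, mask = NULL) {
  agg <- ag_spmm(norm_adj, H, At = Matrix::t(norm_adj))
  out <- ag_add_bias(ag_mm(agg, layer$W1), layer$b1)
  rows <- if (is.null(mask)) NULL else which(mask)
  out <- ag_batchnorm(out, layer$gamma, layer$beta, layer$bn, rows = rows)
  out <- ag_relu(out)
  if (!is.null(mask)) out <- mask_rows_const(out, mask)
  out
}

#' Jumping-Knowledge aggregation
#'
#' Concatenates the K layer outputs column-wise and projects back to the
#' latent width: `h_JK = Concat(h^(1), ..., h^(K)) W_JK`.
#'
#' @param per_layer list of K node tensors of identical shape.
#' @param W_JK (K * D_d) x D_d weight tensor.
#' @return tensor N x D_d.
#' @export
jumping_knowledge <- function(per_layer, W_JK) {
  widths <- vapply(per_layer, function(h) ncol(ag_value(h)), integer(1))
  if (length(unique(widths)) != 1L)
    stop("jumping_knowledge: layer outputs have inconsistent widths")
  cc <- ag_cbind(per_layer)
  if (ncol(ag_value(cc)) != nrow(ag_value(W_JK)))
    stop(sprintf("jumping_knowledge: concat width %d but W_JK expects %d",
                 ncol(ag_value(cc)), nrow(ag_value(W_JK))))
  ag_mm(cc, W_JK)
}

layer_slot <- function(enc, k) {
  nm <- function(s) sprintf("drug.l%d.%s", k, s)
  list(W1 = enc$params[[nm("W1")]], b1 = enc$params[[nm("b1")]],
       W2 = enc$params[[nm("W2")]], b2 = enc$params[[nm("b2")]],
       eps = enc$params[[nm("eps")]],
       gamma = enc$params[[nm("gamma")]], beta = enc$params[[nm("beta")]],
       bn = enc$bn_states[[sprintf("drug.l%d.bn", k)]])
}

#' Encode a molecular graph (or padded batch) into node embeddings
#'
#' Composition of [project_initial()], `n_layers` [gin_layer()]s (or
#' [gcn_layer()]s for the `"gcn"` variant) and [jumping_knowledge()]. Dummy
#' nodes contribute nothing: they carry zero features, no edges, are excluded
#' from batchnorm statistics and are re-zeroed after every layer.
#'
#' @param graph a `mol_graph` or a `graph_batch` from [pad_batch()].
#' @param encoder a `drug_encoder` parameter set.
#' @param training logical; training-mode batchnorm (NULL = inherit the
#'   ambient mode set by [ag_record()]/[ag_no_grad()]).
#' @return list with tensors `H0`, `per_layer` (length K), `h_jk`, plus
#'   `node_mask` and the batch used.
#' @export
encode_drug <- function(graph, encoder, training = NULL) {
  if (is.null(training)) training <- isTRUE(.ag$training)
  batch <- if (inherits(graph, "graph_batch")) graph else pad_batch(list(graph))
  run <- function() {
    H0 <- project_initial(batch$features, encoder$params[["drug.W0"]])
    H <- H0
    per_layer <- vector("list", encoder$n_layers)
    if (encoder$variant == "gcn") {
      deg <- Matrix::rowSums(batch$adjacency) + 1
      norm_adj <- Matrix::Diagonal(x = 1 / deg) %*%
        (batch$adjacency + Matrix::Diagonal(n = nrow(batch$adjacency)))
      norm_adj <- methods::as(norm_adj, "CsparseMatrix")
    }
    for (k in seq_len(encoder$n_layers)) {
      H <- if (encoder$variant == "gin") {
        gin_layer(H, batch$adjacency, layer_slot(encoder, k),
                  mask = batch$node_mask)
      } else {
        gcn_layer(H, norm_adj, layer_slot(encoder, k), mask = batch$node_mask)
      }
      per_layer[[k]] <- H
    }
    h_jk <- jumping_knowledge(per_layer, encoder$params[["drug.W_JK"]])
    h_jk <- mask_rows_const(h_jk, batch$node_mask)
    list(H0 = H0, per_layer = per_layer, h_jk = h_jk,
         node_mask = batch$node_mask, batch = batch)
  }
  if (isTRUE(.ag$recording)) run() else ag_no_grad(run(), training = training)
}
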