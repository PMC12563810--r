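# Full model: drug encoder + protein encoder + k-mer projection + gated
# cross-attention + MLP head, with an Adam trainer (binary cross-entropy,
# best-validation-AUROC checkpointing), batched prediction, the five-run
# evaluation protocol, and JSON checkpoints.

#' Assemble a drug-target interaction model
#'
#' All learnable tensors are initialized from `config$seed`, so identical
#' configs yield identical models. Architecture switches (`use_jk`,
#' `use_residual`, `use_gca`, `encoder_variant`, `gating_mode`, `use_kmer`,
#' `bidirectional`, `n_heads`) select the ablation variants.
#'
#' @param config a `dti_config` from [dti_config()].
#' @return object of class `dti_model`.
#' @export
dti_model <- function(config = dti_config()) {
  stopifnot(inherits(config, "dti_config"))
  d <- config$embedding_dim
  with_seed(config$seed, function() {
    drug <- drug_encoder_params(d, n_layers = config$n_gin_layers,
                                variant = config$encoder_variant)
    prot <- protein_encoder_params(d, n_blocks = config$n_residual_blocks,
                                   kernel_sizes = config$kernel_sizes,
                                   dropout = config$dropout,
                                   use_residual = config$use_residual)
    fusion <- list(use_gca = config$use_gca,
                   bidirectional = config$bidirectional,
                   pool_size = config$pool_size)
    params <- c(drug$params, prot$params)
    if (config$use_gca) {
      fusion$p2d <- gca_params(d, d, d, n_heads = config$n_heads,
                               gating_mode = config$gating_mode,
                               alpha = config$static_alpha, prefix = "gca.p2d")
      params <- c(params, fusion$p2d$params)
      if (config$bidirectional) {
        fusion$d2p <- gca_params(d, d, d, n_heads = config$n_heads,
                                 gating_mode = config$gating_mode,
                                 alpha = config$static_alpha, prefix = "gca.d2p")
        params <- c(params, fusion$d2p$params)
      }
    }
    f_width <- if (config$use_gca) {
      d * (1L + as.integer(config$bidirectional))
    } else {
      2L * d
    }
    kmer_seed <- config$seed + 104729L  # offset keeps R independent of init draws
    R <- NULL
    if (config$use_kmer) {
      f_width <- f_width + config$kmer_dim
      Rmat <- make_projection(25L^config$kmer_k, config$kmer_dim,
                              seed = kmer_seed)
      R <- if (config$kmer_trainable) ag_tensor(Rmat, "kmer.R") else Rmat
      if (config$kmer_trainable) params[["kmer.R"]] <- R
    }
    head <- list("head.W1" = nn_init_weight(f_width, d, "head.W1"),
                 "head.b1" = nn_init_bias(d, "head.b1"),
                 "head.W2" = nn_init_weight(d, 1L, "head.W2"),
                 "head.b2" = nn_init_bias(1L, "head.b2"))
    params <- c(params, head)
    structure(list(config = config, drug = drug, prot = prot, fusion = fusion,
                   head = head, R = R, kmer_seed = kmer_seed, params = params,
                   bn_states = c(drug$bn_states, prot$bn_states)),
              class = "dti_model")
  })
}

#' @export
print.dti_model <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf("<dti_model: %d tensors, %s parameters, D = %d>\n",
              length(x$params), format(n_par, big.mark = ","),
              x$config$embedding_dim))
  invisible(x)
}

graph_cache_get <- function(smiles) {
  key <- paste0("graph:", smiles)
  if (exists(key, envir = .chem$cache)) return(get(key, envir = .chem$cache))
  g <- smiles_to_graph(smiles)
  assign(key, g, envir = .chem$cache)
  g
}

#' Prepare a batch of interaction records for the forward pass
#'
#' Parses and caches molecular graphs and protein tokens, pads drugs to the
#' batch's largest molecule and proteins to the longest sequence, and builds
#' the sparse k-mer frequency matrix.
#'
#' @param records data.frame with `smiles`, `sequence` (and optionally
#'   `label`).
#' @param config the model's `dti_config`.
#' @param max_nodes optional fixed padded node count.
#' @return a `dti_batch` list.
#' @export
prepare_batch <- function(records, config, max_nodes = NULL) {
  B <- nrow(records)
  perceive_smiles(unique(records$smiles))  # one backend call for the batch
  graphs <- lapply(records$smiles, graph_cache_get)
  gb <- pad_batch(graphs, max_nodes = max_nodes)
  toks <- lapply(records$sequence, tokenize_protein)
  lens <- vapply(toks, function(t) t$length, integer(1))
  Lmax <- max(lens)
  pidx <- integer(B * Lmax)
  pmask <- logical(B * Lmax)
  for (b in seq_len(B)) {
    off <- (b - 1L) * Lmax
    pidx[off + seq_len(lens[b])] <- toks[[b]]$indices
    pmask[off + seq_len(lens[b])] <- TRUE
  }
  km <- if (config$use_kmer) kmer_matrix(records$sequence, k = config$kmer_k) else NULL
  structure(list(
    graph_batch = gb, prot_idx = pidx, prot_mask = pmask, prot_len = lens,
    Lmax = Lmax, n = B, kmer = km,
    labels = if ("label" %in% names(records)) as.numeric(records$label) else NULL),
    class = "dti_batch")
}

#' Forward pass over a prepared batch
#'
#' Encodes both modalities, fuses them per pair through gated cross-attention
#' (or plain concatenation under the fusion ablation), appends the projected
#' k-mer features and applies the MLP head. Call inside [ag_record()] to
#' obtain gradients; otherwise wrap in [ag_no_grad()].
#'
#' @param model a `dti_model`; @param batch a `dti_batch`.
#' @param keep_attention also return per-pair attention maps and gate values.
#' @return list with `logits` (tensor B x 1), `probs` (numeric), `loss`
#'   (tensor, if labels present) and optionally `attention`.
#' @export
forward_batch <- function(model, batch, keep_attention = FALSE) {
  cfg <- model$config
  denc <- encode_drug(batch$graph_batch, model$drug)
  h_drug <- if (cfg$use_jk) denc$h_jk else denc$per_layer[[model$drug$n_layers]]

  X_p <- embed_and_project(batch$prot_idx, model$prot)
  X_p <- mask_rows_const(X_p, batch$prot_mask)
  Y <- X_p
  for (b in seq_len(model$prot$n_blocks)) {
    Y <- residual_block(Y, model$prot, b, len = batch$Lmax, n_seq = batch$n,
                        mask = batch$prot_mask)
  }

  kproj <- NULL
  if (cfg$use_kmer) {
    kproj <- if (is_ag(model$R)) {
      ag_spmm(batch$kmer, model$R, At = Matrix::t(batch$kmer))
    } else {
      as.matrix(batch$kmer %*% model$R)
    }
  }

  maxN <- batch$graph_batch$max_nodes
  f_rows <- vector("list", batch$n)
  attention <- if (keep_attention) vector("list", batch$n) else NULL
  for (b in seq_len(batch$n)) {
    drows <- (b - 1L) * maxN + seq_len(batch$graph_batch$n_real[b])
    prows_b <- (b - 1L) * batch$Lmax + seq_len(batch$prot_len[b])
    Hd <- ag_rows(h_drug, drows)
    Hp <- ag_rows(Y, prows_b)
    fz <- gca_forward(Hd, Hp, model$fusion)
    f_b <- fz$f
    if (cfg$use_kmer) f_b <- ag_cbind(list(f_b, ag_rows(kproj, b)))
    f_rows[[b]] <- f_b
    if (keep_attention) {
      attention[[b]] <- list(att_maps = fz$att_maps, alpha = fz$alpha,
                             n_atoms = batch$graph_batch$n_real[b],
                             n_residues = batch$prot_len[b])
    }
  }
  f <- ag_rbind(f_rows)
  hidden <- ag_relu(ag_add_bias(ag_mm(f, model$head[["head.W1"]]), model$head[["head.b1"]]))
  logits <- ag_add_bias(ag_mm(hidden, model$head[["head.W2"]]), model$head[["head.b2"]])
  probs <- as.numeric(stats::plogis(ag_value(logits)))
  probs <- pmin(pmax(probs, 1e-12), 1 - 1e-12)  # keep strictly inside (0, 1)
  out <- list(logits = logits, probs = probs)
  if (!is.null(batch$labels)) out$loss <- ag_bce_logits(logits, batch$labels)
  if (keep_attention) out$attention <- attention
  out
}

#' Predict interaction probabilities
#'
#' Evaluation-mode forward pass (running batchnorm statistics, no dropout);
#' every probability is strictly inside (0, 1).
#'
#' @param model a `dti_model`.
#' @param records data.frame with `smiles` and `sequence`.
#' @param batch_size evaluation batch size.
#' @return numeric vector of probabilities, one per record.
#' @export
predict_dti <- function(model, records, batch_size = 64L) {
  n <- nrow(records)
  probs <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    rows <- s:min(s + batch_size - 1L, n)
    batch <- prepare_batch(records[rows, , drop = FALSE], model$config)
    out <- ag_no_grad(forward_batch(model, batch))
    probs[rows] <- out$probs
  }
  probs
}

snapshot_values <- function(model) {
  list(params = lapply(model$params, function(p) p$value),
       bn = lapply(model$bn_states, function(s)
         list(m = s$running_mean, v = s$running_var)))
}

restore_values <- function(model, snap) {
  for (nm in names(snap$params)) model$params[[nm]]$value <- snap$params[[nm]]
  for (nm in names(snap$bn)) {
    model$bn_states[[nm]]$running_mean <- snap$bn[[nm]]$m
    model$bn_states[[nm]]$running_var <- snap$bn[[nm]]$v
  }
  invisible(model)
}

#' Train a model
#'
#' Minimizes mean binary cross-entropy with Adam. After every epoch the model
#' is scored on the validation set and the parameters achieving the best
#' validation AUROC are retained (and restored into the returned model).
#' Training stops early when validation AUROC reaches `config$stop_auroc` or
#' fails to improve for `config$patience` epochs.
#'
#' @param model a `dti_model` (modified in place and returned).
#' @param train_records,val_records non-empty interaction data.frames with
#'   labels.
#' @param quiet suppress per-epoch logging.
#' @param log_file optional CSV path receiving the epoch history.
#' @return list with `model`, `history` (data.frame: epoch, train_loss,
#'   val_auroc, val_auprc), `best_epoch`, `best_val_auroc`.
#' @export
train_dti <- function(model, train_records, val_records, quiet = FALSE,
                      log_file = NULL) {
  if (nrow(train_records) == 0L || nrow(val_records) == 0L)
    stop("train_dti: empty training or validation split")
  cfg <- model$config
  opt <- adam_init(model$params, lr = cfg$learning_rate)
  best <- list(auroc = -Inf, epoch = 0L, snap = snapshot_values(model))
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auroc = numeric(0), val_auprc = numeric(0))
  with_seed(cfg$seed, function() {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(nrow(train_records))
      starts <- seq(1L, nrow(train_records), by = cfg$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + cfg$batch_size - 1L, nrow(train_records))]
        batch <- prepare_batch(train_records[rows, , drop = FALSE], cfg)
        ag_zero_grad(model$params)
        out <- ag_record(forward_batch(model, batch), training = TRUE)
        ag_backward(out$loss)
        adam_step(opt, clip = cfg$grad_clip)
        epoch_loss <- epoch_loss + as.numeric(ag_value(out$loss)) * length(rows)
      }
      epoch_loss <- epoch_loss / nrow(train_records)
      val_probs <- predict_dti(model, val_records, cfg$batch_size)
      v_auroc <- auroc(val_probs, val_records$label)
      v_auprc <- auprc(val_probs, val_records$label)
      history[nrow(history) + 1L, ] <<- list(epoch, epoch_loss, v_auroc, v_auprc)
      if (!quiet)
        message(sprintf("epoch %3d | loss %.4f | val AUROC %.4f | val AUPRC %.4f",
                        epoch, epoch_loss, v_auroc, v_auprc))
      if (v_auroc > best$auroc) {
        best <<- list(auroc = v_auroc, epoch = epoch, snap = snapshot_values(model))
      }
      if (v_auroc >= cfg$stop_auroc) break
      if (epoch - best$epoch >= cfg$patience) break
    }
  })
  restore_values(model, best$snap)
  if (!is.null(log_file)) utils::write.csv(history, log_file, row.names = FALSE)
  list(model = model, history = history, best_epoch = best$epoch,
       best_val_auroc = best$auroc)
}

#' Five-run evaluation protocol
#'
#' For each run: an independent 7:1:2 split and model initialization (seeds
#' `config$seed + run - 1`), training with best-validation-AUROC selection,
#' then test-set metrics. Reports per-run metrics with mean and standard
#' deviation per metric, plus the id of the run with the best validation
#' AUROC.
#'
#' @param records interaction data.frame (splittable 7:1:2).
#' @param config a `dti_config`.
#' @param n_runs number of independent runs (default 5).
#' @param quiet suppress training logs.
#' @return object of class `run_summary`.
#' @export
evaluate_protocol <- function(records, config, n_runs = 5L, quiet = TRUE) {
  stopifnot(n_runs >= 1L)
  metric_names <- c("auroc", "auprc", "accuracy", "sensitivity", "specificity")
  per_run <- data.frame()
  val_aurocs <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    cfg <- validate_config(cfg)
    sp <- split_dataset(records, seed = cfg$seed)
    fit <- train_dti(dti_model(cfg), sp$train, sp$val, quiet = quiet)
    m <- compute_metrics(predict_dti(fit$model, sp$test), sp$test$label)
    val_aurocs[r] <- fit$best_val_auroc
    per_run <- rbind(per_run, data.frame(run = r, t(unlist(m[metric_names]))))
  }
  means <- colMeans(per_run[metric_names])
  sds <- vapply(per_run[metric_names], stats::sd, numeric(1))
  sds[is.na(sds)] <- 0  # single run
  structure(list(per_run = per_run, mean = means, sd = sds,
                 selected_run = which.max(val_aurocs), n_runs = n_runs),
            class = "run_summary")
}

#' @export
print.run_summary <- function(x, ...) {
  cat(sprintf("Evaluation over %d run(s); selected run %d\n",
              x$n_runs, x$selected_run))
  for (m in names(x$mean)) {
    cat(sprintf("  %-12s %.3f ± %.3f\n", m, x$mean[m], x$sd[m]))
  }
  invisible(x)
}

#' Format a run summary as a metrics table
#' @param x a `run_summary`.
#' @return data.frame with columns `metric` and `mean_sd` ("mean ± sd").
#' @export
summary_table <- function(x) {
  stopifnot(inherits(x, "run_summary"))
  data.frame(metric = names(x$mean),
             mean_sd = sprintf("%.3f ± %.3f", x$mean, x$sd),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Save a model checkpoint
#'
#' Versioned JSON archive holding the config, every parameter tensor, the
#' batchnorm running statistics and the k-mer projection seed (so a frozen
#' projection is regenerated identically at load time).
#'
#' @param model a `dti_model`; @param path output file (.json).
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    format = "gcadti-checkpoint", version = 1L,
    config = unclass(model$config),
    kmer_seed = model$kmer_seed,
    params = lapply(model$params, function(p)
      list(dim = dim(p$value), data = as.numeric(p$value))),
    bn = lapply(model$bn_states, function(s)
      list(m = s$running_mean, v = s$running_var)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return a `dti_model` with restored parameters.
#' @export
load_checkpoint <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "gcadti-checkpoint"))
    stop("load_checkpoint: not a gcadti checkpoint file")
  cfg_raw <- payload$config
  cfg_raw$kernel_sizes <- as.integer(unlist(cfg_raw$kernel_sizes))
  cfg <- validate_config(structure(cfg_raw, class = "dti_config"))
  model <- dti_model(cfg)
  for (nm in names(payload$params)) {
    p <- payload$params[[nm]]
    if (is.null(model$params[[nm]]))
      stop(sprintf("load_checkpoint: unknown parameter '%s'", nm))
    model$params[[nm]]$value <- matrix(p$data, p$dim[1], p$dim[2])
  }
  for (nm in names(payload$bn)) {
    model$bn_states[[nm]]$running_mean <- payload$bn[[nm]]$m
    model$bn_states[[nm]]$running_var <- payload$bn[[nm]]$v
  }
  model
}
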