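# Run configuration. Defaults reproduce the benchmark-scale training setup
# (Adam, lr 1e-5, 100 epochs, batch 64, 2 residual blocks, 4 GIN layers,
# kernels [3, 6, 9], 4 attention heads, pooling size 3); the "fast" profile
# is the documented scaled-down setting used by the test suite and the
# synthetic-data learning check. Every architecture ablation is reachable
# purely through config switches.

config_defaults <- function() {
  list(
    optimizer = "adam",
    learning_rate = 1e-5,
    max_epochs = 100L,
    batch_size = 64L,
    n_residual_blocks = 2L,
    n_gin_layers = 4L,
    kernel_sizes = c(3L, 6L, 9L),
    n_heads = 4L,
    pool_size = 3L,
    gating_mode = "dynamic",     # dynamic | static | averaged
    static_alpha = 0.5,
    bidirectional = TRUE,
    use_kmer = TRUE,
    use_jk = TRUE,
    use_residual = TRUE,
    use_gca = TRUE,
    encoder_variant = "gin",     # gin | gcn
    embedding_dim = 128L,
    kmer_k = 3L,
    kmer_dim = NULL,             # NULL -> embedding_dim
    kmer_trainable = TRUE,
    dropout = 0.1,
    grad_clip = 5,
    patience = 10L,
    stop_auroc = 0.999,
    seed = 1L)
}

#' Build a run configuration
#'
#' Unset fields take the benchmark defaults; `profile = "fast"` switches to
#' the scaled-down training profile (64-dim latents, 2 heads, learning rate
#' 1e-3, 30 epochs) used throughout the test suite, where the benchmark
#' schedule would be impractical.
#'
#' @param ... configuration overrides (see [config_defaults()] for fields).
#' @param profile `"default"` or `"fast"`.
#' @return validated `dti_config` list.
#' @export
dti_config <- function(..., profile = c("default", "fast")) {
  profile <- match.arg(profile)
  cfg <- config_defaults()
  if (profile == "fast") {
    cfg$embedding_dim <- 64L
    cfg$n_heads <- 2L
    cfg$learning_rate <- 1e-3
    cfg$max_epochs <- 30L
  }
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("dti_config: all overrides must be named")
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop(sprintf("dti_config: unrecognized key(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  num_fields <- c("learning_rate", "max_epochs", "batch_size",
                  "n_residual_blocks", "n_gin_layers", "n_heads", "pool_size",
                  "static_alpha", "embedding_dim", "kmer_k", "dropout",
                  "patience", "seed")
  for (f in num_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]))
      stop(sprintf("config: field '%s' must be a single number", f))
  }
  if (!is.numeric(cfg$kernel_sizes) || any(cfg$kernel_sizes < 1))
    stop("config: field 'kernel_sizes' must be positive integers")
  if (!cfg$gating_mode %in% c("dynamic", "static", "averaged"))
    stop("config: field 'gating_mode' must be dynamic, static or averaged")
  if (!cfg$encoder_variant %in% c("gin", "gcn"))
    stop("config: field 'encoder_variant' must be gin or gcn")
  if (cfg$gating_mode == "static" &&
      (cfg$static_alpha <= 0 || cfg$static_alpha >= 1))
    stop("config: field 'static_alpha' must lie strictly in (0, 1)")
  if (!identical(tolower(cfg$optimizer), "adam"))
    stop("config: field 'optimizer' only supports 'adam'")
  for (f in c("bidirectional", "use_kmer", "use_jk", "use_residual", "use_gca",
              "kmer_trainable")) {
    if (!is.logical(cfg[[f]]) || length(cfg[[f]]) != 1L || is.na(cfg[[f]]))
      stop(sprintf("config: field '%s' must be TRUE or FALSE", f))
  }
  if (is.null(cfg$kmer_dim)) cfg$kmer_dim <- cfg$embedding_dim
  ints <- c("max_epochs", "batch_size", "n_residual_blocks", "n_gin_layers",
            "n_heads", "pool_size", "embedding_dim", "kmer_k", "kmer_dim",
            "patience", "seed")
  for (f in ints) cfg[[f]] <- as.integer(cfg[[f]])
  cfg$kernel_sizes <- as.integer(cfg$kernel_sizes)
  if (cfg$embedding_dim %% cfg$n_heads != 0L)
    stop("config: 'embedding_dim' must be divisible by 'n_heads'")
  structure(cfg, class = "dti_config")
}

#' Load a configuration file
#'
#' YAML (or JSON, which YAML subsumes) mapping of configuration keys; unset
#' keys take the benchmark defaults and unknown keys are rejected by name.
#' An empty file yields the full default configuration.
#'
#' @param path config file path.
#' @param profile base profile the file overrides.
#' @return validated `dti_config`.
#' @export
load_config <- function(path, profile = "default") {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("load_config: file must contain a key-value mapping")
  do.call(dti_config, c(raw, list(profile = profile)))
}

#' @export
print.dti_config <- function(x, ...) {
  cat("<dti_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-18s %s\n", f, paste(format(x[[f]]), collapse = ", ")))
  }
  invisible(x)
}

#' Run the single-switch ablation suite
#'
#' Trains and evaluates the full model plus each requested single-switch
#' variant under identical seeds, split and hyperparameters, so only the
#' switched component differs between rows.
#'
#' @param config a `dti_config` (the full-model configuration).
#' @param records interaction data.frame.
#' @param variants named list of config overrides; the default covers the
#'   standard axes: JK removal, residual removal, GCA-to-concatenation,
#'   GIN-to-GCN, and k-mer features off.
#' @param split_seed seed for the shared 7:1:2 split.
#' @param quiet suppress progress output.
#' @return data.frame with one metrics row per variant (full model first).
#' @export
run_ablation_suite <- function(config, records, variants = NULL,
                               split_seed = config$seed, quiet = TRUE) {
  if (is.null(variants)) {
    variants <- list(
      "no_jk" = list(use_jk = FALSE),
      "no_residual" = list(use_residual = FALSE),
      "no_gca" = list(use_gca = FALSE),
      "gcn" = list(encoder_variant = "gcn"),
      "no_kmer" = list(use_kmer = FALSE))
  }
  sp <- split_dataset(records, seed = split_seed)
  rows <- list()
  run_one <- function(name, overrides) {
    cfg <- config
    cfg[names(overrides)] <- overrides
    cfg <- validate_config(cfg)
    model <- dti_model(cfg)
    fit <- train_dti(model, sp$train, sp$val, quiet = quiet)
    m <- compute_metrics(predict_dti(fit$model, sp$test), sp$test$label)
    data.frame(variant = name, auroc = m$auroc, auprc = m$auprc,
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, stringsAsFactors = FALSE)
  }
  rows[["full"]] <- run_one("full", list())
  for (nm in names(variants)) rows[[nm]] <- run_one(nm, variants[[nm]])
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
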