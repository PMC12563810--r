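# Shared fixtures. Heavy artifacts (trained models) are built once per test
# session and memoized here; everything is generated in code — no stored data.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Tiny deterministic config for fast structural tests.
tiny_config <- function(...) {
  dti_config(profile = "fast", embedding_dim = 16L, n_heads = 2L,
             dropout = 0, seed = 7L, ...)
}

# Small synthetic dataset with short proteins for cheap forwards.
tiny_dataset <- function(n = 40L, seed = 3L, noise = 0) {
  generate_dataset(synthetic_spec(n_pairs = n, protein_length = c(20L, 30L),
                                  noise_rate = noise, seed = seed))
}

# A barely-trained small model + data; enough for checkpoints/CLI/attribution
# plumbing without real training cost.
tiny_fit <- function() {
  memo("tiny_fit", function() {
    ds <- tiny_dataset(n = 60L)
    cfg <- tiny_config(max_epochs = 1L)
    sp <- split_dataset(ds, seed = 5L)
    fit <- train_dti(dti_model(cfg), sp$train, sp$val, quiet = TRUE)
    list(fit = fit, data = ds, split = sp, config = cfg)
  })
}

# The scaled-down learning check (acceptance criterion): fast profile,
# D_d = D_p = 64, 2 heads, lr 1e-3, <= 30 epochs, n = 2000 noiseless pairs.
# Trained once and reused by the acceptance and interpretability tests.
learning_fixture <- function() {
  memo("learning_fixture", function() {
    ds <- generate_dataset(synthetic_spec(n_pairs = 2000L, seed = 11L))
    cfg <- dti_config(profile = "fast", seed = 42L)
    sp <- split_dataset(ds, seed = 42L)
    fit <- train_dti(dti_model(cfg), sp$train, sp$val, quiet = TRUE)
    test_probs <- predict_dti(fit$model, sp$test)
    list(fit = fit, data = ds, split = sp, config = cfg,
         metrics = compute_metrics(test_probs, sp$test$label))
  })
}

# Central finite-difference gradient check for a scalar-valued builder.
# build(params) must construct the op graph from a named list of ag_tensors
# and return the scalar output node.
expect_grad_ok <- function(build, params, tol = 1e-4, h = 1e-6, n_probe = 4L) {
  ag_zero_grad(params)
  out <- ag_record(build(params), training = TRUE)
  ag_backward(out)
  loss_at <- function() as.numeric(gcadti:::ag_value(
    ag_no_grad(build(params), training = TRUE)))
  for (nm in names(params)) {
    p <- params[[nm]]
    an_full <- if (is.null(p$grad)) matrix(0, nrow(p$value), ncol(p$value)) else p$grad
    idx <- sample(length(p$value), min(n_probe, length(p$value)))
    for (i in idx) {
      v0 <- p$value[i]
      p$value[i] <- v0 + h; lp <- loss_at()
      p$value[i] <- v0 - h; lm <- loss_at()
      p$value[i] <- v0
      fd <- (lp - lm) / (2 * h)
      expect_lt(abs(fd - an_full[i]) / max(1, abs(fd), abs(an_full[i])), tol,
                label = sprintf("grad mismatch at %s[%d] (fd %.3e vs an %.3e)",
                                nm, i, fd, an_full[i]))
    }
  }
  invisible(out)
}

# Hand-built molecular graph (no SMILES backend) for permutation/padding
# tests: random 74-dim features, explicit edge list.
toy_graph <- function(n, edges, seed = 1L) {
  feats <- gcadti:::with_seed(seed, function()
    matrix(stats::runif(n * atom_feature_dim()), n))
  ed <- if (length(edges)) {
    data.frame(i = vapply(edges, `[`, integer(1), 1L),
               j = vapply(edges, `[`, integer(1), 2L), order = 1)
  } else data.frame(i = integer(0), j = integer(0), order = numeric(0))
  structure(list(n_real = as.integer(n), atoms = NULL, edges = ed,
                 atom_features = feats,
                 node_mask = rep(TRUE, n), smiles = "<toy>"),
            class = "mol_graph")
}

# Apply a node permutation to a toy graph: row r of the permuted graph is row
# perm[r] of the original.
permute_graph <- function(g, perm) {
  inv <- order(perm)
  g2 <- g
  g2$atom_features <- g$atom_features[perm, , drop = FALSE]
  if (nrow(g$edges)) {
    g2$edges$i <- inv[g$edges$i]
    g2$edges$j <- inv[g$edges$j]
  }
  g2
}
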