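# GIN drug encoder: hand-evaluated update rule, permutation equivariance
# (exhaustive on small graphs), padding invariance, JK aggregation, and the
# GCN ablation drop-in.

# minimal permutations generator (avoids extra dependencies)
gtools_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- gtools_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# Plain-R oracle for the pre-activation GIN update: for every node v,
# MLP((1 + eps) h_v + sum_{u in N(v)} h_u), with the encoder's 2-layer MLP.
gin_oracle <- function(H, edges, eps, W1, b1, W2, b2) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W2))
  for (v in seq_len(n)) {
    nb <- c(edges$j[edges$i == v], edges$i[edges$j == v])
    agg <- (1 + eps) * H[v, ]
    for (u in nb) agg <- agg + H[u, ]
    hid <- pmax(agg %*% W1 + as.numeric(b1), 0)
    out[v, ] <- hid %*% W2 + as.numeric(b2)
  }
  out
}

test_that("gin_layer matches hand evaluation of the update rule", {
  # identity MLP, eps = 0, 2-node path with scalar features [1], [2] -> [3], [3]
  layer <- list(W1 = ag_tensor(matrix(1)), b1 = ag_tensor(matrix(0)),
                W2 = ag_tensor(matrix(1)), b2 = ag_tensor(matrix(0)),
                eps = ag_tensor(matrix(0)), gamma = NULL, beta = NULL, bn = NULL)
  A <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = 1, dims = c(2, 2))
  H <- matrix(c(1, 2), 2, 1)
  out <- gcadti:::ag_value(gin_layer(ag_tensor(H), A, layer, bn = FALSE))
  expect_equal(out, matrix(c(3, 3), 2, 1))

  # isolated node, eps = 0, identity MLP: unchanged before normalization
  A1 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(1, 1))
  out1 <- gcadti:::ag_value(gin_layer(ag_tensor(matrix(5)), A1, layer, bn = FALSE))
  expect_equal(out1, matrix(5))
})

test_that("gin_layer equals the brute-force oracle on random small graphs", {
  set.seed(11)
  d <- 4L
  for (case in 1:8) {
    n <- sample(2:5, 1)
    all_pairs <- t(utils::combn(n, 2))
    m <- sample.int(nrow(all_pairs), 1)
    sel <- all_pairs[sample.int(nrow(all_pairs), m), , drop = FALSE]
    edges <- data.frame(i = sel[, 1], j = sel[, 2])
    A <- Matrix::sparseMatrix(i = c(edges$i, edges$j), j = c(edges$j, edges$i),
                              x = 1, dims = c(n, n))
    H <- matrix(rnorm(n * d), n, d)
    W1 <- matrix(rnorm(d * d), d, d); b1 <- matrix(rnorm(d), 1)
    W2 <- matrix(rnorm(d * d), d, d); b2 <- matrix(rnorm(d), 1)
    eps <- rnorm(1)
    layer <- list(W1 = ag_tensor(W1), b1 = ag_tensor(b1), W2 = ag_tensor(W2),
                  b2 = ag_tensor(b2), eps = ag_tensor(matrix(eps)))
    out <- gcadti:::ag_value(gin_layer(ag_tensor(H), A, layer, bn = FALSE))
    expect_equal(out, gin_oracle(H, edges, eps, W1, b1, W2, b2),
                 tolerance = 1e-10)
  }
})

test_that("project_initial applies ReLU(X W0) with dimension checks", {
  enc <- gcadti:::with_seed(1, function() drug_encoder_params(8L, n_layers = 2L))
  Z <- matrix(0, 3, 74)
  expect_equal(gcadti:::ag_value(project_initial(Z, enc$params[["drug.W0"]])),
               matrix(0, 3, 8))
  X <- matrix(rnorm(5 * 74), 5, 74)
  H0 <- gcadti:::ag_value(project_initial(X, enc$params[["drug.W0"]]))
  expect_identical(dim(H0), c(5L, 8L))
  expect_true(all(H0 >= 0))
  expect_equal(H0, pmax(X %*% enc$params[["drug.W0"]]$value, 0))
  expect_error(project_initial(matrix(0, 3, 10), enc$params[["drug.W0"]]),
               "10 columns")
})

test_that("jumping_knowledge concatenates and projects with shape checks", {
  h1 <- matrix(1:6, 3, 2); h2 <- matrix(7:12, 3, 2)
  # K = 1 with identity projection: h_JK = h^(1)
  expect_equal(gcadti:::ag_value(jumping_knowledge(list(ag_tensor(h1)),
                                                   diag(2))), h1)
  # concat width K * D before projection; zero weights -> zero output
  W <- matrix(0, 4, 2)
  expect_equal(gcadti:::ag_value(
    jumping_knowledge(list(ag_tensor(h1), ag_tensor(h2)), W)), matrix(0, 3, 2))
  expect_error(jumping_knowledge(list(ag_tensor(h1), ag_tensor(h2)), diag(2)),
               "concat width 4")
  expect_error(jumping_knowledge(list(ag_tensor(h1), ag_tensor(matrix(0, 3, 3))),
                                 diag(2)), "inconsistent")
})

test_that("encode_drug is deterministic and returns all intermediates", {
  enc <- gcadti:::with_seed(2, function() drug_encoder_params(8L, n_layers = 4L))
  g <- toy_graph(4, list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 1L)))
  e1 <- encode_drug(g, enc)
  e2 <- encode_drug(g, enc)
  expect_equal(length(e1$per_layer), 4L)
  expect_identical(gcadti:::ag_value(e1$h_jk), gcadti:::ag_value(e2$h_jk))
  expect_true(all(is.finite(gcadti:::ag_value(e1$h_jk))))
})

test_that("encode_drug is permutation equivariant (exhaustive, <= 5 nodes)", {
  enc <- gcadti:::with_seed(3, function() drug_encoder_params(6L, n_layers = 2L))
  graphs <- list(
    toy_graph(3, list(c(1L, 2L), c(2L, 3L)), seed = 21),
    toy_graph(4, list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(1L, 4L)), seed = 22),
    toy_graph(5, list(c(1L, 2L), c(1L, 3L), c(1L, 4L), c(4L, 5L)), seed = 23))
  for (g in graphs) {
    base <- gcadti:::ag_value(encode_drug(g, enc)$h_jk)
    perms <- gtools_permutations(g$n_real)
    for (r in seq_len(nrow(perms))) {
      perm <- perms[r, ]
      hp <- gcadti:::ag_value(encode_drug(permute_graph(g, perm), enc)$h_jk)
      expect_equal(hp, base[perm, , drop = FALSE], tolerance = 1e-10)
    }
  }
})

test_that("real-node embeddings are invariant to dummy-node count", {
  enc <- gcadti:::with_seed(4, function() drug_encoder_params(8L, n_layers = 3L))
  g <- toy_graph(5, list(c(1L, 2L), c(2L, 3L), c(3L, 4L), c(4L, 5L)), seed = 31)
  un <- gcadti:::ag_value(encode_drug(pad_batch(list(g)), enc)$h_jk)
  pd <- gcadti:::ag_value(encode_drug(pad_batch(list(g), max_nodes = 50L), enc)$h_jk)
  expect_equal(pd[1:5, ], un[1:5, ], tolerance = 1e-12)
  expect_true(all(pd[6:50, ] == 0))  # dummy rows all-zero
})

test_that("the GCN drop-in differs from GIN on a non-regular graph", {
  gin <- gcadti:::with_seed(5, function() drug_encoder_params(6L, n_layers = 2L))
  gcn <- gcadti:::with_seed(5, function()
    drug_encoder_params(6L, n_layers = 2L, variant = "gcn"))
  g <- toy_graph(4, list(c(1L, 2L), c(1L, 3L), c(1L, 4L)), seed = 41)  # star
  h_gin <- gcadti:::ag_value(encode_drug(g, gin)$h_jk)
  h_gcn <- gcadti:::ag_value(encode_drug(g, gcn)$h_jk)
  expect_gt(max(abs(h_gin - h_gcn)), 1e-6)
})
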