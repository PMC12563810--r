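# Gated cross-attention: softmax normalization across head counts, key
# masking, gate endpoints and dynamic gating, pooling, bidirectional fusion
# and the concatenation ablation.

mk_gca <- function(d_q = 8L, d_kv = 8L, d_h = 8L, h = 2L, mode = "dynamic",
                   alpha = 0.5, seed = 1L) {
  gcadti:::with_seed(seed, function()
    gca_params(d_q, d_kv, d_h, n_heads = h, gating_mode = mode, alpha = alpha))
}

test_that("attention rows sum to 1 for h in {1, 2, 4} and random shapes", {
  set.seed(1)
  for (h in c(1L, 2L, 4L)) {
    for (rep_ in 1:3) {
      Lq <- sample(2:7, 1); Lk <- sample(2:7, 1)
      gca <- mk_gca(d_h = 8L, h = h, seed = h * 10L + rep_)
      Q <- matrix(rnorm(Lq * 8), Lq); K <- matrix(rnorm(Lk * 8), Lk)
      mha <- multi_head_attention(ag_tensor(Q), ag_tensor(K), ag_tensor(K), gca)
      expect_length(mha$att_map, h)
      for (m in mha$att_map) expect_equal(rowSums(m), rep(1, Lq))
      expect_identical(dim(gcadti:::ag_value(mha$A)), c(Lq, 8L))
    }
  }
})

test_that("a single key token receives weight 1 regardless of the query", {
  gca <- mk_gca(seed = 2)
  K <- matrix(rnorm(8), 1, 8)
  for (s in 1:3) {
    Q <- matrix(rnorm(3 * 8, sd = s), 3, 8)
    mha <- multi_head_attention(ag_tensor(Q), ag_tensor(K), ag_tensor(K), gca)
    for (m in mha$att_map) expect_equal(as.numeric(m), rep(1, 3))
  }
})

test_that("identical key logits yield uniform weights 1/L_k", {
  gca <- mk_gca(seed = 3)
  K <- matrix(rep(1, 5 * 8), 5, 8)  # five identical keys
  Q <- matrix(rnorm(2 * 8), 2, 8)
  mha <- multi_head_attention(ag_tensor(Q), ag_tensor(K), ag_tensor(K), gca)
  for (m in mha$att_map) expect_equal(as.numeric(m), rep(0.2, 10))
})

test_that("head count must divide the hidden width", {
  expect_error(gca_params(8L, 8L, 10L, n_heads = 4L), "not divisible")
  expect_error(gca_params(8L, 8L, 8L, n_heads = 2L, gating_mode = "static",
                          alpha = 1), "strictly in")
})

test_that("masked keys receive zero attention and padding leaves A unchanged", {
  gca <- mk_gca(seed = 4)
  set.seed(4)
  Q <- matrix(rnorm(4 * 8), 4); K <- matrix(rnorm(3 * 8), 3)
  clean <- multi_head_attention(ag_tensor(Q), ag_tensor(K), ag_tensor(K), gca)
  # pad keys with junk rows, mask them out
  Kpad <- rbind(K, matrix(99, 2, 8))
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  padded <- multi_head_attention(ag_tensor(Q), ag_tensor(Kpad), ag_tensor(Kpad),
                                 gca, key_mask = mask)
  expect_equal(gcadti:::ag_value(padded$A), gcadti:::ag_value(clean$A),
               tolerance = 1e-12)
  for (m in padded$att_map) {
    expect_true(all(m[, 4:5] == 0))
    expect_equal(rowSums(m), rep(1, 4))
  }
})

test_that("gate endpoints: alpha 1 gives A, alpha 0 gives Proj(Q)", {
  A <- matrix(rnorm(12), 3, 4); PQ <- matrix(rnorm(12), 3, 4)
  expect_equal(gcadti:::ag_value(gated_fuse(ag_tensor(A), ag_tensor(PQ), 1)), A)
  expect_equal(gcadti:::ag_value(gated_fuse(ag_tensor(A), ag_tensor(PQ), 0)), PQ)
  # fixed point: A = Proj(Q) -> H = A at any alpha
  expect_equal(gcadti:::ag_value(gated_fuse(ag_tensor(A), ag_tensor(A), 0.5)), A)
  # convex combination with a per-token alpha column
  al <- matrix(c(0.2, 0.5, 0.9), 3, 1)
  H <- gcadti:::ag_value(gated_fuse(ag_tensor(A), ag_tensor(PQ), ag_tensor(al)))
  expect_equal(H, A * as.numeric(al) + PQ * (1 - as.numeric(al)))
  expect_error(gated_fuse(ag_tensor(A), ag_tensor(PQ), 1.5), "\\[0, 1\\]")
})

test_that("dynamic gate: zero net gives 0.5; bias drives alpha monotonically", {
  gca <- mk_gca(seed = 5)  # gate net is zero-initialized
  A <- ag_tensor(matrix(rnorm(12), 3, 4))
  # widths: gate net consumes [A; Proj(Q)] with D_H = 8
  gca8 <- mk_gca(d_h = 8L, seed = 5)
  A8 <- ag_tensor(matrix(rnorm(24), 3, 8)); P8 <- ag_tensor(matrix(rnorm(24), 3, 8))
  a0 <- gcadti:::ag_value(dynamic_alpha(A8, P8, gca8))
  expect_equal(as.numeric(a0), rep(0.5, 3))
  vals <- vapply(c(0, 2, 5), function(b) {
    gca8$params[[paste0(gca8$prefix, ".bfc")]] <- ag_tensor(matrix(b, 1, 1))
    mean(gcadti:::ag_value(dynamic_alpha(A8, P8, gca8)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3], 0.99)
  expect_true(all(vals > 0 & vals < 1))
})

test_that("dynamic alpha always lies strictly inside (0, 1)", {
  set.seed(6)
  gca <- mk_gca(seed = 6)
  gca$params[[paste0(gca$prefix, ".Wfc")]]$value[] <- rnorm(16, sd = 3)
  A <- ag_tensor(matrix(rnorm(40, sd = 5), 5, 8))
  P <- ag_tensor(matrix(rnorm(40, sd = 5), 5, 8))
  a <- gcadti:::ag_value(dynamic_alpha(A, P, gca))
  expect_true(all(a > 0 & a < 1))
})

test_that("pooling composes window-3 max with token mean", {
  H <- matrix(c(1, 5, 2, 9, 0, 3,
                4, 1, 1, 2, 8, 8), 6, 2)
  pooled <- gcadti:::ag_value(gca_pool(ag_tensor(H), pool_size = 3L))
  expect_equal(as.numeric(pooled), c(mean(c(5, 9)), mean(c(4, 8))))
})

test_that("gca_forward handles directionality modes and the ablation", {
  set.seed(7)
  Hd <- ag_tensor(matrix(rnorm(4 * 8), 4, 8))
  Hp <- ag_tensor(matrix(rnorm(6 * 8), 6, 8))
  uni <- list(use_gca = TRUE, bidirectional = FALSE, pool_size = 3L,
              p2d = mk_gca(seed = 71))
  out_u <- gca_forward(Hd, Hp, uni)
  expect_length(out_u$att_maps, 1L)  # unidirectional: one map
  expect_identical(dim(out_u$att_maps$p2d[[1]]), c(6L, 4L))  # residues x atoms
  expect_equal(ncol(gcadti:::ag_value(out_u$f)), 8L)

  bi <- c(uni, list(d2p = mk_gca(seed = 72)))
  bi$bidirectional <- TRUE
  out_b <- gca_forward(Hd, Hp, bi)
  expect_length(out_b$att_maps, 2L)
  expect_identical(dim(out_b$att_maps$d2p[[1]]), c(4L, 6L))
  expect_equal(ncol(gcadti:::ag_value(out_b$f)), 16L)

  off <- list(use_gca = FALSE)
  out_o <- gca_forward(Hd, Hp, off)
  expect_length(out_o$att_maps, 0L)  # attention bypassed entirely
  expect_equal(ncol(gcadti:::ag_value(out_o$f)), 16L)
  expect_equal(as.numeric(gcadti:::ag_value(out_o$f)),
               c(colMeans(gcadti:::ag_value(Hp)), colMeans(gcadti:::ag_value(Hd))))
})

test_that("static and averaged gating modes run and give convex mixes", {
  set.seed(8)
  Hd <- ag_tensor(matrix(rnorm(3 * 8), 3, 8))
  Hp <- ag_tensor(matrix(rnorm(4 * 8), 4, 8))
  for (mode in c("static", "averaged", "dynamic")) {
    fus <- list(use_gca = TRUE, bidirectional = FALSE, pool_size = 3L,
                p2d = mk_gca(mode = mode, alpha = 0.3, seed = 80))
    out <- gca_forward(Hd, Hp, fus)
    expect_true(all(is.finite(gcadti:::ag_value(out$f))))
    a <- out$alpha$p2d
    expect_true(all(a > 0 & a < 1))
  }
})
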