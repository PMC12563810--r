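# Every primitive's pullback is validated against central finite differences;
# composite layers (conv, batchnorm with masking, attention-style chains) get
# their own checks since they combine several pullbacks.

rand_t <- function(nr, nc, seed) {
  gcadti:::with_seed(seed, function() ag_tensor(matrix(stats::rnorm(nr * nc), nr, nc)))
}

test_that("elementary op pullbacks match finite differences", {
  set.seed(1)
  a <- rand_t(4, 3, 1); b <- rand_t(3, 5, 2); c_ <- rand_t(4, 3, 3)
  bias <- rand_t(1, 5, 4); s <- rand_t(1, 1, 5); v <- rand_t(4, 1, 6)
  expect_grad_ok(function(p) ag_sum(ag_mm(p$a, p$b)), list(a = a, b = b))
  expect_grad_ok(function(p) ag_sum(ag_mm_bt(p$a, p$c_)), list(a = a, c_ = c_))
  expect_grad_ok(function(p) ag_sum(ag_add(p$a, p$c_)), list(a = a, c_ = c_))
  expect_grad_ok(function(p) ag_sum(ag_add_bias(ag_mm(p$a, p$b), p$bias)),
                 list(a = a, b = b, bias = bias))
  expect_grad_ok(function(p) ag_sum(ag_mul(p$a, p$c_)), list(a = a, c_ = c_))
  expect_grad_ok(function(p) ag_sum(ag_mul_scalar(p$a, p$s)), list(a = a, s = s))
  expect_grad_ok(function(p) ag_sum(ag_mul_colvec(p$a, p$v)), list(a = a, v = v))
  expect_grad_ok(function(p) ag_sum(ag_sigmoid(p$a)), list(a = a))
  expect_grad_ok(function(p) ag_sum(ag_scale(p$a, -2.5)), list(a = a))
})

test_that("relu pullback matches finite differences away from the kink", {
  # entries bounded away from 0 so the central difference is valid
  a <- ag_tensor(matrix(c(-2, -1, 0.5, 1.5, -0.7, 2.2), 2, 3))
  expect_grad_ok(function(p) ag_sum(ag_relu(p$a)), list(a = a))
})

test_that("softmax, gather, slice, concat and pooling pullbacks are correct", {
  set.seed(2)
  a <- rand_t(5, 4, 7); b <- rand_t(5, 3, 8); w <- rand_t(4, 2, 9)
  expect_grad_ok(function(p) ag_sum(ag_mul(ag_softmax_rows(p$a), matrix(1:20 / 7, 5, 4))),
                 list(a = a))
  mask <- c(TRUE, FALSE, TRUE, TRUE)
  expect_grad_ok(function(p) ag_sum(ag_mul(ag_softmax_rows(p$a, mask), matrix(1:20 / 7, 5, 4))),
                 list(a = a))
  expect_grad_ok(function(p) ag_sum(ag_mm(ag_rows(p$a, c(2L, 2L, 0L, 4L, 1L)), p$w)),
                 list(a = a, w = w))
  expect_grad_ok(function(p) ag_sum(ag_mul(ag_cols(p$a, c(3L, 1L)), matrix(1, 5, 2))),
                 list(a = a))
  expect_grad_ok(function(p) ag_sum(ag_mm(ag_cbind(list(p$a, p$b)), rand_t(7, 1, 10)$value)),
                 list(a = a, b = b))
  a2 <- rand_t(3, 4, 16)
  expect_grad_ok(function(p) ag_sum(ag_mul(ag_rbind(list(p$a, p$a2)),
                                           matrix(1:32 / 11, 8, 4))),
                 list(a = a, a2 = a2))
  expect_grad_ok(function(p) ag_sum(ag_mul(ag_maxpool_rows(p$a, 2L), matrix(1:12 / 5, 3, 4))),
                 list(a = a))
})

test_that("masked softmax zeroes masked keys and rows still sum to 1", {
  set.seed(3)
  x <- matrix(rnorm(12), 3, 4)
  mask <- c(TRUE, TRUE, FALSE, TRUE)
  s <- gcadti:::ag_value(ag_softmax_rows(ag_tensor(x), mask))
  expect_equal(rowSums(s), rep(1, 3))
  expect_true(all(s[, 3] == 0))
})

test_that("batchnorm pullback is correct with and without masked rows", {
  set.seed(4)
  a <- rand_t(6, 3, 11)
  gamma <- ag_tensor(matrix(c(1.2, 0.8, 1.1), 1)); beta <- ag_tensor(matrix(0.1, 1, 3))
  st <- nn_bn_state(3)
  probe <- matrix(seq_len(18) / 10, 6, 3)
  expect_grad_ok(function(p) ag_sum(ag_mul(
    ag_batchnorm(p$a, p$gamma, p$beta, st), probe)),
    list(a = a, gamma = gamma, beta = beta), tol = 1e-3)
  # masked: stats over rows 1-4 only, dummy rows 5-6 still transformed
  st2 <- nn_bn_state(3)
  expect_grad_ok(function(p) ag_sum(ag_mul(
    ag_batchnorm(p$a, p$gamma, p$beta, st2, rows = 1:4), probe)),
    list(a = a, gamma = gamma, beta = beta), tol = 1e-3)
})

test_that("batchnorm eval mode uses running statistics", {
  st <- nn_bn_state(2)
  st$running_mean <- c(1, -1); st$running_var <- c(4, 0.25)
  x <- matrix(c(3, 1, 0, -2), 2, 2)
  out <- gcadti:::ag_value(ag_no_grad(
    ag_batchnorm(ag_tensor(x), ag_tensor(matrix(1, 1, 2)),
                 ag_tensor(matrix(0, 1, 2)), st), training = FALSE))
  expect_equal(out, (x - rep(c(1, -1), each = 2)) /
                 rep(sqrt(c(4, 0.25) + 1e-5), each = 2), tolerance = 1e-6)
})

test_that("conv1d pullback is correct and preserves length", {
  set.seed(5)
  x <- rand_t(10, 3, 12)  # 2 sequences of length 5, 3 channels
  W <- rand_t(9, 2, 13)   # width 3
  b <- rand_t(1, 2, 14)
  probe <- matrix(seq_len(20) / 9, 10, 2)
  expect_grad_ok(function(p) ag_sum(ag_mul(
    nn_conv1d(p$x, p$W, p$b, width = 3L, len = 5L, n_seq = 2L), probe)),
    list(x = x, W = W, b = b))
  out <- gcadti:::ag_value(nn_conv1d(x, W, b, 3L, 5L, 2L))
  expect_identical(dim(out), c(10L, 2L))
})

test_that("conv1d windows do not leak across stacked sequences", {
  # one-hot tap at the left neighbor: output at position t = x[t-1]
  xv <- matrix(0, 6, 1); xv[3, 1] <- 7  # last position of sequence 1
  W <- matrix(c(1, 0, 0), 3, 1)  # only the j=1 tap (offset -1)
  out <- gcadti:::ag_value(nn_conv1d(ag_tensor(xv), ag_tensor(W),
                                     ag_tensor(matrix(0, 1, 1)),
                                     width = 3L, len = 3L, n_seq = 2L))
  expect_equal(out[4, 1], 0)  # first position of sequence 2 sees zero padding
  expect_equal(out[3, 1], 0)
  expect_equal(sum(out != 0), 0)  # x[3] only feeds forbidden cross-boundary tap
})

test_that("bce-with-logits matches the closed form and its gradient", {
  z <- ag_tensor(matrix(c(2, -1, 0.5), 3, 1))
  y <- c(1, 0, 1)
  loss <- ag_record(ag_bce_logits(z, y))
  manual <- -mean(y * log(stats::plogis(c(2, -1, 0.5))) +
                  (1 - y) * log(1 - stats::plogis(c(2, -1, 0.5))))
  expect_equal(as.numeric(gcadti:::ag_value(loss)), manual, tolerance = 1e-10)
  ag_backward(loss)
  expect_equal(as.numeric(z$grad), (stats::plogis(c(2, -1, 0.5)) - y) / 3,
               tolerance = 1e-10)
})

test_that("sparse product pullback matches dense computation", {
  set.seed(6)
  A <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 3),
                            x = c(1, 1, 2, 1), dims = c(3, 3))
  h <- rand_t(3, 2, 15)
  probe <- matrix(1:6 / 4, 3, 2)
  expect_grad_ok(function(p) ag_sum(ag_mul(ag_spmm(A, p$h), probe)), list(h = h))
})

test_that("tape mechanics: no_grad records nothing, zero_grad clears", {
  w <- ag_tensor(matrix(1:4 / 2, 2, 2))
  out <- ag_no_grad(ag_sum(ag_mm(w, w)))
  expect_null(attr(out, "ag_tape"))
  l <- ag_record(ag_sum(ag_relu(w)))
  ag_backward(l)
  expect_false(is.null(w$grad))
  ag_zero_grad(list(w))
  expect_null(w$grad)
})

test_that("adam reduces a simple quadratic", {
  w <- ag_tensor(matrix(c(5, -3), 1, 2))
  opt <- adam_init(list(w = w), lr = 0.1)
  for (i in 1:200) {
    ag_zero_grad(list(w))
    loss <- ag_record(ag_sum(ag_mul(w, w)))
    ag_backward(loss)
    adam_step(opt)
  }
  expect_lt(sum(w$value^2), 1e-2)
})
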