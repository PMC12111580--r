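# Analytic backward passes are checked against central-difference gradients;
# each case perturbs every input element of a deliberately tiny problem.

grad_check <- function(forward, x0, tol = 1e-6) {
  # forward(ag_node) must return an output node; the loss is a fixed random
  # projection so every output element contributes to the gradient
  set.seed(99)
  probe <- NULL
  out0 <- vl(forward(ag_tensor(x0)))
  probe <- array(stats::rnorm(length(out0)), dim(out0) %||% length(out0))
  f_num <- function(xv) sum(vl(forward(ag_tensor(xv))) * probe)
  g_ana <- with_tape({
    xn <- ag_param(x0)
    out <- forward(xn)
    loss <- ag_op(sum(vl(out) * probe), list(out),
                  function(g) list(probe * as.numeric(g)))
    ag_backward(loss)
    xn$g
  })
  max(abs(g_ana - num_grad(f_num, x0)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("conv2d forward matches hand arithmetic and backward matches finite differences", {
  set.seed(1)
  # known arithmetic: 1x1 input, 1 channel, 3x3 kernel with pad 1 sees only center
  x <- array(2, c(1, 1, 1, 1))
  w <- array(seq(0.1, 0.9, by = 0.1), c(1, 1, 3, 3))
  out <- vl(ag_conv2d(ag_tensor(x), ag_tensor(w), pad = 1L))
  expect_equal(as.vector(out), 2 * w[1, 1, 2, 2])
  x0 <- array(stats::rnorm(2 * 5 * 4 * 2), c(2, 5, 4, 2))
  wk <- array(stats::rnorm(3 * 2 * 3 * 3), c(3, 2, 3, 3))
  bk <- stats::rnorm(3)
  expect_lt(grad_check(function(xn) ag_conv2d(xn, ag_tensor(wk), ag_tensor(bk),
                                              stride = 2L, pad = 1L), x0), 1e-6)
})

test_that("normalization and softmax ops pass finite-difference checks", {
  set.seed(2)
  xm <- matrix(stats::rnorm(4 * 6), 4, 6)
  gam <- stats::rnorm(4) + 1; bet <- stats::rnorm(4)
  expect_lt(grad_check(function(xn) ag_layernorm(xn, ag_tensor(gam), ag_tensor(bet)), xm), 1e-6)
  xs <- array(stats::rnorm(4 * 3 * 2), c(4, 3, 2))
  expect_lt(grad_check(ag_softmax1, xs), 1e-6)
  st <- new.env(); st$rm <- numeric(2); st$rv <- rep(1, 2)
  xb <- array(stats::rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  expect_lt(grad_check(function(xn) {
    s2 <- new.env(); s2$rm <- numeric(2); s2$rv <- rep(1, 2)
    ag_bn2d(xn, ag_tensor(c(1.2, 0.8)), ag_tensor(c(0.1, -0.2)), s2, training = TRUE)
  }, xb), 1e-6)
})

test_that("structural ops (bmm, interpolation, pooling, roll) are exact linear adjoints", {
  set.seed(3)
  B <- array(stats::rnorm(4 * 5 * 2), c(4, 5, 2))
  A0 <- array(stats::rnorm(3 * 4 * 2), c(3, 4, 2))
  expect_lt(grad_check(function(an) ag_bmm(an, ag_tensor(B)), A0), 1e-6)
  xi <- array(stats::rnorm(2 * 4 * 6 * 2), c(2, 4, 6, 2))
  expect_lt(grad_check(function(xn) ag_interp2(xn, 8, 3), xi), 1e-6)
  xp <- array(stats::rnorm(2 * 4 * 4 * 2), c(2, 4, 4, 2))
  expect_lt(grad_check(function(xn) ag_avgpool2(xn, 2L), xp), 1e-6)
  expect_lt(grad_check(function(xn) ag_roll2(xn, 1L, -2L), xp), 1e-6)
})

test_that("cross-entropy gradient matches finite differences and its value matches the closed form", {
  set.seed(4)
  K <- 3; N <- 5
  lg <- matrix(stats::rnorm(K * N), K, N)
  y <- sample(seq_len(K), N, replace = TRUE)
  f <- function(lv) vl(ag_cross_entropy(ag_tensor(lv), y))
  g <- with_tape({
    ln <- ag_param(lg)
    loss <- ag_cross_entropy(ln, y)
    ag_backward(loss)
    ln$g
  })
  expect_lt(max(abs(g - num_grad(f, lg))), 1e-6)
  p <- apply(lg, 2, function(v) exp(v - max(v)) / sum(exp(v - max(v))))
  expect_equal(f(lg), mean(-log(p[cbind(y, seq_len(N))])), tolerance = 1e-12)
})

test_that("bilinear resampling is exact on linear ramps away from clamped edges", {
  # half-pixel-center interpolation reproduces an affine function exactly in
  # the interior (edges are clamped)
  H <- 8; W <- 8
  ramp <- outer(seq_len(H), seq_len(W), function(i, j) 2 * i + 3 * j)
  x <- array(ramp, c(1, H, W, 1))
  up <- vl(ag_interp2(ag_tensor(x), 16, 16))[1, , , 1]
  ctr <- 3:14
  expected <- outer(ctr, ctr, function(i, j) {
    2 * ((i - 0.5) / 2 + 0.5) + 3 * ((j - 0.5) / 2 + 0.5)
  })
  expect_max_diff(up[ctr, ctr], expected, 1e-10)
})
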