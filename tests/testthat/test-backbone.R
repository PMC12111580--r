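test_that("rep blocks fold into a single kernel with identical eval-mode function", {
  set.seed(30)
  for (case in list(c(4, 4, 1), c(4, 6, 1), c(4, 4, 2), c(3, 8, 2))) {
    m <- mod_rep_block(case[1], case[2], case[3])
    for (i in 1:3) {
      invisible(sr_forward(m, ag_tensor(array(stats::rnorm(case[1] * 64), c(case[1], 8, 8, 1)))))
    }
    sr_set_training(m, FALSE)
    x <- array(stats::rnorm(case[1] * 8 * 8 * 2), c(case[1], 8, 8, 2))
    before <- vl(sr_forward(m, ag_tensor(x)))
    reparameterize(m)
    expect_max_diff(vl(sr_forward(m, ag_tensor(x))), before, 1e-4)
  }
})

test_that("reparameterization places kernels correctly and requires eval mode", {
  m <- mod_rep_block(2, 2, 1)
  expect_error(reparameterize(m), "eval mode")
  sr_set_training(m, FALSE)
  # neutral batch norms, zero 3x3 branch, zero identity bn scale: fused kernel
  # is the 1x1 weight at the center tap
  m$children$conv3$params$w$v[] <- 0
  w1 <- array(stats::rnorm(4), c(2, 2, 1, 1))
  m$children$conv1$params$w$v <- w1
  m$children$id_bn$params$gamma$v[] <- 0
  f <- reparameterize(m)
  # unit-variance BN still rescales by 1/sqrt(1 + eps)
  expect_max_diff(f$w[, , 2, 2], w1[, , 1, 1] / sqrt(1 + 1e-5), 1e-12)
  expect_max_diff(f$w[, , -2, ], 0, 1e-12)
  # identity branch alone (unit bn) gives per-channel delta kernels
  m2 <- mod_rep_block(3, 3, 1)
  sr_set_training(m2, FALSE)
  m2$children$conv3$params$w$v[] <- 0
  m2$children$conv1$params$w$v[] <- 0
  m2$children$bn3$params$gamma$v[] <- 0
  m2$children$bn1$params$gamma$v[] <- 0
  f2 <- reparameterize(m2)
  delta <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) delta[i, i, 2, 2] <- 1 / sqrt(1 + 1e-5)
  expect_max_diff(f2$w, delta, 1e-6)
})

test_that("rep blocks map zero inputs to zero and halve spatial size at stride 2", {
  m <- mod_rep_block(4, 6, 2)
  for (p in sr_parameters(m)) p$v[] <- 0
  out <- vl(sr_forward(m, ag_tensor(array(stats::rnorm(4 * 56 * 56), c(4, 56, 56, 1)))))
  expect_equal(dim(out), c(6, 28, 28, 1))
  expect_max_diff(out, 0, 1e-12)
})

test_that("attention complexity closed forms evaluate exactly and scale as stated", {
  expect_identical(msa_complexity(14, 14, 96), 14601216)
  expect_identical(wmsa_complexity(14, 14, 96, 7), 9069312)
  expect_identical(msa_complexity(1, 1, 1), 6)
  for (h in c(2, 5, 8)) for (w in c(3, 7)) for (C in c(16, 96)) {
    expect_identical(msa_complexity(h, w, C), 4 * h * w * C^2 + 2 * (h * w)^2 * C)
    for (M in c(2, 7)) {
      expect_identical(wmsa_complexity(h, w, C, M), 4 * h * w * C^2 + 2 * M^2 * h * w * C)
    }
    # doubling h: quadratic term x4, linear term x2 (global attention)
    q <- 2 * (h * w)^2 * C; lin <- 4 * h * w * C^2
    expect_identical(msa_complexity(2 * h, w, C), 4 * q + 2 * lin)
    # windowed cost is linear in the token count
    expect_identical(wmsa_complexity(2 * h, w, C, 2), 2 * wmsa_complexity(h, w, C, 2))
    # M^2 = hw makes both coincide
    if (sqrt(h * w) %% 1 == 0) {
      expect_identical(wmsa_complexity(h, w, C, sqrt(h * w)), msa_complexity(h, w, C))
    }
  }
})

test_that("shifted-window attention equals the roll-and-partition oracle", {
  set.seed(31)
  m <- mod_swin_block(8, 2, c(8, 8), window = 4L, shifted = TRUE)
  x <- array(stats::rnorm(8 * 8 * 8 * 2), c(8, 8, 8, 2))
  expect_max_diff(vl(swimrep:::swin_attention(m, ag_tensor(x))),
                  swin_attention_oracle(m, x), 1e-10)
  mu <- mod_swin_block(8, 2, c(8, 8), window = 4L, shifted = FALSE)
  expect_max_diff(vl(swimrep:::swin_attention(mu, ag_tensor(x))),
                  swin_attention_oracle(mu, x), 1e-10)
})

test_that("a single-window shifted block reduces to the unshifted computation", {
  set.seed(32)
  ms <- mod_swin_block(8, 2, c(4, 4), window = 4L, shifted = TRUE)
  mu <- mod_swin_block(8, 2, c(4, 4), window = 4L, shifted = FALSE)
  for (nm in names(ms$children)) {
    for (pn in names(ms$children[[nm]]$params)) {
      mu$children[[nm]]$params[[pn]]$v <- ms$children[[nm]]$params[[pn]]$v
    }
  }
  mu$params$relpos$v <- ms$params$relpos$v
  x <- array(stats::rnorm(8 * 4 * 4 * 2), c(8, 4, 4, 2))
  expect_max_diff(vl(sr_forward(ms, ag_tensor(x))), vl(sr_forward(mu, ag_tensor(x))), 1e-12)
})

test_that("window attention weights are normalized per query", {
  set.seed(33)
  m <- mod_swin_block(8, 2, c(8, 8), window = 4L, shifted = TRUE)
  x <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  # recompute the softmax input exactly as the block does, then check columns
  att <- local({
    xn <- sr_forward(m$children$ln1, ag_tensor(x))
    # probe through the public forward: weights sum to 1 is equivalent to the
    # attention output of a constant-V configuration being constant
    mv <- mod_swin_block(8, 2, c(8, 8), window = 4L, shifted = TRUE)
    mv$params$relpos$v <- m$params$relpos$v
    mv$children$qkv$params$w$v <- m$children$qkv$params$w$v
    mv$children$qkv$params$b$v <- m$children$qkv$params$b$v
    # force V rows to a constant and proj to identity read-out of the sums
    mv$children$qkv$params$w$v[2 * 8 + seq_len(8), ] <- 0
    mv$children$qkv$params$b$v[2 * 8 + seq_len(8)] <- 1
    pw <- matrix(0, 8, 8); diag(pw) <- 1
    mv$children$proj$params$w$v <- pw
    mv$children$proj$params$b$v[] <- 0
    vl(swimrep:::swin_attention(mv, ag_tensor(x)))
  })
  # with V == 1 and identity projection, each output equals the weight sum
  expect_max_diff(att, 1, 1e-6)
})

test_that("the assembled network meets its shape, determinism and parameter-ordering contracts", {
  set.seed(34)
  cfg <- swimrep_config(c(32, 64, 128, 256), rep_depths = c(1, 1, 1, 1),
                        swin_depths = c(1, 1, 1, 1), window = 7,
                        heads = c(2, 4, 4, 8), num_classes = 5,
                        fusion = "mpf", attention = "frcpa")
  mdl <- build_swimrep(cfg)
  x <- array(stats::rnorm(3 * 224 * 224 * 2), c(3, 224, 224, 2))
  lg <- vl(sr_forward(mdl, ag_tensor(x)))
  expect_equal(dim(lg), c(5, 2))
  expect_true(all(is.finite(lg)))
  # ablation path is deterministic under a fixed seed
  set.seed(40)
  cfg0 <- swimrep_config(c(8, 16, 32, 64), rep_depths = c(1, 1, 1, 1),
                         swin_depths = c(1, 1, 1, 1), window = 4,
                         heads = c(2, 2, 4, 4), num_classes = 5,
                         input_size = c(32, 32))
  m1 <- build_swimrep(cfg0)
  set.seed(40)
  m2 <- build_swimrep(cfg0)
  xt <- array(stats::rnorm(3 * 32 * 32), c(3, 32, 32, 1))
  expect_identical(vl(sr_forward(m1, ag_tensor(xt))), vl(sr_forward(m2, ag_tensor(xt))))
  # MPF has more branches than AFF, hence more parameters
  set.seed(41)
  cfg_mpf <- swimrep_variant("tiny"); cfg_mpf$attention <- "none"
  cfg_aff <- cfg_mpf; cfg_aff$fusion <- "aff"
  expect_gt(count_params(build_swimrep(cfg_mpf)), count_params(build_swimrep(cfg_aff)))
  # config validation
  expect_error(swimrep_config(c(8, 8, 16, 32), c(1, 1, 1, 1), c(1, 1, 1, 1),
                              heads = c(2, 2, 2, 2), input_size = c(32, 32)),
               "strictly increasing")
  expect_error(swimrep_config(c(8, 16, 32, 64), c(0, 1, 1, 1), c(0, 1, 1, 1),
                              heads = c(2, 2, 2, 2), input_size = c(32, 32)),
               "at least one block")
  expect_error(swimrep_config(c(8, 16, 32, 64), c(1, 1, 1, 1), c(1, 1, 1, 1),
                              heads = c(2, 2, 2, 2), input_size = c(30, 30)),
               "divisible")
  cfgp <- swimrep_variant("tiny"); cfgp$connection <- "parallel"
  expect_error(build_swimrep(cfgp), "not implemented")
})

test_that("stage resolutions follow the /4 /8 /16 /32 schedule", {
  cfg <- swimrep_variant("tiny")
  mdl <- build_swimrep(cfg)
  expect_equal(lapply(mdl$res, function(r) r[1]), list(8L, 4L, 2L, 1L))
  cfg2 <- swimrep_variant("even")
  expect_equal(lapply(build_swimrep(cfg2)$res, function(r) r[1]),
               list(56L, 28L, 14L, 7L))
})

test_that("parameter and FLOP counters reproduce hand-counted layers", {
  m <- mod_conv2d(3, 8, 3)
  expect_equal(count_params(m), 3 * 3 * 3 * 8 + 8)
  expect_equal(sr_count(m, c(3, 4, 4))$macs, 27 * 8 * 4)   # valid conv: 2x2 out
  mp <- mod_conv2d(3, 8, 3, pad = 1)
  expect_equal(sr_count(mp, c(3, 4, 4))$macs, 27 * 8 * 16) # padded: 4x4 out
  ml <- mod_linear(10, 4)
  expect_equal(count_params(ml), 44)
})

test_that("measured window-attention FLOPs grow linearly with token count", {
  costs <- vapply(c(8, 16, 32), function(hw) {
    m <- mod_swin_block(16, 2, c(hw, hw), window = 8L)
    sr_count(m, c(16, hw, hw))$macs
  }, numeric(1))
  expect_equal(costs[2] / costs[1], 4, tolerance = 1e-12)
  expect_equal(costs[3] / costs[2], 4, tolerance = 1e-12)
})

test_that("checkpoints round-trip bitwise through save and load", {
  set.seed(35)
  cfg <- swimrep_variant("tiny")
  m1 <- build_swimrep(cfg)
  x <- array(stats::rnorm(3 * 32 * 32), c(3, 32, 32, 1))
  sr_set_training(m1, FALSE)
  o1 <- vl(sr_forward(m1, ag_tensor(x)))
  path <- tempfile(fileext = ".rds")
  save_model(m1, path, meta = list(variant = "tiny"))
  set.seed(999)
  m2 <- build_swimrep(cfg)
  load_model(m2, path)
  sr_set_training(m2, FALSE)
  expect_identical(vl(sr_forward(m2, ag_tensor(x))), o1)
  expect_error(suppressWarnings(load_model(m2, tempfile())),
               "cannot open|No such file")
})
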