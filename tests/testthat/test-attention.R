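test_that("criss-cross attention matches the per-pixel oracle on random inputs", {
  set.seed(7)
  for (case in list(c(4, 3, 3), c(8, 4, 2), c(2, 2, 4), c(6, 4, 4))) {
    C <- case[1]; H <- case[2]; W <- case[3]
    m <- mod_cca(C, qk_channels = max(1L, C %/% 2L), rounds = 1L)
    x <- array(stats::rnorm(C * H * W * 2), c(C, H, W, 2))
    expect_max_diff(vl(sr_forward(m, ag_tensor(x))), cca_oracle(m, x), 1e-5)
  }
})

test_that("cross attention maps are normalized, uniform on constant input, and degenerate at 1x1", {
  set.seed(8)
  m <- mod_cca(4, 2)
  x <- array(stats::rnorm(4 * 3 * 4 * 2), c(4, 3, 4, 2))
  amap <- cca_attention_map(m, x)
  expect_equal(dim(amap), c(2, 12, 3 + 4 - 1))
  expect_max_diff(apply(amap, c(1, 2), sum), 1, 1e-6)
  expect_true(all(amap >= 0))
  # spatially constant input: all cross energies equal -> uniform weights
  xc <- array(rep(stats::rnorm(4), 3 * 4), c(4, 3, 4, 1))
  expect_max_diff(cca_attention_map(m, xc), 1 / (3 + 4 - 1), 1e-8)
  # single position: weight 1, output = V(x) + x
  m1 <- mod_cca(4, 2)
  x1 <- array(stats::rnorm(4), c(4, 1, 1, 1))
  o1 <- as.vector(vl(sr_forward(m1, ag_tensor(x1))))
  v1 <- as.vector(matrix(m1$children$v$params$w$v, 4, 4) %*% x1[, 1, 1, 1] + x1[, 1, 1, 1])
  expect_max_diff(o1, v1, 1e-12)
})

test_that("recurrent criss-cross equals composed single rounds and preserves shape", {
  set.seed(9)
  m2 <- mod_cca(4, 2, rounds = 2L)
  m1 <- mod_cca(4, 2, rounds = 1L)
  for (nm in names(m2$children)) m1$children[[nm]]$params$w$v <- m2$children[[nm]]$params$w$v
  x <- array(stats::rnorm(4 * 3 * 3), c(4, 3, 3, 1))
  composed <- cca_oracle(m1, cca_oracle(m1, x))
  expect_max_diff(vl(sr_forward(m2, ag_tensor(x))), composed, 1e-5)
  for (r in 1:3) {
    mr <- mod_cca(4, 2, rounds = r)
    expect_equal(dim(vl(sr_forward(mr, ag_tensor(x)))), dim(x))
  }
  expect_error(mod_cca(4, 2, rounds = 0), "rounds")
  expect_error(mod_cca(2, qk_channels = 5), "exceeds")
})

test_that("frca rescales through a half-resolution attention plane and adds the input back", {
  set.seed(10)
  m <- mod_frca(4, 2, rounds = 2L)
  # zero V projection: attention adds nothing, recurrent_cca(H') = H'
  m$children$cca$children$v$params$w$v[] <- 0
  x <- array(stats::rnorm(4 * 6 * 6 * 2), c(4, 6, 6, 2))
  expected <- vl(ag_interp2(ag_interp2(ag_tensor(x), 3, 3), 6, 6)) + x
  expect_max_diff(vl(sr_forward(m, ag_tensor(x))), expected, 1e-10)
  m8 <- mod_frca(8)
  x8 <- array(stats::rnorm(8 * 8 * 8), c(8, 8, 8, 1))
  expect_equal(dim(vl(sr_forward(m8, ag_tensor(x8)))), c(8, 8, 8, 1))
  expect_error(sr_forward(m8, ag_tensor(array(0, c(8, 1, 1, 1)))), "degenerate")
})

test_that("the half-resolution path cuts the attention operation count", {
  for (hw in c(8, 12, 16)) {
    full <- sr_count(mod_cca(8, 1, rounds = 2L), c(8, hw, hw))$macs
    sparse <- sr_count(mod_frca(8, 1, rounds = 2L), c(8, hw, hw))$macs
    expect_lt(sparse, full)
    # quadratic energy term shrinks 4x; allow the linear terms + resampling
    expect_lt(sparse, 0.25 * full + 3 * (2 * 8 * 1 + 8 * 8) * hw * hw)
  }
})

test_that("polarized self-attention gates lie in [0,1], preserve shape, and saturate to identity", {
  set.seed(11)
  m <- mod_psa(16)
  x <- array(stats::rnorm(16 * 7 * 7 * 2), c(16, 7, 7, 2))
  out <- vl(sr_forward(m, ag_tensor(x)))
  expect_equal(dim(out), c(16, 7, 7, 2))
  expect_true(all(m$last_gates$channel >= 0 & m$last_gates$channel <= 1))
  expect_true(all(m$last_gates$spatial >= 0 & m$last_gates$spatial <= 1))
  psa_force_identity(m)
  expect_max_diff(vl(sr_forward(m, ag_tensor(x))), x, 1e-4)
  # odd channel counts reduce to floor(C/2) internally
  m5 <- mod_psa(5)
  expect_equal(m5$cm, 2L)
  x5 <- array(stats::rnorm(5 * 4 * 4), c(5, 4, 4, 1))
  expect_equal(dim(vl(sr_forward(m5, ag_tensor(x5)))), dim(x5))
  expect_error(mod_psa(1), "2 channels")
})

test_that("frcpa concatenates both branches to 2C and projects back to C", {
  set.seed(12)
  m <- mod_frcpa(32)
  x <- array(stats::rnorm(32 * 14 * 14), c(32, 14, 14, 1))
  out <- vl(sr_forward(m, ag_tensor(x)))
  expect_equal(dim(out), dim(x))
  expect_equal(m$last_concat_channels, 64L)
  m$children$proj$params$w$v[] <- 0
  m$children$proj$params$b$v[] <- 0
  expect_max_diff(vl(sr_forward(m, ag_tensor(x))), 0, 1e-12)
  expect_error(sr_forward(mod_frcpa(4), ag_tensor(array(0, c(4, 1, 1, 1)))), "degenerate")
})

test_that("attention blocks preserve shape across spatial sizes", {
  set.seed(13)
  for (hw in c(2, 5, 9, 16)) {
    x <- array(stats::rnorm(4 * hw * hw), c(4, hw, hw, 1))
    expect_equal(dim(vl(sr_forward(mod_frca(4, 1), ag_tensor(x)))), dim(x))
    expect_equal(dim(vl(sr_forward(mod_psa(4), ag_tensor(x)))), dim(x))
    expect_equal(dim(vl(sr_forward(mod_frcpa(4, 1), ag_tensor(x)))), dim(x))
  }
})
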