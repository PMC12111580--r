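# Criss-cross attention and its fused variants.
#
# Criss-cross attention restricts self-attention, per query pixel u = (i, j),
# to the H + W - 1 pixels sharing u's row or column. The pixel itself is
# counted once: it participates through the column branch and is masked out of
# the row branch before the joint softmax. Two weight-shared rounds (RCCA)
# propagate information across the full plane. FRCA runs RCCA at half spatial
# resolution and adds the bilinearly rescaled result back to the input; FRCPA
# concatenates FRCA with polarized self-attention and compresses back to the
# input width with a 1x1 convolution.

#' Criss-cross attention module
#'
#' @param c input/output channel count.
#' @param qk_channels reduced channel count for the query/key projections
#'   (default `max(1, c %/% 8)`, the criss-cross convention).
#' @param rounds number of weight-shared recurrent applications (>= 1).
#' @return a module whose forward pass preserves the `(C, H, W, B)` shape and,
#'   per position, adds the attention-aggregated cross features to the input.
#' @export
mod_cca <- function(c, qk_channels = max(1L, c %/% 8L), rounds = 1L) {
  if (rounds < 1) stop("rounds must be >= 1")
  if (qk_channels > c) stop("q_channels (", qk_channels, ") exceeds input channels (", c, ")")
  m <- new_module("cca")
  m$c <- c; m$qc <- qk_channels; m$rounds <- as.integer(rounds)
  m$children$q <- mod_conv2d(c, qk_channels, 1L, bias = FALSE)
  m$children$k <- mod_conv2d(c, qk_channels, 1L, bias = FALSE)
  m$children$v <- mod_conv2d(c, c, 1L, bias = FALSE)
  m
}

# joint row+column energies, masked so the query pixel enters once;
# returns the softmax-normalized (H+W, H, W, B) attention node
cca_joint_attention <- function(m, x) {
  d <- dim(vl(x))
  H <- d[2]; W <- d[3]; B <- d[4]
  q <- sr_forward(m$children$q, x)
  k <- sr_forward(m$children$k, x)
  qc <- m$qc
  # column energies: batch over (w, b)
  q3 <- ag_reshape(q, c(qc, H, W * B))
  k3 <- ag_reshape(k, c(qc, H, W * B))
  ec <- ag_bmm(ag_aperm(k3, c(2, 1, 3)), q3)          # (Hk, Hq, W*B)
  ec <- ag_reshape(ec, c(H, H, W, B))
  # row energies: batch over (i, b)
  qr <- ag_reshape(ag_aperm(q, c(1, 3, 2, 4)), c(qc, W, H * B))
  kr <- ag_reshape(ag_aperm(k, c(1, 3, 2, 4)), c(qc, W, H * B))
  er <- ag_bmm(ag_aperm(kr, c(2, 1, 3)), qr)          # (Wk, Wq, H*B)
  er <- ag_aperm(ag_reshape(er, c(W, W, H, B)), c(1, 3, 2, 4)) # (Wk, H, W, B)
  e <- ag_concat1(ec, er)                             # (H+W, H, W, B)
  mask <- array(0, c(H + W, H, W, B))
  for (j in seq_len(W)) mask[H + j, , j, ] <- -1e9    # row branch self key
  ag_softmax1(ag_addc(e, mask))
}

cca_single_round <- function(m, x) {
  d <- dim(vl(x))
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  a <- cca_joint_attention(m, x)
  v <- sr_forward(m$children$v, x)
  ac <- ag_reshape(ag_take1(a, seq_len(H)), c(H, H, W * B))
  v3 <- ag_reshape(v, c(C, H, W * B))
  outc <- ag_reshape(ag_bmm(v3, ac), c(C, H, W, B))
  ar <- ag_take1(a, H + seq_len(W))                   # (Wk, H, W, B)
  ar <- ag_reshape(ag_aperm(ar, c(1, 3, 2, 4)), c(W, W, H * B))
  vr <- ag_reshape(ag_aperm(v, c(1, 3, 2, 4)), c(C, W, H * B))
  outr <- ag_aperm(ag_reshape(ag_bmm(vr, ar), c(C, W, H, B)), c(1, 3, 2, 4))
  ag_add(ag_add(outc, outr), x)
}

#' @export
sr_forward.sr_cca <- function(m, x, ...) {
  x <- as_ag(x)
  for (r in seq_len(m$rounds)) x <- cca_single_round(m, x)
  x
}

#' Criss-cross attention weights per position
#'
#' Returns the normalized attention of every spatial position over the
#' H + W - 1 pixels of its row/column cross (the H column keys first, then the
#' W - 1 row keys excluding the query pixel itself, which is already counted
#' by the column branch).
#' @param m a [mod_cca()] module.
#' @param x `(C, H, W, B)` array or node.
#' @return array of shape `(B, H*W, H+W-1)`; each slice sums to 1.
#' @export
cca_attention_map <- function(m, x) {
  x <- as_ag(x)
  d <- dim(vl(x))
  H <- d[2]; W <- d[3]; B <- d[4]
  a <- vl(cca_joint_attention(m, x))                  # (H+W, H, W, B)
  out <- array(0, c(B, H * W, H + W - 1L))
  for (b in seq_len(B)) {
    for (j in seq_len(W)) {
      for (i in seq_len(H)) {
        u <- (j - 1L) * H + i
        keep <- c(seq_len(H), H + setdiff(seq_len(W), j))
        out[b, u, ] <- a[keep, i, j, b]
      }
    }
  }
  out
}

#' @export
sr_count.sr_cca <- function(m, in_shape) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  per_round <- (2 * C * m$qc + C * C) * H * W +       # q/k/v projections
    H * W * (H + W) * m$qc +                          # energies
    H * W * (H + W) * C                               # aggregation
  list(macs = m$rounds * per_round, out = in_shape)
}

# ---- FRCA -----------------------------------------------------------------

#' Sparse (half-resolution) recurrent criss-cross attention
#'
#' Rescales the input to half resolution, applies weight-shared recurrent
#' criss-cross attention there, rescales the result back to the input size and
#' adds it to the input. The half-resolution plane is what makes the attention
#' sparse: the quadratic cross-energy term shrinks by a factor of four.
#' @param c channel count.
#' @param qk_channels reduced query/key channels.
#' @param rounds recurrent rounds (default 2).
#' @return a module; its forward errors on inputs smaller than 2x2.
#' @export
mod_frca <- function(c, qk_channels = max(1L, c %/% 8L), rounds = 2L) {
  m <- new_module("frca")
  m$c <- c
  m$children$cca <- mod_cca(c, qk_channels, rounds)
  m
}

#' @export
sr_forward.sr_frca <- function(m, x, ...) {
  x <- as_ag(x)
  d <- dim(vl(x))
  if (d[2] < 2 || d[3] < 2) {
    stop("frca requires H >= 2 and W >= 2 (got ", d[2], "x", d[3],
         "): the half-resolution plane would be degenerate")
  }
  h2 <- max(1L, d[2] %/% 2L); w2 <- max(1L, d[3] %/% 2L)
  hs <- ag_interp2(x, h2, w2)
  att <- sr_forward(m$children$cca, hs)
  mm <- ag_interp2(att, d[2], d[3])
  ag_add(mm, x)
}

#' @export
sr_count.sr_frca <- function(m, in_shape) {
  C <- in_shape[1]; H <- in_shape[2]; W <- in_shape[3]
  h2 <- max(1L, H %/% 2L); w2 <- max(1L, W %/% 2L)
  inner <- sr_count(m$children$cca, c(C, h2, w2))$macs
  resample <- 4 * C * h2 * w2 + 4 * C * H * W
  list(macs = inner + resample, out = in_shape)
}

# ---- polarized self-attention ---------------------------------------------

#' Polarized self-attention module (sequential channel -> spatial)
#'
#' Channel branch: a spatial-softmax-pooled C/2 bottleneck descriptor is
#' re-expanded to C and squashed by a sigmoid into a per-channel gate.
#' Spatial branch (applied to the channel-gated map): a channel-softmax-pooled
#' descriptor scores each pixel; the sigmoid of the score gates the map
#' spatially. Both gates lie in [0, 1]; the last computed gates are kept in
#' `$last_gates` for inspection.
#' @param c channel count (>= 2; odd values use `floor(c/2)`, minimum 1, for
#'   the bottleneck).
#' @return a module preserving the input shape.
#' @export
mod_psa <- function(c) {
  if (c < 2) stop("psa requires at least 2 channels")
  m <- new_module("psa")
  cm <- max(1L, c %/% 2L)
  m$c <- c; m$cm <- cm
  m$children$wq_ch <- mod_conv2d(c, 1L, 1L, bias = FALSE)
  m$children$wv_ch <- mod_conv2d(c, cm, 1L, bias = FALSE)
  m$children$wz_ch <- mod_linear(cm, c)
  m$children$wq_sp <- mod_conv2d(c, cm, 1L, bias = FALSE)
  m$children$wv_sp <- mod_conv2d(c, cm, 1L, bias = FALSE)
  reg_param(m, "b_sp", 0)
  m
}

#' @export
sr_forward.sr_psa <- function(m, x, ...) {
  x <- as_ag(x)
  d <- dim(vl(x))
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  hw <- H * W
  # channel gate
  qc <- ag_softmax1(ag_reshape(sr_forward(m$children$wq_ch, x), c(hw, B)))
  vc <- ag_reshape(sr_forward(m$children$wv_ch, x), c(m$cm, hw, B))
  z <- ag_bmm(vc, ag_reshape(qc, c(hw, 1L, B)))       # (cm, 1, B)
  gate_ch <- ag_sigmoid(sr_forward(m$children$wz_ch, ag_reshape(z, c(m$cm, B))))
  xc <- ag_mul(x, ag_expand_hw(gate_ch, H, W))
  # spatial gate
  qs <- ag_softmax1(ag_mean_hw(sr_forward(m$children$wq_sp, xc)))  # (cm, B)
  vs <- ag_reshape(sr_forward(m$children$wv_sp, xc), c(m$cm, hw, B))
  sc <- ag_bmm(ag_reshape(qs, c(m$cm, 1L, B)) |> ag_aperm(c(2, 1, 3)), vs) # (1, hw, B)
  sc <- ag_bias1(ag_reshape(sc, c(1L, H, W, B)), m$params$b_sp)
  gate_sp <- ag_sigmoid(sc)
  m$last_gates <- list(channel = vl(gate_ch), spatial = vl(gate_sp))
  ag_mul(xc, ag_expand_c(gate_sp, C))
}

#' Force a polarized self-attention module to the identity
#'
#' Saturates both sigmoid gates at 1 (large bias on the channel expansion,
#' zeroed spatial scoring weights with a large score bias) so that
#' `psa(x) == x` up to sigmoid saturation error; used to validate the gating
#' path.
#' @param m a [mod_psa()] module.
#' @export
psa_force_identity <- function(m) {
  m$children$wz_ch$params$w$v[] <- 0
  m$children$wz_ch$params$b$v[] <- 20
  m$children$wv_sp$params$w$v[] <- 0
  m$params$b_sp$v[] <- 20
  invisible(m)
}

#' @export
sr_count.sr_psa <- function(m, in_shape) {
  C <- in_shape[1]; hw <- in_shape[2] * in_shape[3]
  macs <- (C * 1 + C * m$cm) * hw + m$cm * hw +       # channel branch
    m$cm * C +                                        # expansion
    (2 * C * m$cm) * hw + m$cm * hw                   # spatial branch
  list(macs = macs, out = in_shape)
}

# ---- FRCPA ----------------------------------------------------------------

#' Fused criss-cross / polarized attention block
#'
#' Concatenates the polarized self-attention and sparse recurrent criss-cross
#' attention outputs along channels (2C) and compresses back to C with a 1x1
#' convolution; no residual term is added around the projection.
#' @param c channel count (>= 2).
#' @param qk_channels reduced query/key channels for the criss-cross branch.
#' @param rounds recurrent rounds of the criss-cross branch.
#' @return a module preserving the input shape; errors on inputs smaller than
#'   2x2 (propagated from the half-resolution branch).
#' @export
mod_frcpa <- function(c, qk_channels = max(1L, c %/% 8L), rounds = 2L) {
  m <- new_module("frcpa")
  m$c <- c
  m$children$psa <- mod_psa(c)
  m$children$frca <- mod_frca(c, qk_channels, rounds)
  m$children$proj <- mod_conv2d(2L * c, c, 1L, bias = TRUE)
  m
}

#' @export
sr_forward.sr_frcpa <- function(m, x, ...) {
  x <- as_ag(x)
  p <- sr_forward(m$children$psa, x)
  f <- sr_forward(m$children$frca, x)
  cat2 <- ag_concat1(p, f)
  m$last_concat_channels <- dim(vl(cat2))[1]
  sr_forward(m$children$proj, cat2)
}

#' @export
sr_count.sr_frcpa <- function(m, in_shape) {
  hw <- in_shape[2] * in_shape[3]
  macs <- sr_count(m$children$psa, in_shape)$macs +
    sr_count(m$children$frca, in_shape)$macs +
    2 * m$c * m$c * hw
  list(macs = macs, out = in_shape)
}
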