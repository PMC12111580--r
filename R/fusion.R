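# Feature-fusion blocks: strip pooling, the two-branch AFF-style gate, and the
# five-branch multi-scale strip-pooling fusion (MPF).
#
# Both fusion modules mix two same-shaped feature maps x (deeper/transformed
# features) and y (skip features) as M*x + (1-M)*y, where the gate M in [0,1]
# is the sigmoid of summed branch outputs computed on x + y. AFF uses a global
# (average-pooled) and a local (point-wise) channel-context branch; MPF adds
# horizontal-strip, vertical-strip and 3x3 local-convolution branches, five in
# total, so the gate sees long-range context along both axes.

# mean over one spatial axis, keeping a singleton dim
ag_mean_axis <- function(x, axis) {
  x <- as_ag(x)
  d <- dim(x$v)
  stopifnot(axis %in% c(2L, 3L))
  n <- d[axis]
  if (axis == 2L) {
    v <- aperm(x$v, c(2, 1, 3, 4))                 # (H, C, W, B)
    out <- colMeans(matrix(v, nrow = d[2]))
    dim(out) <- c(d[1], 1L, d[3], d[4])
  } else {
    v <- aperm(x$v, c(3, 1, 2, 4))                 # (W, C, H, B)
    out <- colMeans(matrix(v, nrow = d[3]))
    dim(out) <- c(d[1], d[2], 1L, d[4])
  }
  ag_op(out, list(x), function(g) {
    if (axis == 2L) {
      gm <- array(rep(as.vector(g) / n, each = n), c(n, d[1], d[3], d[4]))
      list(aperm(gm, c(2, 1, 3, 4)))
    } else {
      gm <- array(rep(as.vector(g) / n, each = n), c(n, d[1], d[2], d[4]))
      list(aperm(gm, c(2, 3, 1, 4)))
    }
  })
}

# broadcast a (C, H, 1, B) or (C, 1, W, B) map back to (C, H, W, B)
ag_expand_axis <- function(x, axis, n) {
  x <- as_ag(x)
  d <- dim1(x$v)
  if (axis == 2L) {                                # expand height? no: axis kept
    # x is (C, 1, W, B): repeat along H
    out <- array(0, c(d[1], n, d[3], d[4]))
    perm <- aperm(x$v, c(2, 1, 3, 4))              # (1, C, W, B)
    out <- aperm(array(rep(as.vector(perm), each = n), c(n, d[1], d[3], d[4])),
                 c(2, 1, 3, 4))
    ag_op(out, list(x), function(g) {
      gs <- colSums(matrix(aperm(g, c(2, 1, 3, 4)), nrow = n))
      dim(gs) <- d
      list(gs)
    })
  } else {
    # x is (C, H, 1, B): repeat along W
    perm <- aperm(x$v, c(3, 1, 2, 4))              # (1, C, H, B)
    out <- aperm(array(rep(as.vector(perm), each = n), c(n, d[1], d[2], d[4])),
                 c(2, 3, 1, 4))
    ag_op(out, list(x), function(g) {
      gs <- colSums(matrix(aperm(g, c(3, 1, 2, 4)), nrow = n))
      dim(gs) <- d
      list(gs)
    })
  }
}

#' Per-axis strip means of a feature map
#'
#' The raw pooling stage of strip pooling: the average over the width
#' (`axis = "horizontal"`, giving a `(C, H, 1, B)` profile) or over the height
#' (`axis = "vertical"`, giving `(C, 1, W, B)`).
#' @param x `(C, H, W, B)` array or node.
#' @param axis `"horizontal"` or `"vertical"`.
#' @return an `ag` node holding the strip means (singleton pooled axis kept).
#' @export
strip_pool_means <- function(x, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  ag_mean_axis(as_ag(x), if (axis == "horizontal") 3L else 2L)
}

#' Strip-pooling module
#'
#' Averages the map along one axis with a long 1xN (or Nx1) kernel, mixes the
#' retained axis with a length-3 one-dimensional convolution, and broadcasts
#' the profile back over the pooled axis.
#' @param c channel count.
#' @param axis `"horizontal"` (pool width, keep height) or `"vertical"`.
#' @return a module preserving the `(C, H, W, B)` shape.
#' @export
mod_strip_pool <- function(c, axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  m <- new_module("strip_pool")
  m$axis <- axis
  m$c <- c
  k <- if (axis == "horizontal") c(3L, 1L) else c(1L, 3L)
  p <- if (axis == "horizontal") c(1L, 0L) else c(0L, 1L)
  m$children$conv <- mod_conv2d(c, c, k, pad = p)
  m
}

#' @export
sr_forward.sr_strip_pool <- function(m, x, ...) {
  x <- as_ag(x)
  d <- dim(vl(x))
  pooled <- strip_pool_means(x, m$axis)
  mixed <- sr_forward(m$children$conv, pooled)
  if (m$axis == "horizontal") ag_expand_axis(mixed, 3L, d[3])
  else ag_expand_axis(mixed, 2L, d[2])
}

#' @export
sr_count.sr_strip_pool <- function(m, in_shape) {
  n <- if (m$axis == "horizontal") in_shape[2] else in_shape[3]
  list(macs = 3 * m$c * m$c * n, out = in_shape)
}

# ---- channel-context branches ---------------------------------------------

# global channel context: GAP -> C/r -> ReLU -> C, broadcast over space
mod_global_ctx <- function(c, r = 4L) {
  m <- new_module("global_ctx")
  m$c <- c
  cr <- max(1L, c %/% r)
  m$cr <- cr
  m$children$fc1 <- mod_linear(c, cr)
  m$children$fc2 <- mod_linear(cr, c)
  m
}

#' @export
sr_forward.sr_global_ctx <- function(m, x, ...) {
  x <- as_ag(x)
  d <- dim(vl(x))
  z <- ag_mean_hw(x)                               # (C, B)
  z <- sr_forward(m$children$fc2, ag_relu(sr_forward(m$children$fc1, z)))
  ag_expand_hw(z, d[2], d[3])
}

#' @export
sr_count.sr_global_ctx <- function(m, in_shape) {
  list(macs = 2 * m$c * m$cr, out = in_shape)
}

# local (point-wise) channel context: 1x1 C->C/r -> ReLU -> 1x1 C/r->C
mod_local_ctx <- function(c, r = 4L) {
  m <- new_module("local_ctx")
  m$c <- c
  cr <- max(1L, c %/% r)
  m$children$c1 <- mod_conv2d(c, cr, 1L)
  m$children$c2 <- mod_conv2d(cr, c, 1L)
  m
}

#' @export
sr_forward.sr_local_ctx <- function(m, x, ...) {
  sr_forward(m$children$c2, ag_relu(sr_forward(m$children$c1, x)))
}

#' @export
sr_count.sr_local_ctx <- function(m, in_shape) {
  s1 <- sr_count(m$children$c1, in_shape)
  s2 <- sr_count(m$children$c2, s1$out)
  list(macs = s1$macs + s2$macs, out = in_shape)
}

# ---- gated fusion ---------------------------------------------------------

fusion_forward <- function(m, x, y) {
  x <- as_ag(x); y <- as_ag(y)
  if (!identical(dim(vl(x)), dim(vl(y)))) {
    stop("fusion inputs must share one shape; got ",
         paste(dim(vl(x)), collapse = "x"), " vs ",
         paste(dim(vl(y)), collapse = "x"))
  }
  s <- ag_add(x, y)
  acc <- NULL
  for (br in m$children$branches$children) {
    b <- sr_forward(br, s)
    acc <- if (is.null(acc)) b else ag_add(acc, b)
  }
  gate <- ag_sigmoid(acc)
  m$last_gate <- vl(gate)
  one_minus <- ag_addc(ag_smul(gate, -1), 1)
  ag_add(ag_mul(gate, x), ag_mul(one_minus, y))
}

#' Two-branch attentional feature fusion (AFF baseline)
#'
#' Gate computed from global + local channel context of `x + y`;
#' output is `M*x + (1-M)*y`.
#' @param c channel count.
#' @param r bottleneck reduction ratio of the context branches.
#' @return a fusion module; call as `sr_forward(m, x, y)`.
#' @export
mod_aff <- function(c, r = 4L) {
  m <- new_module("aff")
  m$c <- c
  br <- new_module("branchset")
  br$children$global <- mod_global_ctx(c, r)
  br$children$local <- mod_local_ctx(c, r)
  m$children$branches <- br
  m
}

#' @export
sr_forward.sr_aff <- function(m, x, y, ...) fusion_forward(m, x, y)

#' Five-branch multi-scale strip-pooling fusion (MPF)
#'
#' The gate sums five parallel branches of `x + y`: global channel context,
#' horizontal strip pooling, vertical strip pooling, point-wise local channel
#' context, and a 3x3 local convolution; the sigmoid of the sum mixes the two
#' inputs as `M*x + (1-M)*y`.
#' @param c channel count.
#' @param r bottleneck reduction ratio of the channel-context branches.
#' @return a fusion module; call as `sr_forward(m, x, y)`.
#' @export
mod_mpf <- function(c, r = 4L) {
  m <- new_module("mpf")
  m$c <- c
  br <- new_module("branchset")
  br$children$global <- mod_global_ctx(c, r)
  br$children$strip_h <- mod_strip_pool(c, "horizontal")
  br$children$strip_v <- mod_strip_pool(c, "vertical")
  br$children$local <- mod_local_ctx(c, r)
  br$children$conv3 <- mod_conv2d(c, c, 3L, pad = 1L)
  m$children$branches <- br
  m
}

#' @export
sr_forward.sr_mpf <- function(m, x, y, ...) fusion_forward(m, x, y)

#' Number of parallel gate branches of a fusion module
#' @param m a [mod_aff()] or [mod_mpf()] module.
#' @return integer branch count (2 for AFF, 5 for MPF).
#' @export
fusion_branch_count <- function(m) length(m$children$branches$children)

#' Zero-initialize every gate branch of a fusion module
#'
#' With all branch convolutions and linear maps zeroed the pre-sigmoid sum is
#' 0, the gate is exactly 0.5 everywhere and fusion returns `(x + y) / 2`.
#' @param m a fusion module.
#' @export
fusion_zero_init <- function(m) {
  for (p in sr_parameters(m$children$branches)) p$v[] <- 0
  invisible(m)
}

fusion_count <- function(m, in_shape) {
  macs <- sum(vapply(m$children$branches$children,
                     function(br) sr_count(br, in_shape)$macs, numeric(1)))
  list(macs = macs, out = in_shape)
}

#' @export
sr_count.sr_aff <- function(m, in_shape) fusion_count(m, in_shape)

#' @export
sr_count.sr_mpf <- function(m, in_shape) fusion_count(m, in_shape)

# ---- cross-layer alignment -------------------------------------------------

#' Cross-stage feature alignment
#'
#' Brings a feature map to a target `(C, H, W)` shape before fusion:
#' downsampling averages over the integer stride (falling back to bilinear
#' resampling for non-integer ratios) followed by a 1x1 channel projection;
#' upsampling projects channels first, then resamples bilinearly.
#' @param cin,cout input and target channel counts.
#' @return a module; call as `sr_forward(m, x, target_h, target_w)`.
#' @export
mod_align <- function(cin, cout) {
  m <- new_module("align")
  m$cin <- cin; m$cout <- cout
  m$children$proj <- mod_conv2d(cin, cout, 1L)
  m
}

#' @export
sr_forward.sr_align <- function(m, x, target_h, target_w, ...) {
  x <- as_ag(x)
  d <- dim(vl(x))
  H <- d[2]; W <- d[3]
  if (target_h <= H) {
    if (H %% target_h == 0 && W %% target_w == 0 && H %/% target_h == W %/% target_w) {
      k <- H %/% target_h
      if (k > 1) x <- ag_avgpool2(x, k)
    } else if (target_h != H || target_w != W) {
      x <- ag_interp2(x, target_h, target_w)
    }
    sr_forward(m$children$proj, x)
  } else {
    ag_interp2(sr_forward(m$children$proj, x), target_h, target_w)
  }
}

#' Identity-initialize the 1x1 projection of an alignment module
#'
#' Requires matching channel counts; afterwards aligning to the input's own
#' shape is the identity map.
#' @param m a [mod_align()] module with `cin == cout`.
#' @export
align_identity_init <- function(m) {
  stopifnot(m$cin == m$cout)
  w <- array(0, c(m$cout, m$cin, 1L, 1L))
  for (i in seq_len(m$cin)) w[i, i, 1, 1] <- 1
  m$children$proj$params$w$v <- w
  m$children$proj$params$b$v[] <- 0
  invisible(m)
}

#' @export
sr_count.sr_align <- function(m, in_shape) {
  # counted at the (coarser) projection resolution; callers pass target shape
  list(macs = m$cin * m$cout * in_shape[2] * in_shape[3],
       out = c(m$cout, in_shape[2], in_shape[3]))
}
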