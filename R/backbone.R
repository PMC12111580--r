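# Backbone blocks and assembly.
#
# Rep blocks are RepVGG-style convolution blocks: at training time a parallel
# sum of 3x3 conv + BN, 1x1 conv + BN and (when shapes permit) an identity BN
# branch, each foldable after training into a single equivalent 3x3
# convolution ("structural reparameterization"). Swin blocks are shifted-window
# multi-head self-attention blocks over token grids with relative position
# bias. The four-stage hybrid network stacks Rep blocks then Swin blocks per
# stage, optionally fusing consecutive stages with AFF/MPF and refining with
# FRCPA.

# ---- Rep block -------------------------------------------------------------

#' Structurally reparameterizable convolution block
#'
#' Training structure: `ReLU(BN(conv3x3(x)) + BN(conv1x1(x)) + BN(x))`, with
#' the identity branch present iff `cin == cout` and `stride == 1`. After
#' [reparameterize()] the block runs a single fused 3x3 convolution.
#' @param cin,cout channel counts.
#' @param stride 1 or 2.
#' @return a module.
#' @export
mod_rep_block <- function(cin, cout, stride = 1L) {
  m <- new_module("rep_block")
  m$cin <- cin; m$cout <- cout; m$stride <- as.integer(stride)
  m$deploy <- FALSE
  m$children$conv3 <- mod_conv2d(cin, cout, 3L, stride = stride, pad = 1L, bias = FALSE)
  m$children$bn3 <- mod_bn2d(cout)
  m$children$conv1 <- mod_conv2d(cin, cout, 1L, stride = stride, pad = 0L, bias = FALSE)
  m$children$bn1 <- mod_bn2d(cout)
  if (cin == cout && stride == 1L) {
    m$children$id_bn <- mod_bn2d(cout)
  }
  m
}

#' @export
sr_forward.sr_rep_block <- function(m, x, ...) {
  if (isTRUE(m$deploy)) {
    return(ag_relu(sr_forward(m$children$fused, x)))
  }
  y <- ag_add(sr_forward(m$children$bn3, sr_forward(m$children$conv3, x)),
              sr_forward(m$children$bn1, sr_forward(m$children$conv1, x)))
  if (!is.null(m$children$id_bn)) {
    y <- ag_add(y, sr_forward(m$children$id_bn, x))
  }
  ag_relu(y)
}

fold_bn <- function(w, bn, eps = 1e-5) {
  # w: (Cout, Cin, 3, 3); returns list(w, b) with the BN affine folded in
  sc <- as.vector(bn$params$gamma$v) / sqrt(bn$state$rv + eps)
  list(w = w * sc, b = as.vector(bn$params$beta$v) - bn$state$rm * sc)
}

#' Fold the parallel branches of a Rep block into one 3x3 kernel
#'
#' The 1x1 kernel is zero-padded to 3x3 (center tap), the identity branch is
#' expressed as a per-channel delta kernel, each branch's batch norm is folded
#' into its kernel, and the three are summed. Requires finalized batch-norm
#' statistics (the block must be in evaluation mode).
#' @param m a [mod_rep_block()] module in eval mode.
#' @return list with the fused `w` (`(cout, cin, 3, 3)`) and bias `b`; the
#'   block is switched to deploy mode as a side effect.
#' @export
reparameterize <- function(m) {
  stopifnot(inherits(m, "sr_rep_block"))
  if (isTRUE(m$training)) {
    stop("reparameterize() requires finalized batch-norm statistics: ",
         "put the block in eval mode first (sr_set_training(m, FALSE))")
  }
  f3 <- fold_bn(m$children$conv3$params$w$v, m$children$bn3)
  w1 <- array(0, c(m$cout, m$cin, 3L, 3L))
  w1[, , 2L, 2L] <- m$children$conv1$params$w$v[, , 1L, 1L]
  f1 <- fold_bn(w1, m$children$bn1)
  w <- f3$w + f1$w
  b <- f3$b + f1$b
  if (!is.null(m$children$id_bn)) {
    wid <- array(0, c(m$cout, m$cin, 3L, 3L))
    for (i in seq_len(m$cout)) wid[i, i, 2L, 2L] <- 1
    fid <- fold_bn(wid, m$children$id_bn)
    w <- w + fid$w
    b <- b + fid$b
  }
  fused <- mod_conv2d(m$cin, m$cout, 3L, stride = m$stride, pad = 1L, bias = TRUE)
  fused$params$w$v <- w
  fused$params$b$v <- b
  # drop the branch parameters so deploy-mode accounting sees the fused form
  m$children <- list(fused = fused)
  m$params <- list()
  m$deploy <- TRUE
  sr_set_training(m, FALSE)
  list(w = w, b = b)
}

#' Reparameterize every Rep block in a model
#' @param model a module tree (switched to eval mode first).
#' @return `model`, with all Rep blocks fused, invisibly.
#' @export
reparameterize_model <- function(model) {
  sr_set_training(model, FALSE)
  walk <- function(m) {
    if (inherits(m, "sr_rep_block") && !isTRUE(m$deploy)) reparameterize(m)
    else for (ch in m$children) walk(ch)
  }
  walk(model)
  invisible(model)
}

#' @export
sr_count.sr_rep_block <- function(m, in_shape) {
  ho <- (in_shape[2] + 2 - 3) %/% m$stride + 1
  wo <- (in_shape[3] + 2 - 3) %/% m$stride + 1
  macs <- if (isTRUE(m$deploy)) {
    9 * m$cin * m$cout * ho * wo
  } else {
    (9 + 1) * m$cin * m$cout * ho * wo
  }
  list(macs = macs, out = c(m$cout, ho, wo))
}

# ---- attention complexity closed forms -------------------------------------

#' Computational complexity of global multi-head self-attention
#'
#' The standard closed form `4*h*w*C^2 + 2*(h*w)^2*C` for an `h x w` grid of
#' C-dimensional tokens: the quadratic term is the all-pairs attention.
#' @param h,w token-grid height and width.
#' @param c token dimension.
#' @return operation count (numeric, exact integer value).
#' @export
msa_complexity <- function(h, w, c) {
  4 * h * w * c^2 + 2 * (h * w)^2 * c
}

#' Computational complexity of window-restricted multi-head self-attention
#'
#' `4*h*w*C^2 + 2*M^2*h*w*C`: restricting attention to MxM windows makes the
#' attention term linear in the token count.
#' @param h,w token-grid height and width.
#' @param c token dimension.
#' @param m window side M.
#' @return operation count (numeric, exact integer value).
#' @export
wmsa_complexity <- function(h, w, c, m) {
  4 * h * w * c^2 + 2 * m^2 * h * w * c
}

# ---- Swin block ------------------------------------------------------------

# relative-position index for an MxM window, (key fast, query slow), 1-based
relpos_index <- function(M) {
  pos <- expand.grid(i = seq_len(M), j = seq_len(M)) # token order: i fast
  K <- M * M
  idx <- integer(K * K)
  n <- 0L
  for (q in seq_len(K)) {
    for (k in seq_len(K)) {
      n <- n + 1L
      di <- pos$i[k] - pos$i[q] + M - 1L
      dj <- pos$j[k] - pos$j[q] + M - 1L
      idx[n] <- di * (2L * M - 1L) + dj + 1L
    }
  }
  idx
}

# shifted-window attention mask: (K, K, nw) array of 0 / -1e9
swin_shift_mask <- function(H, W, M, s) {
  idmap <- matrix(0, H, W)
  hs <- list(seq_len(H - M), H - M + seq_len(M - s), H - s + seq_len(s))
  ws <- list(seq_len(W - M), W - M + seq_len(M - s), W - s + seq_len(s))
  cnt <- 0
  for (a in 1:3) for (b in 1:3) {
    if (length(hs[[a]]) && length(ws[[b]])) {
      idmap[hs[[a]], ws[[b]]] <- cnt
    }
    cnt <- cnt + 1
  }
  nwh <- H %/% M; nww <- W %/% M
  K <- M * M
  mask <- array(0, c(K, K, nwh * nww))
  # partition layout: batch index = (iw fast, jw slow)
  for (jw in seq_len(nww)) for (iw in seq_len(nwh)) {
    ids <- as.vector(idmap[(iw - 1L) * M + seq_len(M), (jw - 1L) * M + seq_len(M)])
    d <- outer(ids, ids, FUN = function(a, b) ifelse(a == b, 0, -1e9))
    mask[, , (jw - 1L) * nwh + iw] <- d # [key, query]
  }
  mask
}

#' Shifted-window transformer block
#'
#' Pre-norm block: window (or shifted-window) multi-head self-attention with
#' relative position bias, then a 2-layer GELU MLP, each with a residual
#' connection. The window is clamped to the feature size when larger; the
#' shifted variant displaces windows by `floor(M/2)` with masked attention
#' across wrap boundaries.
#' @param d token dimension.
#' @param heads number of attention heads (`d %% heads == 0`).
#' @param input_resolution `(H, W)` of the token grid this block will see.
#' @param window window side M before clamping.
#' @param shifted logical; use the displaced window layout?
#' @param mlp_ratio hidden-layer multiplier of the MLP.
#' @return a module on `(D, H, W, B)` token grids.
#' @export
mod_swin_block <- function(d, heads, input_resolution, window = 7L,
                           shifted = FALSE, mlp_ratio = 4) {
  stopifnot(d %% heads == 0)
  m <- new_module("swin_block")
  H <- input_resolution[1]; W <- input_resolution[2]
  M <- min(window, H, W)
  s <- if (M > 1) M %/% 2L else 0L
  if (M == H && M == W) s <- 0L # single window: shifting is a no-op
  if (H %% M != 0 || W %% M != 0) {
    stop("token grid ", H, "x", W, " is not divisible by window ", M,
         "; choose a window that divides the stage resolution")
  }
  m$d <- d; m$heads <- heads; m$M <- M
  m$shifted <- shifted && s > 0L
  m$s <- if (m$shifted) s else 0L
  m$H <- H; m$W <- W
  m$mlp_hidden <- as.integer(round(mlp_ratio * d))
  m$children$ln1 <- mod_layernorm(d)
  m$children$qkv <- mod_linear(d, 3L * d)
  m$children$proj <- mod_linear(d, d)
  m$children$ln2 <- mod_layernorm(d)
  m$children$fc1 <- mod_linear(d, m$mlp_hidden)
  m$children$fc2 <- mod_linear(m$mlp_hidden, d)
  reg_param(m, "relpos", matrix(stats::rnorm((2 * M - 1)^2 * heads, sd = 0.02),
                                (2 * M - 1)^2, heads))
  m$relidx <- relpos_index(M)
  m$mask <- if (m$shifted) swin_shift_mask(H, W, M, m$s) else NULL
  m
}

# windows: (D, H, W, B) -> (D, K, nw*B); batch order (iw fast, jw, b slow)
win_partition <- function(x, M) {
  d <- dim(vl(x))
  H <- d[2]; W <- d[3]; B <- d[4]
  nwh <- H %/% M; nww <- W %/% M
  x <- ag_reshape(x, c(d[1], M, nwh, M, nww, B))
  x <- ag_aperm(x, c(1, 2, 4, 3, 5, 6))
  ag_reshape(x, c(d[1], M * M, nwh * nww * B))
}

win_merge <- function(x, M, H, W, B) {
  nwh <- H %/% M; nww <- W %/% M
  d1 <- dim(vl(x))[1]
  x <- ag_reshape(x, c(d1, M, M, nwh, nww, B))
  x <- ag_aperm(x, c(1, 2, 4, 3, 5, 6))
  ag_reshape(x, c(d1, H, W, B))
}

swin_attention <- function(m, x) {
  D <- m$d; M <- m$M; K <- M * M; h <- m$heads; hd <- D %/% h
  d <- dim(vl(x))
  H <- d[2]; W <- d[3]; B <- d[4]
  if (m$s > 0) x <- ag_roll2(x, -m$s, -m$s)
  xw <- win_partition(x, M)                       # (D, K, nw*B)
  nb <- dim(vl(xw))[3]
  qkv <- sr_forward(m$children$qkv, ag_reshape(xw, c(D, K * nb)))
  qkv <- ag_aperm(ag_reshape(qkv, c(hd, h, 3L, K, nb)), c(3, 1, 2, 4, 5))
  split_head <- function(i) {
    t <- ag_take1(qkv, i)                          # (1, hd, h, K, nb)
    t <- ag_reshape(t, c(hd, h, K, nb))
    ag_reshape(ag_aperm(t, c(1, 3, 2, 4)), c(hd, K, h * nb))
  }
  q <- split_head(1L); k <- split_head(2L); v <- split_head(3L)
  scores <- ag_smul(ag_bmm(ag_aperm(k, c(2, 1, 3)), q), 1 / sqrt(hd)) # (Kk, Kq, h*nb)
  bias <- ag_gather_rows(m$params$relpos, m$relidx)  # (K*K, h), key fast
  bias <- ag_reshape(bias, c(K, K, h))
  bias <- ag_reshape(ag_tile_last(bias, nb), c(K, K, h * nb))
  scores <- ag_add(scores, bias)
  if (!is.null(m$mask)) {
    nw <- dim(m$mask)[3]
    mk <- array(rep(as.vector(m$mask), times = h), c(K, K, nw, h))
    mk <- aperm(mk, c(1, 2, 4, 3))                 # (K, K, h, nw)
    mk <- array(rep(as.vector(mk), times = B), c(K, K, h * nw * B))
    scores <- ag_addc(scores, mk)
  }
  attn <- ag_softmax1(scores)
  out <- ag_bmm(v, attn)                           # (hd, Kq, h*nb)
  out <- ag_reshape(out, c(hd, K, h, nb))
  out <- ag_reshape(ag_aperm(out, c(1, 3, 2, 4)), c(D, K * nb))
  out <- sr_forward(m$children$proj, out)
  out <- win_merge(ag_reshape(out, c(D, K, nb)), M, H, W, B)
  if (m$s > 0) out <- ag_roll2(out, m$s, m$s)
  out
}

#' @export
sr_forward.sr_swin_block <- function(m, x, ...) {
  x <- as_ag(x)
  att <- swin_attention(m, sr_forward(m$children$ln1, x))
  x <- ag_add(x, att)
  mlp <- sr_forward(m$children$fc2,
                    ag_gelu(sr_forward(m$children$fc1,
                                       sr_forward(m$children$ln2, x))))
  ag_add(x, mlp)
}

#' @export
sr_count.sr_swin_block <- function(m, in_shape) {
  D <- m$d
  n <- in_shape[2] * in_shape[3]
  K <- m$M^2
  macs <- 3 * n * D^2 +      # qkv
    2 * n * K * D +          # scores and aggregation
    n * D^2 +                # output projection
    2 * n * D * m$mlp_hidden # MLP
  list(macs = macs, out = in_shape)
}

# ---- patch embedding and merging -------------------------------------------

mod_patch_embed <- function(cin, d, patch = 4L) {
  m <- new_module("patch_embed")
  m$patch <- patch; m$d <- d
  m$children$conv <- mod_conv2d(cin, d, patch, stride = patch, bias = TRUE)
  m$children$norm <- mod_layernorm(d)
  m
}

#' @export
sr_forward.sr_patch_embed <- function(m, x, ...) {
  sr_forward(m$children$norm, sr_forward(m$children$conv, x))
}

#' @export
sr_count.sr_patch_embed <- function(m, in_shape) sr_count(m$children$conv, in_shape)

mod_patch_merge <- function(din, dout) {
  m <- new_module("patch_merge")
  m$din <- din; m$dout <- dout
  m$children$norm <- mod_layernorm(4L * din)
  m$children$reduce <- mod_linear(4L * din, dout, bias = FALSE)
  m
}

#' @export
sr_forward.sr_patch_merge <- function(m, x, ...) {
  x <- as_ag(x)
  d <- dim(vl(x))
  D <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  x <- ag_reshape(x, c(D, 2L, H %/% 2L, 2L, W %/% 2L, B))
  x <- ag_aperm(x, c(1, 2, 4, 3, 5, 6))             # (D, 2, 2, H/2, W/2, B)
  x <- ag_reshape(x, c(4L * D, H %/% 2L, W %/% 2L, B))
  sr_forward(m$children$reduce, sr_forward(m$children$norm, x))
}

#' @export
sr_count.sr_patch_merge <- function(m, in_shape) {
  ho <- in_shape[2] %/% 2; wo <- in_shape[3] %/% 2
  list(macs = 4 * m$din * m$dout * ho * wo, out = c(m$dout, ho, wo))
}

# ---- model configuration ---------------------------------------------------

#' Define a Swim-Rep model variant
#'
#' @param stage_widths 4 strictly increasing channel counts.
#' @param rep_depths,swin_depths 4 nonnegative block counts per stage; every
#'   stage must hold at least one block.
#' @param window attention window side M.
#' @param heads 4 head counts (each must divide its stage width).
#' @param num_classes classifier width.
#' @param fusion inter-stage fusion: `"none"`, `"aff"` or `"mpf"`.
#' @param attention inter-stage attention: `"none"` or `"frcpa"`.
#' @param input_size `(H, W)`; must be divisible by `patch * 8` so all four
#'   stages are well-formed.
#' @param patch patch-embedding stride.
#' @param connection stage wiring; only `"serial"` is implemented.
#' @return a `swimrep_config` list.
#' @export
swimrep_config <- function(stage_widths, rep_depths, swin_depths,
                           window = 7L, heads = c(2L, 4L, 8L, 16L),
                           num_classes = 5L,
                           fusion = c("none", "aff", "mpf"),
                           attention = c("none", "frcpa"),
                           input_size = c(224L, 224L), patch = 4L,
                           connection = "serial") {
  fusion <- match.arg(fusion)
  attention <- match.arg(attention)
  stopifnot(length(stage_widths) == 4, length(rep_depths) == 4,
            length(swin_depths) == 4, length(heads) == 4)
  if (any(rep_depths < 0) || any(swin_depths < 0)) {
    stop("block depths must be nonnegative")
  }
  if (any(rep_depths + swin_depths < 1)) {
    stop("every stage needs at least one block")
  }
  if (any(diff(stage_widths) <= 0)) {
    stop("stage widths must be strictly increasing")
  }
  if (any(input_size %% (patch * 8L) != 0)) {
    stop("input size ", paste(input_size, collapse = "x"),
         " must be divisible by patch size * 8 = ", patch * 8L,
         " so that all four stages have integer resolutions")
  }
  if (any(stage_widths %% heads != 0)) {
    stop("each stage width must be divisible by its head count")
  }
  structure(list(stage_widths = as.integer(stage_widths),
                 rep_depths = as.integer(rep_depths),
                 swin_depths = as.integer(swin_depths),
                 window = as.integer(window), heads = as.integer(heads),
                 num_classes = as.integer(num_classes),
                 fusion = fusion, attention = attention,
                 input_size = as.integer(input_size), patch = as.integer(patch),
                 connection = connection),
            class = "swimrep_config")
}

#' Built-in model variants
#'
#' `"tiny"` is the desk-scale test variant (32x32 input); `"even"` is the
#' default evenly-stacked hybrid at 224x224; `"repvgg-b0"` and `"swin-base"`
#' are the pure reference architectures used for complexity accounting.
#' @param name variant name.
#' @param num_classes classifier width.
#' @return a `swimrep_config` (for hybrid variants) or the name tag (for the
#'   pure reference variants, consumed by [build_reference()]).
#' @export
swimrep_variant <- function(name = c("tiny", "even"), num_classes = 5L) {
  name <- match.arg(name)
  switch(name,
    tiny = swimrep_config(stage_widths = c(8L, 16L, 32L, 64L),
                          rep_depths = c(1L, 1L, 1L, 1L),
                          swin_depths = c(1L, 1L, 1L, 1L),
                          window = 4L, heads = c(2L, 2L, 4L, 4L),
                          num_classes = num_classes,
                          fusion = "mpf", attention = "frcpa",
                          input_size = c(32L, 32L)),
    even = swimrep_config(stage_widths = c(64L, 128L, 256L, 512L),
                          rep_depths = c(2L, 2L, 2L, 2L),
                          swin_depths = c(2L, 2L, 2L, 2L),
                          window = 7L, heads = c(4L, 8L, 16L, 32L),
                          num_classes = num_classes,
                          fusion = "mpf", attention = "frcpa",
                          input_size = c(224L, 224L))
  )
}

# ---- assembly --------------------------------------------------------------

#' Build a Swim-Rep fusion network
#'
#' Patch embedding, then four stages of Rep blocks followed by Swin blocks
#' (stage resolutions 1/4, 1/8, 1/16, 1/32 of the input); between consecutive
#' stages the previous stage's output is aligned with [mod_align()] and fused
#' into the current stage (per `cfg$fusion`), then refined with FRCPA (per
#' `cfg$attention`); finally layer norm, global average pooling and a linear
#' classifier head.
#' @param cfg a [swimrep_config()].
#' @return a model module; forward maps `(3, H, W, B)` to `(num_classes, B)`.
#' @export
build_swimrep <- function(cfg) {
  stopifnot(inherits(cfg, "swimrep_config"))
  if (!identical(cfg$connection, "serial")) {
    stop("connection style '", cfg$connection, "' is not implemented; only 'serial'")
  }
  m <- new_module("swimrep")
  m$cfg <- cfg
  w <- cfg$stage_widths
  res <- lapply(1:4, function(i) cfg$input_size %/% (cfg$patch * 2L^(i - 1L)))
  m$res <- res
  m$children$embed <- mod_patch_embed(3L, w[1], cfg$patch)
  for (i in 1:4) {
    st <- new_module("stage")
    if (cfg$rep_depths[i] > 0) {
      for (r in seq_len(cfg$rep_depths[i])) {
        st$children[[paste0("rep", r)]] <- mod_rep_block(w[i], w[i], 1L)
      }
    }
    if (cfg$swin_depths[i] > 0) {
      for (s in seq_len(cfg$swin_depths[i])) {
        st$children[[paste0("swin", s)]] <-
          mod_swin_block(w[i], cfg$heads[i], res[[i]], cfg$window,
                         shifted = (s %% 2L == 0L))
      }
    }
    m$children[[paste0("stage", i)]] <- st
    if (i < 4) {
      m$children[[paste0("merge", i)]] <- mod_patch_merge(w[i], w[i + 1])
    }
    if (i > 1) {
      if (cfg$fusion != "none") {
        m$children[[paste0("align", i)]] <- mod_align(w[i - 1], w[i])
        m$children[[paste0("fuse", i)]] <-
          if (cfg$fusion == "aff") mod_aff(w[i]) else mod_mpf(w[i])
      }
      if (cfg$attention == "frcpa") {
        m$children[[paste0("attn", i)]] <- mod_frcpa(w[i])
      }
    }
  }
  m$children$norm <- mod_layernorm(w[4])
  m$children$head <- mod_linear(w[4], cfg$num_classes)
  m
}

stage_forward <- function(st, x) {
  for (blk in st$children) x <- sr_forward(blk, x)
  x
}

#' @export
sr_forward.sr_swimrep <- function(m, x, ...) {
  cfg <- m$cfg
  x <- sr_forward(m$children$embed, as_ag(x))
  prev <- NULL
  for (i in 1:4) {
    if (i > 1) x <- sr_forward(m$children[[paste0("merge", i - 1)]], x)
    s <- stage_forward(m$children[[paste0("stage", i)]], x)
    if (i > 1 && cfg$fusion != "none") {
      al <- sr_forward(m$children[[paste0("align", i)]], prev,
                       m$res[[i]][1], m$res[[i]][2])
      s <- sr_forward(m$children[[paste0("fuse", i)]], s, al)
    }
    if (i > 1 && cfg$attention == "frcpa" && all(dim(vl(s))[2:3] >= 2)) {
      s <- sr_forward(m$children[[paste0("attn", i)]], s)
    }
    prev <- s
    x <- s
  }
  x <- sr_forward(m$children$norm, x)
  z <- ag_mean_hw(x)                                 # (C, B)
  sr_forward(m$children$head, z)
}

#' @export
sr_count.sr_swimrep <- function(m, in_shape) {
  cfg <- m$cfg
  total <- 0
  sc <- sr_count(m$children$embed, in_shape)
  total <- total + sc$macs
  shp <- sc$out
  for (i in 1:4) {
    if (i > 1) {
      mg <- sr_count(m$children[[paste0("merge", i - 1)]], shp)
      total <- total + mg$macs
      shp <- mg$out
    }
    for (blk in m$children[[paste0("stage", i)]]$children) {
      bc <- sr_count(blk, shp)
      total <- total + bc$macs
      shp <- bc$out
    }
    if (i > 1 && cfg$fusion != "none") {
      total <- total + sr_count(m$children[[paste0("align", i)]], shp)$macs
      total <- total + sr_count(m$children[[paste0("fuse", i)]], shp)$macs
    }
    if (i > 1 && cfg$attention == "frcpa" && all(shp[2:3] >= 2)) {
      total <- total + sr_count(m$children[[paste0("attn", i)]], shp)$macs
    }
  }
  total <- total + cfg$stage_widths[4] * cfg$num_classes
  list(macs = total, out = c(cfg$num_classes, 1, 1))
}

#' Operator-level forward-pass FLOP count
#'
#' Multiply-accumulate count of one forward pass at the stated input size,
#' covering convolutions, linear layers and attention matrix products
#' (one MAC = one FLOP unit; normalizations and activations excluded).
#' @param model a built model.
#' @param input_h,input_w input spatial size.
#' @param cin input channels.
#' @return numeric MAC count.
#' @export
count_flops <- function(model, input_h = 224L, input_w = 224L, cin = 3L) {
  sr_count(model, c(cin, input_h, input_w))$macs
}

# ---- reference architectures ----------------------------------------------

#' Build a reference architecture for complexity accounting
#'
#' `"repvgg-b0"`: five groups of Rep blocks (depths 1, 4, 6, 16, 1; widths 64,
#' 64, 128, 256, 1280; the first block of each group has stride 2) with a
#' global-average-pool linear head. `"swin-base"`: patch-4 embedding to 128
#' channels, depths (2, 2, 18, 2), heads (4, 8, 16, 32), window 7.
#' @param name reference model name.
#' @param num_classes classifier width (7 for the scene-classification
#'   benchmark these reference counts are quoted at).
#' @return a model module.
#' @export
build_reference <- function(name = c("repvgg-b0", "swin-base"), num_classes = 7L) {
  name <- match.arg(name)
  if (name == "swin-base") {
    cfg <- swimrep_config(stage_widths = c(128L, 256L, 512L, 1024L),
                          rep_depths = c(0L, 0L, 0L, 0L),
                          swin_depths = c(2L, 2L, 18L, 2L),
                          window = 7L, heads = c(4L, 8L, 16L, 32L),
                          num_classes = num_classes,
                          fusion = "none", attention = "none")
    return(build_swimrep(cfg))
  }
  m <- new_module("repvgg")
  widths <- c(64L, 64L, 128L, 256L, 1280L)
  depths <- c(1L, 4L, 6L, 16L, 1L)
  cin <- 3L
  for (g in seq_along(widths)) {
    for (b in seq_len(depths[g])) {
      stride <- if (b == 1L) 2L else 1L
      m$children[[paste0("g", g, "b", b)]] <- mod_rep_block(cin, widths[g], stride)
      cin <- widths[g]
    }
  }
  m$children$head <- mod_linear(1280L, num_classes)
  m$num_classes <- num_classes
  m
}

#' @export
sr_forward.sr_repvgg <- function(m, x, ...) {
  x <- as_ag(x)
  for (nm in names(m$children)) {
    if (nm == "head") break
    x <- sr_forward(m$children[[nm]], x)
  }
  sr_forward(m$children$head, ag_mean_hw(x))
}

#' @export
sr_count.sr_repvgg <- function(m, in_shape) {
  shp <- in_shape
  total <- 0
  for (nm in names(m$children)) {
    if (nm == "head") break
    bc <- sr_count(m$children[[nm]], shp)
    total <- total + bc$macs
    shp <- bc$out
  }
  total <- total + shp[1] * m$num_classes
  list(macs = total, out = c(m$num_classes, 1, 1))
}
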