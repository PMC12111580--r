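# Reverse-mode automatic differentiation over dense R arrays.
#
# Feature maps are stored channel-first as (C, H, W, B) arrays, token blocks as
# (D, N, B) or (D, cols) matrices; C/D is always the fastest-varying dimension so
# per-channel broadcasts reduce to ordinary R recycling and convolutions reduce
# to BLAS matrix products over kernel taps.
#
# Every operation returns a lightweight node (an environment holding the value).
# When a tape is active (see `with_tape`) the node also carries a backward
# closure; `ag_backward` replays the tape in reverse creation order, which is a
# valid topological order because the graph is built during the forward pass.

the <- new.env(parent = emptyenv())
the$tape <- NULL

new_ag <- function(value, req = TRUE) {
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$bw <- NULL
  n$parents <- NULL
  n$req <- req
  class(n) <- "ag"
  n
}

#' Wrap an array as an autograd tensor
#'
#' @param value numeric array (or vector/matrix).
#' @param req logical; should gradients be accumulated into this node?
#' @return an object of class `ag` whose value is accessible with [vl()].
#' @export
ag_tensor <- function(value, req = FALSE) new_ag(value, req = req)

#' Create a trainable parameter node
#'
#' Parameter nodes persist across tapes; gradients accumulate into `$g` until
#' [opt_zero_grad()] clears them.
#' @param value initial numeric array.
#' @return an `ag` node flagged as a parameter.
#' @export
ag_param <- function(value) {
  n <- new_ag(value, req = TRUE)
  n$param <- TRUE
  n
}

#' Extract the value array of an autograd node
#' @param x an `ag` node (plain arrays pass through).
#' @return the underlying numeric array.
#' @export
vl <- function(x) if (inherits(x, "ag")) x$v else x

as_ag <- function(x) if (inherits(x, "ag")) x else new_ag(x, req = FALSE)

tape_push <- function(n) {
  t <- the$tape
  t$k <- t$k + 1L
  t$nodes[[t$k]] <- n
  invisible(n)
}

#' Record a computation on a fresh gradient tape
#'
#' @param expr expression to evaluate; operations executed inside are recorded
#'   so that [ag_backward()] can propagate gradients.
#' @return the value of `expr`.
#' @export
with_tape <- function(expr) {
  old <- the$tape
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 4096L)
  t$k <- 0L
  the$tape <- t
  on.exit(the$tape <- old, add = TRUE)
  force(expr)
}

# Register an op result on the active tape. `backward` receives the output
# gradient and must return a list of gradient arrays aligned with `parents`
# (NULL entries for parents that need no gradient).
ag_op <- function(value, parents, backward) {
  n <- new_ag(value)
  if (!is.null(the$tape)) {
    n$parents <- parents
    n$bw <- backward
    tape_push(n)
  }
  n
}

#' Backpropagate gradients from a scalar loss node
#'
#' Must be called inside the same [with_tape()] scope that built `root`.
#' @param root the loss node (its gradient seed is 1).
#' @export
ag_backward <- function(root) {
  t <- the$tape
  if (is.null(t)) stop("ag_backward() called with no active tape")
  root$g <- array(1, dim = dim1(root$v))
  for (i in seq(t$k, 1L)) {
    n <- t$nodes[[i]]
    if (is.null(n$g) || is.null(n$bw)) next
    gs <- n$bw(n$g)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.null(p) || !p$req || is.null(gs[[j]])) next
      p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
    }
    if (is.null(n$param)) n$g <- NULL # free intermediate grads eagerly
  }
  invisible(NULL)
}

dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# ---- elementwise ----------------------------------------------------------

#' @rdname ag-ops
#' @param a,b `ag` nodes or arrays of identical shape.
#' @export
ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$v + b$v, list(a, b), function(g) list(g, g))
}

#' @rdname ag-ops
#' @export
ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_op(a$v - b$v, list(a, b), function(g) list(g, -g))
}

#' @rdname ag-ops
#' @export
ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$v; bv <- b$v
  ag_op(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

#' Elementwise operations on autograd nodes
#'
#' Shape-preserving arithmetic and activation primitives. All record backward
#' closures when a tape is active.
#' @name ag-ops
#' @param x an `ag` node or array.
#' @param s a plain scalar.
#' @return an `ag` node.
NULL

#' @rdname ag-ops
#' @export
ag_smul <- function(x, s) {
  x <- as_ag(x)
  ag_op(x$v * s, list(x), function(g) list(g * s))
}

#' @rdname ag-ops
#' @export
ag_relu <- function(x) {
  x <- as_ag(x)
  m <- x$v > 0
  ag_op(x$v * m, list(x), function(g) list(g * m))
}

#' @rdname ag-ops
#' @export
ag_sigmoid <- function(x) {
  x <- as_ag(x)
  y <- 1 / (1 + exp(-x$v))
  ag_op(y, list(x), function(g) list(g * y * (1 - y)))
}

#' @rdname ag-ops
#' @export
ag_gelu <- function(x) {
  x <- as_ag(x)
  xv <- x$v
  ph <- stats::pnorm(xv)
  ag_op(xv * ph, list(x), function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

# Add a per-leading-dim bias: bias length == dim(x)[1]; recycling down the
# fastest dimension makes this a plain vector add.
#' @rdname ag-ops
#' @param bias `ag` node holding a vector of length `dim(x)[1]`.
#' @export
ag_bias1 <- function(x, bias) {
  x <- as_ag(x); bias <- as_ag(bias)
  d <- dim1(x$v)
  ag_op(x$v + as.vector(bias$v), list(x, bias), function(g) {
    list(g, rowSums(matrix(g, nrow = d[1])))
  })
}

# Add a constant (non-differentiated) array, recycled like base R.
ag_addc <- function(x, cst) {
  x <- as_ag(x)
  ag_op(x$v + cst, list(x), function(g) list(g))
}

# ---- shape ----------------------------------------------------------------

#' @rdname ag-ops
#' @param dims integer vector of target dimensions.
#' @export
ag_reshape <- function(x, dims) {
  x <- as_ag(x)
  old <- dim1(x$v)
  v <- x$v
  dim(v) <- dims
  ag_op(v, list(x), function(g) { dim(g) <- old; list(g) })
}

#' @rdname ag-ops
#' @param perm permutation of the dimensions, as in [aperm()].
#' @export
ag_aperm <- function(x, perm) {
  x <- as_ag(x)
  inv <- order(perm)
  ag_op(aperm(x$v, perm), list(x), function(g) list(aperm(g, inv)))
}

#' @rdname ag-ops
#' @export
ag_concat1 <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  da <- dim1(a$v); db <- dim1(b$v)
  nd <- length(da)
  v <- array(0, c(da[1] + db[1], da[-1]))
  ia <- seq_len(da[1]); ib <- da[1] + seq_len(db[1])
  arr_assign1(v, ia) <- a$v
  arr_assign1(v, ib) <- b$v
  ag_op(v, list(a, b), function(g) {
    list(arr_index1(g, ia), arr_index1(g, ib))
  })
}

# index/assign along dim 1 of an n-d array without spelling out commas
arr_index1 <- function(x, idx) {
  d <- dim1(x)
  m <- matrix(x, nrow = d[1])
  out <- m[idx, , drop = FALSE]
  dim(out) <- c(length(idx), d[-1])
  out
}
`arr_assign1<-` <- function(x, idx, value) {
  d <- dim1(x)
  m <- matrix(x, nrow = d[1])
  m[idx, ] <- value
  dim(m) <- d
  m
}

#' @rdname ag-ops
#' @param idx integer indices (unique) into dimension 1.
#' @export
ag_take1 <- function(x, idx) {
  x <- as_ag(x)
  d <- dim1(x$v)
  ag_op(arr_index1(x$v, idx), list(x), function(g) {
    out <- array(0, d)
    arr_assign1(out, idx) <- g
    list(out)
  })
}

# ---- matrix products ------------------------------------------------------

#' @rdname ag-ops
#' @param A,B matrices (or `ag` nodes holding them).
#' @export
ag_matmul <- function(A, B) {
  A <- as_ag(A); B <- as_ag(B)
  Av <- A$v; Bv <- B$v
  ag_op(Av %*% Bv, list(A, B), function(g) {
    list(g %*% t(Bv), t(Av) %*% g)
  })
}

#' Batched matrix multiply
#'
#' Multiplies `(m, k, nb)` by `(k, n, nb)` slice-wise, giving `(m, n, nb)`.
#' @param A,B rank-3 `ag` nodes or arrays with matching batch size.
#' @return an `ag` node of shape `(m, n, nb)`.
#' @export
ag_bmm <- function(A, B) {
  A <- as_ag(A); B <- as_ag(B)
  Av <- A$v; Bv <- B$v
  da <- dim(Av); db <- dim(Bv)
  stopifnot(length(da) == 3L, length(db) == 3L, da[2] == db[1], da[3] == db[3])
  nb <- da[3]
  out <- array(0, c(da[1], db[2], nb))
  for (i in seq_len(nb)) {
    out[, , i] <- matrix(Av[, , i], da[1], da[2]) %*% matrix(Bv[, , i], db[1], db[2])
  }
  ag_op(out, list(A, B), function(g) {
    gA <- array(0, da); gB <- array(0, db)
    for (i in seq_len(nb)) {
      gi <- matrix(g[, , i], da[1], db[2])
      gA[, , i] <- gi %*% t(matrix(Bv[, , i], db[1], db[2]))
      gB[, , i] <- t(matrix(Av[, , i], da[1], da[2])) %*% gi
    }
    list(gA, gB)
  })
}

# ---- softmax / normalization ---------------------------------------------

#' @rdname ag-ops
#' @export
ag_softmax1 <- function(x) {
  x <- as_ag(x)
  d <- dim1(x$v)
  m <- matrix(x$v, nrow = d[1])
  m <- m - rep(apply(m, 2, max), each = d[1])
  e <- exp(m)
  p <- e / rep(colSums(e), each = d[1])
  pv <- p; dim(pv) <- d
  ag_op(pv, list(x), function(g) {
    gm <- matrix(g, nrow = d[1])
    dot <- colSums(gm * p)
    gx <- p * (gm - rep(dot, each = d[1]))
    dim(gx) <- d
    list(gx)
  })
}

#' Layer normalization over the leading dimension
#'
#' Normalizes each column of the `(D, cols)` view of `x` to zero mean and unit
#' variance, then applies a learned per-feature affine transform.
#' @param x `ag` node; `gamma`, `beta` length-`D` parameter nodes.
#' @param gamma,beta affine parameters.
#' @param eps variance floor.
#' @return an `ag` node shaped like `x`.
#' @export
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim1(x$v)
  D <- d[1]
  m <- matrix(x$v, nrow = D)
  mu <- colMeans(m)
  xc <- m - rep(mu, each = D)
  va <- colMeans(xc * xc)
  istd <- 1 / sqrt(va + eps)
  xn <- xc * rep(istd, each = D)
  gv <- as.vector(gamma$v)
  out <- xn * gv + as.vector(beta$v)
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = D)
    dgamma <- rowSums(gm * xn)
    dbeta <- rowSums(gm)
    gh <- gm * gv
    # d/dx of column-wise standardization
    s1 <- colSums(gh)
    s2 <- colSums(gh * xn)
    gx <- (gh - rep(s1, each = D) / D - xn * rep(s2, each = D) / D) *
      rep(istd, each = D)
    dim(gx) <- d
    list(gx, dgamma, dbeta)
  })
}

# ---- reductions / broadcast ----------------------------------------------

#' Spatial mean of a feature map
#' @param x `(C, H, W, B)` node.
#' @return `(C, B)` node of per-channel spatial means.
#' @export
ag_mean_hw <- function(x) {
  x <- as_ag(x)
  d <- dim(x$v)
  hw <- d[2] * d[3]
  m <- array(x$v, c(d[1], hw, d[4]))
  out <- colSums(aperm(m, c(2, 1, 3))) / hw # (C, B)
  dim(out) <- c(d[1], d[4])
  ag_op(out, list(x), function(g) {
    gm <- matrix(g, d[1], d[4])
    gfull <- array(gm[, rep(seq_len(d[4]), each = hw)] / hw, d)
    list(gfull)
  })
}

#' Broadcast a per-channel map over space
#' @param x `(C, 1, 1, B)` (or `(C, B)`) node.
#' @param H,W target spatial size.
#' @return `(C, H, W, B)` node.
#' @export
ag_expand_hw <- function(x, H, W) {
  x <- as_ag(x)
  d <- dim1(x$v)
  C <- d[1]; B <- d[length(d)]
  hw <- H * W
  m <- matrix(x$v, C, B)
  out <- array(m[, rep(seq_len(B), each = hw), drop = FALSE], c(C, H, W, B))
  ag_op(out, list(x), function(g) {
    g3 <- array(g, c(C, hw, B))
    gs <- colSums(aperm(g3, c(2, 1, 3))) # (C, B)
    dim(gs) <- d
    list(gs)
  })
}

#' Broadcast a single-channel map over channels
#' @param x `(1, H, W, B)` node.
#' @param C target channel count.
#' @return `(C, H, W, B)` node.
#' @export
ag_expand_c <- function(x, C) {
  x <- as_ag(x)
  d <- dim1(x$v)
  out <- array(rep(as.vector(x$v), each = C), c(C, d[2], d[3], d[4]))
  ag_op(out, list(x), function(g) {
    gs <- colSums(matrix(g, nrow = C))
    dim(gs) <- d
    list(gs)
  })
}

# Tile a (..., K) array to (..., K, times) along a new trailing dim.
ag_tile_last <- function(x, times) {
  x <- as_ag(x)
  d <- dim1(x$v)
  out <- array(rep(as.vector(x$v), times), c(d, times))
  ag_op(out, list(x), function(g) {
    gm <- matrix(g, nrow = prod(d))
    gs <- rowSums(gm)
    dim(gs) <- d
    list(gs)
  })
}

# Gather rows of a (T, h) table: out[k, j] = tab[idx[k], j], idx may repeat.
ag_gather_rows <- function(tab, idx) {
  tab <- as_ag(tab)
  dt <- dim1(tab$v)
  tv <- matrix(tab$v, nrow = dt[1])
  out <- tv[idx, , drop = FALSE]
  ag_op(out, list(tab), function(g) {
    gm <- matrix(g, nrow = length(idx))
    acc <- rowsum(gm, group = idx)
    out2 <- matrix(0, dt[1], dt[2])
    out2[as.integer(rownames(acc)), ] <- acc
    dim(out2) <- dt
    list(out2)
  })
}

# ---- convolution ----------------------------------------------------------

pad_hw <- function(x, p) {
  p <- rep(p, length.out = 2)
  if (all(p == 0)) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p[1], d[3] + 2 * p[2], d[4]))
  out[, p[1] + seq_len(d[2]), p[2] + seq_len(d[3]), ] <- x
  out
}

#' 2-D convolution (channel-first)
#'
#' Cross-correlation of a `(C_in, H, W, B)` map with a `(C_out, C_in, kh, kw)`
#' kernel, implemented as one BLAS product per kernel tap.
#' @param x input node.
#' @param w kernel parameter node.
#' @param bias optional length-`C_out` parameter node.
#' @param stride,pad integer stride and zero padding; scalars or length-2
#'   `(height, width)` vectors.
#' @return `(C_out, H_out, W_out, B)` node.
#' @export
ag_conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L) {
  x <- as_ag(x); w <- as_ag(w)
  if (!is.null(bias)) bias <- as_ag(bias)
  stride <- rep(as.integer(stride), length.out = 2)
  pad <- rep(as.integer(pad), length.out = 2)
  dx <- dim(x$v); dw <- dim(w$v)
  Cin <- dx[1]; H <- dx[2]; W <- dx[3]; B <- dx[4]
  Cout <- dw[1]; kh <- dw[3]; kw <- dw[4]
  stopifnot(dw[2] == Cin)
  Ho <- (H + 2L * pad[1] - kh) %/% stride[1] + 1L
  Wo <- (W + 2L * pad[2] - kw) %/% stride[2] + 1L
  xp <- pad_hw(x$v, pad)
  L <- Ho * Wo * B
  acc <- matrix(0, Cout, L)
  for (di in seq_len(kh)) {
    ih <- di + stride[1] * (seq_len(Ho) - 1L)
    for (dj in seq_len(kw)) {
      iw <- dj + stride[2] * (seq_len(Wo) - 1L)
      xs <- xp[, ih, iw, , drop = FALSE]
      acc <- acc + matrix(w$v[, , di, dj], Cout, Cin) %*% matrix(xs, Cin, L)
    }
  }
  if (!is.null(bias)) acc <- acc + as.vector(bias$v)
  out <- array(acc, c(Cout, Ho, Wo, B))
  parents <- list(x, w, bias)
  ag_op(out, parents, function(g) {
    gm <- matrix(g, Cout, L)
    gw <- array(0, dw)
    gxp <- array(0, dim(xp))
    for (di in seq_len(kh)) {
      ih <- di + stride[1] * (seq_len(Ho) - 1L)
      for (dj in seq_len(kw)) {
        iw <- dj + stride[2] * (seq_len(Wo) - 1L)
        xs <- matrix(xp[, ih, iw, , drop = FALSE], Cin, L)
        gw[, , di, dj] <- gm %*% t(xs)
        gslice <- t(matrix(w$v[, , di, dj], Cout, Cin)) %*% gm
        dim(gslice) <- c(Cin, Ho, Wo, B)
        gxp[, ih, iw, ] <- gxp[, ih, iw, , drop = FALSE] + gslice
      }
    }
    gx <- if (any(pad > 0)) {
      gxp[, pad[1] + seq_len(H), pad[2] + seq_len(W), , drop = FALSE]
    } else gxp
    dim(gx) <- dx
    gb <- if (!is.null(bias)) rowSums(gm) else NULL
    list(gx, gw, gb)
  })
}

#' Non-overlapping average pooling
#' @param x `(C, H, W, B)` node; `H`, `W` divisible by `k`.
#' @param k pooling window and stride.
#' @return `(C, H/k, W/k, B)` node.
#' @export
ag_avgpool2 <- function(x, k) {
  x <- as_ag(x)
  d <- dim(x$v)
  stopifnot(d[2] %% k == 0, d[3] %% k == 0)
  Ho <- d[2] %/% k; Wo <- d[3] %/% k
  v <- array(x$v, c(d[1], k, Ho, k, Wo, d[4]))
  v <- aperm(v, c(2, 4, 1, 3, 5, 6))
  out <- colMeans(matrix(v, nrow = k * k))
  dim(out) <- c(d[1], Ho, Wo, d[4])
  ag_op(out, list(x), function(g) {
    gup <- matrix(rep(as.vector(g) / (k * k), each = k * k), nrow = k * k)
    dim(gup) <- c(k, k, d[1], Ho, Wo, d[4])
    gup <- aperm(gup, c(3, 1, 4, 2, 5, 6))
    dim(gup) <- d
    list(gup)
  })
}

# ---- bilinear interpolation -----------------------------------------------

# Interpolation matrix for resizing n_in samples to n_out, align_corners=FALSE
# (half-pixel centers), edge-clamped.
interp_matrix <- function(n_in, n_out) {
  R <- matrix(0, n_out, n_in)
  if (n_in == 1) { R[, 1] <- 1; return(R) }
  scale <- n_in / n_out
  for (i in seq_len(n_out)) {
    src <- (i - 0.5) * scale - 0.5
    src <- min(max(src, 0), n_in - 1)
    i0 <- floor(src); w1 <- src - i0
    i0 <- as.integer(i0)
    i1 <- min(i0 + 1L, n_in - 1L)
    R[i, i0 + 1L] <- R[i, i0 + 1L] + (1 - w1)
    R[i, i1 + 1L] <- R[i, i1 + 1L] + w1
  }
  R
}

#' Bilinear spatial resampling
#'
#' Resizes a `(C, H, W, B)` map to `(C, oh, ow, B)` with half-pixel-center
#' bilinear interpolation (corner alignment disabled), as separable row/column
#' interpolation matrices.
#' @param x input node.
#' @param oh,ow output height and width.
#' @return resized `ag` node.
#' @export
ag_interp2 <- function(x, oh, ow) {
  x <- as_ag(x)
  d <- dim(x$v)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  Rh <- interp_matrix(H, oh)
  Rw <- interp_matrix(W, ow)
  fwd <- function(v) {
    m <- aperm(v, c(2, 3, 1, 4))             # (H, W, C, B)
    m <- Rh %*% matrix(m, H)                 # (oh, W*C*B)
    dim(m) <- c(oh, W, C, B)
    m <- aperm(m, c(2, 1, 3, 4))             # (W, oh, C, B)
    m <- Rw %*% matrix(m, W)                 # (ow, oh*C*B)
    dim(m) <- c(ow, oh, C, B)
    aperm(m, c(3, 2, 1, 4))                  # (C, oh, ow, B)
  }
  bwd <- function(g) {
    m <- aperm(g, c(3, 2, 1, 4))             # (ow, oh, C, B)
    m <- t(Rw) %*% matrix(m, ow)             # (W, oh*C*B)
    dim(m) <- c(W, oh, C, B)
    m <- aperm(m, c(2, 1, 3, 4))             # (oh, W, C, B)
    m <- t(Rh) %*% matrix(m, oh)             # (H, W*C*B)
    dim(m) <- c(H, W, C, B)
    aperm(m, c(3, 1, 2, 4))                  # (C, H, W, B)
  }
  ag_op(fwd(x$v), list(x), function(g) list(bwd(g)))
}

#' Circular (roll) shift of a feature map
#' @param x `(C, H, W, B)` node.
#' @param sh,sw shift along height and width (positive rolls down/right).
#' @return shifted node of the same shape.
#' @export
ag_roll2 <- function(x, sh, sw) {
  x <- as_ag(x)
  d <- dim(x$v)
  ih <- ((seq_len(d[2]) - 1L - sh) %% d[2]) + 1L
  iw <- ((seq_len(d[3]) - 1L - sw) %% d[3]) + 1L
  out <- x$v[, ih, iw, , drop = FALSE]
  ag_op(out, list(x), function(g) {
    jh <- ((seq_len(d[2]) - 1L + sh) %% d[2]) + 1L
    jw <- ((seq_len(d[3]) - 1L + sw) %% d[3]) + 1L
    list(g[, jh, jw, , drop = FALSE])
  })
}

# ---- batch normalization ---------------------------------------------------

#' 2-D batch normalization
#'
#' Per-channel normalization of a `(C, H, W, B)` map. In training mode batch
#' statistics are used and running statistics updated in `state` (an
#' environment with `$rm`, `$rv`); in eval mode the running statistics are
#' used.
#' @param x input node.
#' @param gamma,beta per-channel affine parameter nodes.
#' @param state environment holding running mean/var vectors `rm`, `rv`.
#' @param training logical.
#' @param momentum running-statistics update rate.
#' @param eps variance floor.
#' @return normalized node shaped like `x`.
#' @export
ag_bn2d <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$v)
  C <- d[1]; n <- prod(d[-1])
  m <- matrix(x$v, nrow = C)
  if (training) {
    mu <- rowMeans(m)
    xc <- m - mu
    va <- rowMeans(xc * xc)
    state$rm <- (1 - momentum) * state$rm + momentum * mu
    ub <- if (n > 1) va * n / (n - 1) else va
    state$rv <- (1 - momentum) * state$rv + momentum * ub
  } else {
    mu <- state$rm
    va <- state$rv
    xc <- m - mu
  }
  istd <- 1 / sqrt(va + eps)
  xn <- xc * istd
  gv <- as.vector(gamma$v)
  out <- xn * gv + as.vector(beta$v)
  dim(out) <- d
  ag_op(out, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = C)
    dgamma <- rowSums(gm * xn)
    dbeta <- rowSums(gm)
    gh <- gm * gv
    if (training) {
      s1 <- rowSums(gh)
      s2 <- rowSums(gh * xn)
      gx <- (gh - s1 / n - xn * s2 / n) * istd
    } else {
      gx <- gh * istd
    }
    dim(gx) <- d
    list(gx, dgamma, dbeta)
  })
}

# ---- losses ---------------------------------------------------------------

#' Mean cross-entropy from logits
#' @param logits `(K, N)` node of unnormalized scores.
#' @param y integer class labels in `1..K`, length `N`.
#' @return scalar `ag` loss node.
#' @export
ag_cross_entropy <- function(logits, y) {
  logits <- as_ag(logits)
  d <- dim1(logits$v)
  K <- d[1]; N <- d[2]
  m <- matrix(logits$v, K, N)
  mx <- apply(m, 2, max)
  z <- m - rep(mx, each = K)
  lse <- log(colSums(exp(z))) + mx
  picked <- m[cbind(y, seq_len(N))]
  loss <- mean(lse - picked)
  p <- exp(z) / rep(colSums(exp(z)), each = K)
  ag_op(loss, list(logits), function(g) {
    gx <- p
    gx[cbind(y, seq_len(N))] <- gx[cbind(y, seq_len(N))] - 1
    gx <- gx * (as.numeric(g) / N)
    dim(gx) <- d
    list(gx)
  })
}

#' Numerical gradient check helper
#'
#' Central-difference gradient of a scalar-valued function of one array, used
#' by the test suite as an oracle for the analytic backward passes.
#' @param f function taking an array and returning a scalar.
#' @param x0 point at which to differentiate.
#' @param eps step size.
#' @return array of the same shape as `x0`.
#' @export
num_grad <- function(f, x0, eps = 1e-5) {
  g <- array(0, dim1(x0))
  for (i in seq_along(x0)) {
    xp <- x0; xp[i] <- xp[i] + eps
    xm <- x0; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}
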