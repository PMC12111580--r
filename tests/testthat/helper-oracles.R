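# Independent brute-force oracles used against the vectorized implementations,
# plus small fixture builders. The oracles are deliberately written as plain
# per-pixel / per-window loops so they share no code path with the package.

# Criss-cross attention, one round, computed pixel by pixel from the module's
# projection weights: softmax over the H+W-1 cross positions (column keys
# include the pixel itself; row keys exclude it), attention-weighted V
# aggregation plus the residual input.
cca_oracle <- function(m, x) {
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
  qc <- m$qc
  Wq <- matrix(m$children$q$params$w$v, qc, C)
  Wk <- matrix(m$children$k$params$w$v, qc, C)
  Wv <- matrix(m$children$v$params$w$v, C, C)
  out <- array(0, d)
  for (b in seq_len(B)) for (i in seq_len(H)) for (j in seq_len(W)) {
    qu <- Wq %*% x[, i, j, b]
    keys <- rbind(cbind(seq_len(H), j),
                  if (W > 1) cbind(i, setdiff(seq_len(W), j)))
    e <- apply(keys, 1, function(kk) sum(qu * (Wk %*% x[, kk[1], kk[2], b])))
    a <- exp(e - max(e)); a <- a / sum(a)
    agg <- numeric(C)
    for (r in seq_len(nrow(keys))) {
      agg <- agg + a[r] * as.vector(Wv %*% x[, keys[r, 1], keys[r, 2], b])
    }
    out[, i, j, b] <- agg + x[, i, j, b]
  }
  out
}

# Shifted-window attention oracle: explicit roll, per-window double loop over
# query/key token pairs with relative-position bias and region mask.
swin_attention_oracle <- function(m, x) {
  D <- m$d; M <- m$M; K <- M * M; heads <- m$heads; hd <- D %/% heads
  d <- dim(x)
  H <- d[2]; W <- d[3]; B <- d[4]
  s <- m$s
  Wqkv <- m$children$qkv$params$w$v; bqkv <- m$children$qkv$params$b$v
  Wp <- m$children$proj$params$w$v; bp <- m$children$proj$params$b$v
  tab <- m$params$relpos$v
  roll <- function(a, sh, sw) {
    dd <- dim(a)
    ih <- ((seq_len(dd[2]) - 1 - sh) %% dd[2]) + 1
    iw <- ((seq_len(dd[3]) - 1 - sw) %% dd[3]) + 1
    a[, ih, iw, , drop = FALSE]
  }
  xs <- if (s > 0) roll(x, -s, -s) else x
  idmap <- matrix(0, H, W)
  if (s > 0) {
    hs <- list(seq_len(H - M), H - M + seq_len(M - s), H - s + seq_len(s))
    ws <- list(seq_len(W - M), W - M + seq_len(M - s), W - s + seq_len(s))
    cnt <- 0
    for (a in 1:3) for (b in 1:3) {
      if (length(hs[[a]]) && length(ws[[b]])) idmap[hs[[a]], ws[[b]]] <- cnt
      cnt <- cnt + 1
    }
  }
  out <- array(0, d)
  for (bb in seq_len(B)) for (jw in seq_len(W %/% M)) for (iw in seq_len(H %/% M)) {
    ri <- (iw - 1) * M + seq_len(M); rj <- (jw - 1) * M + seq_len(M)
    tok <- matrix(0, D, K); ids <- numeric(K); posm <- matrix(0, K, 2)
    t <- 0
    for (j in rj) for (i in ri) {
      t <- t + 1
      tok[, t] <- xs[, i, j, bb]
      ids[t] <- idmap[i, j]
      posm[t, ] <- c(i - (iw - 1) * M, j - (jw - 1) * M)
    }
    qkv <- Wqkv %*% tok + bqkv
    outw <- matrix(0, D, K)
    for (hh in seq_len(heads)) {
      rows <- (hh - 1) * hd + seq_len(hd)
      Q <- qkv[rows, , drop = FALSE]
      Km <- qkv[D + rows, , drop = FALSE]
      V <- qkv[2 * D + rows, , drop = FALSE]
      for (q in seq_len(K)) {
        e <- numeric(K)
        for (k in seq_len(K)) {
          di <- posm[k, 1] - posm[q, 1] + M - 1
          dj <- posm[k, 2] - posm[q, 2] + M - 1
          e[k] <- sum(Q[, q] * Km[, k]) / sqrt(hd) +
            tab[di * (2 * M - 1) + dj + 1, hh] +
            if (ids[k] == ids[q]) 0 else -1e9
        }
        a <- exp(e - max(e)); a <- a / sum(a)
        outw[rows, q] <- V %*% a
      }
    }
    outw <- Wp %*% outw + bp
    t <- 0
    for (j in rj) for (i in ri) { t <- t + 1; out[, i, j, bb] <- outw[, t] }
  }
  if (s > 0) roll(out, s, s) else out
}

# balanced synthetic beat dataset at a given input side, split 80/20
make_beat_dataset <- function(n_per_class, size = 32L, seed = 11L,
                              scheme = "supervised", split_seed = 7L) {
  g <- gen_ecg_beats(synthetic_ecg_spec(), n_per_class, seed = seed)
  labels <- vapply(g$beats, function(b) b$label, character(1))
  ds <- beats_to_dataset(g$beats, size = size)
  sp <- split_dataset(length(g$beats), scheme, seed = split_seed,
                      stratify_labels = labels)
  list(ds = ds, split = sp, labels = labels)
}

# simple linearly separable two-class toy in beat-image form
make_separable_images <- function(n_per_class, size = 16L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  x <- array(stats::rnorm(3 * size * size * n, sd = 0.05), c(3, size, size, n))
  y <- rep(1:2, each = n_per_class)
  for (i in seq_len(n)) {
    x[, , , i] <- x[, , , i] + if (y[i] == 1) 0.2 else -0.2
  }
  list(x = x, y = y)
}

expect_max_diff <- function(a, b, tol) {
  expect_lt(max(abs(a - b)), tol)
}
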