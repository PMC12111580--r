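# ECG beat pipeline: AAMI five-class labeling, R-peak-centred beat windowing,
# wavelet baseline-wander removal, 60 Hz notch filtering, network-input
# conversion and dataset splitting.

#' The five AAMI beat classes
#' @export
AAMI_CLASSES <- c("N", "SVEB", "VEB", "F", "Q")

# MIT-BIH beat symbol -> AAMI class (EC57 grouping)
AAMI_MAP <- c(
  "N" = "N", "L" = "N", "R" = "N", "e" = "N", "j" = "N",
  "A" = "SVEB", "a" = "SVEB", "J" = "SVEB", "S" = "SVEB", "n" = "SVEB",
  "V" = "VEB", "E" = "VEB",
  "F" = "F",
  "/" = "Q", "f" = "Q", "Q" = "Q"
)

#' Map MIT-BIH annotation symbols to AAMI beat classes
#'
#' Beat symbols are grouped into the five AAMI classes
#' (N, SVEB, VEB, F, Q); non-beat annotations (rhythm changes,
#' artifacts, unknown symbols) map to `"excluded"`.
#' @param symbols character vector of annotation symbols.
#' @return character vector over `c(AAMI_CLASSES, "excluded")`.
#' @export
map_beat_labels <- function(symbols) {
  out <- unname(AAMI_MAP[symbols])
  out[is.na(out)] <- "excluded"
  out
}

#' Extract fixed-length R-peak-centred beats from a record
#'
#' For every annotation whose symbol maps to an AAMI class, the half-open
#' window from 0.5 s before to 0.4 s after the annotated R peak is cut out
#' (324 samples at 360 Hz). Beats whose window would cross the record
#' boundary are dropped and counted.
#' @param rec an `ecg_record` from [read_record()] (optionally denoised).
#' @return list of beat records (`samples`, `label`, `record`, `r_index`),
#'   with attribute `counts` = `(labeled, excluded, dropped_boundary)`.
#' @export
extract_beats <- function(rec) {
  fs <- rec$fs
  pre <- round(0.5 * fs)
  post <- round(0.4 * fs)
  labels <- map_beat_labels(rec$annotations$symbol)
  keep <- labels != "excluded"
  n_excluded <- sum(!keep)
  r <- rec$annotations$sample[keep]
  lab <- labels[keep]
  n <- length(rec$signal)
  inside <- r - pre >= 0 & r + post <= n
  n_dropped <- sum(!inside)
  beats <- vector("list", sum(inside))
  k <- 0L
  for (i in which(inside)) {
    k <- k + 1L
    idx <- (r[i] - pre + 1L):(r[i] + post) # 0-based [r-pre, r+post)
    beats[[k]] <- list(samples = rec$signal[idx], label = lab[i],
                       record = rec$record, r_index = r[i])
  }
  attr(beats, "counts") <- c(labeled = length(r), excluded = n_excluded,
                             dropped_boundary = n_dropped)
  beats
}

# ---- wavelet baseline removal ---------------------------------------------

# Daubechies-6 (12-tap) scaling filter, sum = sqrt(2)
DB6_LO <- c(0.111540743350, 0.494623890398, 0.751133908021, 0.315250351709,
            -0.226264693965, -0.129766867567, 0.097501605587, 0.027522865530,
            -0.031582039318, 0.000553842201, 0.004777257511, -0.001077301085)

qmf_hi <- function(lo) rev(lo) * (-1)^(seq_along(lo) - 1)

dwt_step <- function(x, lo) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(lo)
  hi <- qmf_hi(lo)
  half <- n %/% 2
  a <- numeric(half); d <- numeric(half)
  base <- 2 * (seq_len(half) - 1)
  for (tap in seq_len(L)) {
    idx <- ((base + tap - 1) %% n) + 1
    a <- a + lo[tap] * x[idx]
    d <- d + hi[tap] * x[idx]
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, lo, n) {
  L <- length(lo)
  hi <- qmf_hi(lo)
  x <- numeric(n)
  base <- 2 * (seq_along(a) - 1)
  for (tap in seq_len(L)) {
    idx <- ((base + tap - 1) %% n) + 1
    x[idx] <- x[idx] + lo[tap] * a + hi[tap] * d
  }
  x
}

# periodized multilevel DWT; pads odd lengths by edge replication
dwt_multilevel <- function(x, level) {
  n0 <- length(x)
  details <- list()
  lens <- integer(0)
  for (l in seq_len(level)) {
    if (length(x) %% 2 == 1) x <- c(x, x[length(x)])
    lens <- c(lens, length(x))
    st <- dwt_step(x, DB6_LO)
    details[[l]] <- st$d
    x <- st$a
  }
  list(a = x, d = details, lens = lens, n0 = n0)
}

idwt_multilevel <- function(dec) {
  a <- dec$a
  for (l in rev(seq_along(dec$d))) {
    a <- a[seq_along(dec$d[[l]])] # drop padding introduced at odd lengths
    a <- idwt_step(a, dec$d[[l]], DB6_LO, dec$lens[l])
  }
  a[seq_len(dec$n0)]
}

# Slope-continuous signal extension for drift estimation: the line through
# the endpoints extends linearly, and the residual (which is zero at both
# endpoints) extends by odd reflection with period 2(n-1). Both value and
# first derivative are continuous at the joins, so the lowpass baseline
# estimate carries no edge kink. Linear in x.
sym_extend <- function(x, pad) {
  n <- length(x)
  if (n < 2) return(rep(x, 1L + 2L * pad))
  t <- seq.int(-pad, n - 1L + pad)              # 0-based positions
  slope <- (x[n] - x[1]) / (n - 1)
  line <- x[1] + slope * t
  r <- x - (x[1] + slope * (seq_len(n) - 1L))
  p <- 2L * (n - 1L)
  m <- ((t %% p) + p) %% p
  inside <- m <= (n - 1L)
  idx <- ifelse(inside, m, p - m) + 1L
  line + ifelse(inside, r[idx], -r[idx])
}

# one level of the undecimated (a trous) approximation cascade: zero-phase
# convolution with the symmetrized Daubechies-6 scaling kernel whose taps are
# spaced 2^(l-1) samples apart; x is already symmetric-extended
atrous_smooth <- function(x, spacing) {
  h1 <- DB6_LO / sqrt(2)                       # lowpass, sum 1
  g <- stats::convolve(h1, h1, type = "open")  # symmetric, zero phase
  half <- (length(g) - 1L) %/% 2L
  n <- length(x)
  out <- numeric(n)
  for (j in seq_along(g)) {
    off <- (j - 1L - half) * spacing
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    out <- out + g[j] * x[idx]
  }
  out
}

#' Remove baseline wander with an undecimated wavelet approximation
#'
#' Estimates the baseline as the coarse approximation of a stationary
#' (undecimated, a trous) Daubechies-6 cascade of the given depth -- a
#' zero-phase lowpass whose pass band at 360 Hz and depth 8 lies below about
#' 0.7 Hz -- and subtracts it ("zeroing the coarsest approximation"). The
#' undecimated transform is shift-invariant, so pure drift tones are removed
#' without aliasing residue and R-peak locations are untouched. The depth is
#' reduced (with a message) for signals shorter than the kernel support.
#' @param signal numeric vector (mV).
#' @param level cascade depth (default 8: approximation band 0 to
#'   `fs / 2^9` Hz at 360 Hz).
#' @param passes number of applications of the drift-removal operator; the
#'   operator is linear and time-invariant, so each pass squares the residual
#'   drift gain while leaving the cardiac pass band essentially unchanged.
#' @return baseline-corrected signal of the same length.
#' @export
remove_baseline <- function(signal, level = 8L, passes = 2L) {
  n <- length(signal)
  if (n < length(DB6_LO)) {
    message("remove_baseline: signal shorter than the wavelet support; ",
            "returning it unchanged")
    return(signal)
  }
  max_level <- max(1L, floor(log2(n)))
  if (level > max_level) {
    message("remove_baseline: reducing level from ", level, " to ", max_level,
            " for signal of length ", n)
    level <- max_level
  }
  pad <- min(length(DB6_LO) * 2L^level + 64L, 20L * n)
  out <- signal
  for (p in seq_len(passes)) {
    base <- sym_extend(out, pad)
    for (l in seq_len(level)) base <- atrous_smooth(base, 2L^(l - 1L))
    out <- out - base[pad + seq_len(n)]
  }
  out
}

# ---- powerline notch -------------------------------------------------------

#' Remove powerline interference with a 60 Hz notch
#'
#' Zero-phase (forward-backward) application of a second-order IIR notch
#' (quality factor 30) centred at 60 Hz, followed by a light centred
#' moving-average smoothing with reflected edges. Zero phase keeps R-peak
#' locations intact.
#' @param signal numeric vector.
#' @param fs sampling frequency in Hz (> 120 so the notch is below Nyquist).
#' @param f0 notch centre frequency.
#' @param Q notch quality factor.
#' @param smooth_width moving-average width in samples (odd; 1 disables).
#' @return filtered signal of the same length.
#' @export
remove_powerline <- function(signal, fs, f0 = 60, Q = 30, smooth_width = 5L) {
  stopifnot(fs > 2 * f0)
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  y <- signal::filtfilt(signal::Arma(b = b, a = a), signal)
  if (smooth_width > 1) {
    k <- smooth_width %/% 2L
    padded <- c(rev(y[seq_len(k)]), y, rev(y[length(y) - seq_len(k) + 1L]))
    sm <- stats::filter(padded, rep(1 / smooth_width, smooth_width), sides = 2)
    y <- as.numeric(sm[(k + 1):(k + length(y))])
  }
  y
}

#' Denoise a record in place
#'
#' Baseline-wander removal followed by the powerline notch.
#' @param rec an `ecg_record`.
#' @param level wavelet depth for [remove_baseline()].
#' @return the record with `signal` replaced by its denoised version.
#' @export
denoise_record <- function(rec, level = 9L) {
  rec$signal <- remove_powerline(remove_baseline(rec$signal, level), rec$fs)
  rec
}

# ---- network input ---------------------------------------------------------

#' Convert a beat to a network input tensor
#'
#' Linearly resamples the beat to `size` points, min-max normalizes to [0, 1]
#' (constant beats map to 0.5), tiles the row `size` times (time along the
#' width axis) and replicates across 3 channels.
#' @param beat a beat record (or bare numeric vector of samples).
#' @param size output side length (224 matches the full-scale training setup).
#' @return array of shape `(3, size, size)` with values in [0, 1].
#' @export
beat_to_input <- function(beat, size = 224L) {
  v <- if (is.list(beat)) beat$samples else beat
  r <- stats::approx(seq_along(v), v, n = size)$y
  rng <- range(r)
  r <- if (rng[2] > rng[1]) (r - rng[1]) / (rng[2] - rng[1]) else rep(0.5, size)
  row_tiled <- matrix(r, nrow = size, ncol = size, byrow = TRUE)
  out <- array(0, c(3L, size, size))
  for (c in 1:3) out[c, , ] <- row_tiled
  out
}

#' Stack beats into a batched input array
#' @param beats list of beat records.
#' @param size input side length.
#' @return list with `x` `(3, size, size, N)` and integer labels `y` (indices
#'   into [AAMI_CLASSES]).
#' @export
beats_to_dataset <- function(beats, size = 224L) {
  n <- length(beats)
  x <- array(0, c(3L, size, size, n))
  for (i in seq_len(n)) x[, , , i] <- beat_to_input(beats[[i]], size)
  y <- match(vapply(beats, function(b) b$label, character(1)), AAMI_CLASSES)
  list(x = x, y = y)
}

# ---- splits ----------------------------------------------------------------

# largest-remainder allocation of n into parts proportional to p
alloc_sizes <- function(n, p) {
  raw <- n * p
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Stratified dataset split
#'
#' Partitions item indices into the supervised 80/20 train/test split or the
#' semi-supervised 50/40/10 labeled/unlabeled/validation split, stratified by
#' class and deterministic under the seed.
#' @param n_items number of items.
#' @param scheme `"supervised"` (80/20) or `"ssl"` (50/40/10).
#' @param seed RNG seed recorded in the result.
#' @param stratify_labels optional per-item labels for stratification.
#' @return a `dataset_split` list of index vectors (`train`, `test` or
#'   `labeled`, `unlabeled`, `validation`) plus `scheme` and `seed`.
#' @export
split_dataset <- function(n_items, scheme = c("supervised", "ssl"),
                          seed = 42L, stratify_labels = NULL) {
  scheme <- match.arg(scheme)
  p <- if (scheme == "supervised") c(0.8, 0.2) else c(0.5, 0.4, 0.1)
  parts <- if (scheme == "supervised") c("train", "test")
  else c("labeled", "unlabeled", "validation")
  if (n_items < length(p)) stop("need at least ", length(p), " items")
  if (is.null(stratify_labels)) stratify_labels <- rep("all", n_items)
  stopifnot(length(stratify_labels) == n_items)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  buckets <- vector("list", length(p))
  for (cl in unique(stratify_labels)) {
    idx <- sample(which(stratify_labels == cl))
    if (length(idx) < length(p)) {
      warning("class '", cl, "' has fewer items (", length(idx),
              ") than partitions; stratification degraded")
    }
    sizes <- alloc_sizes(length(idx), p)
    off <- 0L
    for (k in seq_along(p)) {
      buckets[[k]] <- c(buckets[[k]], idx[off + seq_len(sizes[k])])
      off <- off + sizes[k]
    }
  }
  out <- lapply(buckets, sort)
  names(out) <- parts
  out$scheme <- scheme
  out$seed <- seed
  class(out) <- "dataset_split"
  out
}

# ---- dataset export --------------------------------------------------------

#' Preprocess a directory of WFDB records into a beat dataset
#'
#' Reads every record (`*.hea`) in `records_dir`, denoises the chosen lead,
#' extracts labeled beats, splits them and writes `beats.rds` (the beat list)
#' plus `manifest.csv` (record id, R index, label, split) and `meta.json`
#' into `out_dir`.
#' @param records_dir directory of WFDB records.
#' @param out_dir output directory (created if needed).
#' @param scheme split scheme, see [split_dataset()].
#' @param seed split seed.
#' @param lead lead name to read.
#' @return invisibly, a list with `beats`, `split` and the per-record counts.
#' @export
preprocess_records <- function(records_dir, out_dir,
                               scheme = c("supervised", "ssl"),
                               seed = 42L, lead = "MLII") {
  scheme <- match.arg(scheme)
  heas <- sort(list.files(records_dir, pattern = "\\.hea$", full.names = TRUE))
  if (!length(heas)) stop("no WFDB records (*.hea) found in ", records_dir)
  beats <- list()
  counts <- list()
  for (h in heas) {
    rec <- read_record(sub("\\.hea$", "", h), lead = lead)
    rec <- denoise_record(rec)
    b <- extract_beats(rec)
    counts[[rec$record]] <- attr(b, "counts")
    beats <- c(beats, b)
  }
  labels <- vapply(beats, function(b) b$label, character(1))
  split <- split_dataset(length(beats), scheme, seed, labels)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(beats, file.path(out_dir, "beats.rds"))
  part <- rep(NA_character_, length(beats))
  for (nm in setdiff(names(split), c("scheme", "seed"))) part[split[[nm]]] <- nm
  manifest <- data.frame(
    record = vapply(beats, function(b) b$record, character(1)),
    r_index = vapply(beats, function(b) b$r_index, numeric(1)),
    label = labels, split = part)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(scheme = scheme, seed = seed,
                            n_beats = length(beats), counts = counts),
                       file.path(out_dir, "meta.json"), auto_unbox = TRUE)
  invisible(list(beats = beats, split = split, counts = counts))
}
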