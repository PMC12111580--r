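# Deterministic synthetic data generators: five-class ECG beats built from
# sums of Gaussian bumps with class-dependent morphology, plus oriented-
# texture images, so the full pipeline is testable without downloading data.
#
# The ECG classes encode clinically *suggestive* differences only as parameter
# choices (widened high-amplitude R without P wave for the VEB-like class,
# absent P for the SVEB-like class, pacing spike plus wide complex for the
# Q/paced-like class); no claim of physiological realism is made. Every beat
# is corrupted with additive baseline drift (a slow sinusoid), 60 Hz powerline
# interference and white noise, and returned together with its clean version
# so denoising is measurable.

# per-class morphology: list of Gaussian components (amp mV, center s
# relative to the R peak, width s)
ecg_class_morphology <- function() {
  list(
    N = list(c(0.15, -0.17, 0.020), c(-0.10, -0.030, 0.008),
             c(1.00, 0.000, 0.012), c(-0.20, 0.030, 0.008),
             c(0.30, 0.150, 0.040)),
    SVEB = list(c(-0.05, -0.10, 0.015), c(0.90, 0.000, 0.011),
                c(-0.25, 0.028, 0.008), c(0.22, 0.120, 0.030)),
    VEB = list(c(1.40, 0.010, 0.045), c(-0.45, 0.120, 0.050),
               c(-0.15, -0.060, 0.025)),
    F = list(c(0.08, -0.15, 0.020), c(0.85, 0.005, 0.028),
             c(0.15, 0.140, 0.045)),
    Q = list(c(1.20, -0.015, 0.005), c(0.80, 0.025, 0.035),
             c(-0.10, 0.150, 0.050))
  )
}

#' Specification of the synthetic ECG generator
#'
#' @param fs sampling rate (Hz).
#' @param beat_len beat length in samples (`round(0.9 * fs)`).
#' @param wander_amp,wander_freq baseline-wander amplitude (mV) and
#'   frequency (Hz).
#' @param powerline_amp 60 Hz interference amplitude (mV).
#' @param noise_sd white-noise standard deviation (mV).
#' @param amp_jitter_sd per-beat multiplicative amplitude jitter.
#' @return a `synthetic_ecg_spec` list (5 classes, fixed morphologies).
#' @export
synthetic_ecg_spec <- function(fs = 360, beat_len = round(0.9 * fs),
                               wander_amp = 0.15, wander_freq = 0.25,
                               powerline_amp = 0.05, noise_sd = 0.03,
                               amp_jitter_sd = 0.05) {
  structure(list(fs = fs, beat_len = as.integer(beat_len),
                 classes = AAMI_CLASSES,
                 morphology = ecg_class_morphology(),
                 wander_amp = wander_amp, wander_freq = wander_freq,
                 powerline_amp = powerline_amp, noise_sd = noise_sd,
                 amp_jitter_sd = amp_jitter_sd),
            class = "synthetic_ecg_spec")
}

gaussian_sum <- function(t, comps, amp_scale = 1) {
  v <- numeric(length(t))
  for (g in comps) v <- v + amp_scale * g[1] * exp(-((t - g[2])^2) / (2 * g[3]^2))
  v
}

#' Generate labeled synthetic ECG beats
#'
#' Each beat is a class-specific Gaussian-mixture waveform centred 0.5 s into
#' the window, plus baseline sinusoid, 60 Hz sinusoid and white noise; class
#' sizes are balanced. A pure function of `(spec, seed)`.
#' @param spec a [synthetic_ecg_spec()].
#' @param n_per_class beats per class.
#' @param seed RNG seed.
#' @return list with `beats` (noisy beat records) and `clean` (noise-free
#'   copies, same order).
#' @export
gen_ecg_beats <- function(spec, n_per_class, seed = 42L) {
  stopifnot(inherits(spec, "synthetic_ecg_spec"), n_per_class >= 1)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  fs <- spec$fs
  L <- spec$beat_len
  pre <- round(0.5 * fs)
  t <- (seq_len(L) - 1 - pre) / fs  # seconds relative to the R peak
  beats <- list(); clean <- list()
  k <- 0L
  for (cl in spec$classes) {
    comps <- spec$morphology[[cl]]
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      amp <- 1 + stats::rnorm(1, sd = spec$amp_jitter_sd)
      pure <- gaussian_sum(t, comps, amp)
      wander <- spec$wander_amp *
        sin(2 * pi * spec$wander_freq * (t + 0.5) + stats::runif(1, 0, 2 * pi))
      powerline <- spec$powerline_amp *
        sin(2 * pi * 60 * (t + 0.5) + stats::runif(1, 0, 2 * pi))
      noise <- stats::rnorm(L, sd = spec$noise_sd)
      beats[[k]] <- list(samples = pure + wander + powerline + noise,
                         label = cl, record = "synth", r_index = pre)
      clean[[k]] <- list(samples = pure, label = cl, record = "synth",
                         r_index = pre)
    }
  }
  list(beats = beats, clean = clean)
}

#' Write a synthetic WFDB fixture record
#'
#' Concatenates synthetic beats at a regular 1 s spacing into a two-lead
#' record (lead `MLII` plus a scaled `V5` copy), annotates the R peaks with
#' the MIT symbols of their classes, and writes the WFDB triplet; the record
#' round-trips through [read_record()] and [extract_beats()].
#' @param spec a [synthetic_ecg_spec()].
#' @param n_beats number of beats.
#' @param dir output directory.
#' @param name record name.
#' @param seed RNG seed.
#' @return the record path (without extension).
#' @export
gen_wfdb_fixture <- function(spec, n_beats, dir, name = "synth01", seed = 42L) {
  gen <- gen_ecg_beats(spec, ceiling(n_beats / length(spec$classes)), seed)
  beats <- gen$beats[seq_len(n_beats)]
  fs <- spec$fs
  rr <- fs                         # 1 s beat spacing >= window length
  pre <- round(0.5 * fs)
  n <- rr * (n_beats + 1L)
  sig <- numeric(n)
  r_at <- integer(n_beats)
  for (i in seq_len(n_beats)) {
    start <- (i - 1L) * rr + (rr - pre) # leaves a full pre-window
    sig[start + seq_len(spec$beat_len)] <- beats[[i]]$samples
    r_at[i] <- start + pre         # 0-based R-peak index
  }
  class_to_symbol <- c(N = "N", SVEB = "A", VEB = "V", F = "F", Q = "/")
  ann <- data.frame(
    sample = r_at,
    symbol = unname(class_to_symbol[vapply(beats, function(b) b$label, character(1))]))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_wfdb(dir, name, cbind(sig, 0.6 * sig), fs,
             leads = c("MLII", "V5"), annotations = ann)
}

# ---- synthetic images ------------------------------------------------------

#' Specification of the synthetic texture-image generator
#'
#' Class k is an oriented sinusoidal grating (class-specific frequency and
#' angle) with superimposed random blobs at a class-specific density.
#' @param classes number of classes (>= 2).
#' @param size image side in pixels.
#' @param noise_sd additive pixel noise.
#' @return a `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(classes = 7L, size = 224L, noise_sd = 0.05) {
  stopifnot(classes >= 2)
  k <- seq_len(classes)
  structure(list(classes = classes, size = as.integer(size),
                 freq = 2 + 3 * (k - 1),              # cycles per image
                 angle = pi * (k - 1) / classes,
                 blob_density = (k - 1) / (classes - 1) * 8,
                 noise_sd = noise_sd),
            class = "synthetic_image_spec")
}

synth_image <- function(spec, class_id) {
  s <- spec$size
  gx <- matrix(rep(seq(0, 1, length.out = s), each = s), s, s)
  gy <- t(gx)
  a <- spec$angle[class_id]
  u <- cos(a) * gx + sin(a) * gy
  img <- 0.5 + 0.35 * sin(2 * pi * spec$freq[class_id] * u)
  nb <- stats::rpois(1, spec$blob_density)
  if (nb > 0) {
    for (b in seq_len(nb)) {
      cx <- stats::runif(1); cy <- stats::runif(1); r <- stats::runif(1, 0.02, 0.08)
      img <- img + 0.3 * exp(-((gx - cx)^2 + (gy - cy)^2) / (2 * r^2))
    }
  }
  img <- img + matrix(stats::rnorm(s * s, sd = spec$noise_sd), s, s)
  pmin(pmax(img, 0), 1)
}

#' Generate a class-per-directory synthetic image dataset
#'
#' Writes `n_per_class` RGB PNG images per class under
#' `dir/class_<k>/img_<i>.png`; deterministic under the seed.
#' @param spec a [synthetic_image_spec()].
#' @param n_per_class images per class.
#' @param dir output directory.
#' @param seed RNG seed.
#' @return invisibly, the vector of written file paths.
#' @export
gen_image_dataset <- function(spec, n_per_class, dir, seed = 42L) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  paths <- character(0)
  for (k in seq_len(spec$classes)) {
    cdir <- file.path(dir, sprintf("class_%d", k))
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n_per_class)) {
      img <- synth_image(spec, k)
      rgb <- array(0, c(spec$size, spec$size, 3))
      # class-tinted channels keep the texture dominant but add colour cues
      rgb[, , 1] <- img
      rgb[, , 2] <- pmin(pmax(img * (0.6 + 0.4 * k / spec$classes), 0), 1)
      rgb[, , 3] <- pmin(pmax(1 - img * (0.4 + 0.3 * k / spec$classes), 0), 1)
      p <- file.path(cdir, sprintf("img_%03d.png", i))
      png::writePNG(rgb, p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}

#' Read a class-per-directory image folder into a batched array
#' @param dir dataset root (one subdirectory per class).
#' @param size images are bilinearly resized to `size` x `size`.
#' @return list with `x` `(3, size, size, N)`, integer labels `y`, and
#'   `class_names`.
#' @export
read_image_dataset <- function(dir, size = 224L) {
  classes <- sort(list.dirs(dir, recursive = FALSE))
  if (!length(classes)) stop("no class directories under ", dir)
  xs <- list(); ys <- integer(0)
  for (k in seq_along(classes)) {
    files <- sort(list.files(classes[k], pattern = "\\.png$", full.names = TRUE))
    for (f in files) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
      a <- aperm(img[, , 1:3, drop = FALSE], c(3, 1, 2)) # (3, H, W)
      node <- ag_tensor(array(a, c(dim(a), 1)))
      if (dim(a)[2] != size || dim(a)[3] != size) {
        node <- ag_interp2(node, size, size)
      }
      xs[[length(xs) + 1L]] <- vl(node)
      ys <- c(ys, k)
    }
  }
  x <- array(0, c(3L, size, size, length(xs)))
  for (i in seq_along(xs)) x[, , , i] <- xs[[i]]
  list(x = x, y = ys, class_names = basename(classes))
}
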