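# Minimal WFDB (PhysioNet) record I/O: header (.hea), signal (.dat, formats
# 16 and 212) and MIT annotation (.atr) files. Covers the subset of the
# format used by ambulatory ECG databases: multiplexed signals with per-signal
# gain/baseline, and annotation streams of (time delta, type code) words with
# SKIP/NUM/SUB/CHN/AUX escapes.

# MIT annotation type codes <-> symbols (the standard code table)
MIT_ANN_CODES <- c(
  "N" = 1L, "L" = 2L, "R" = 3L, "a" = 4L, "V" = 5L, "F" = 6L, "J" = 7L,
  "A" = 8L, "S" = 9L, "E" = 10L, "j" = 11L, "/" = 12L, "Q" = 13L, "~" = 14L,
  "|" = 16L, "s" = 18L, "T" = 19L, "*" = 20L, "D" = 21L, "\"" = 22L,
  "=" = 23L, "p" = 24L, "B" = 25L, "^" = 26L, "t" = 27L, "+" = 28L,
  "u" = 29L, "?" = 30L, "!" = 31L, "x" = 32L, "(" = 33L, ")" = 34L,
  "e" = 35L, "n" = 36L, "r" = 37L, "f" = 38L
)

mit_code_to_symbol <- function(code) {
  sym <- names(MIT_ANN_CODES)[match(code, MIT_ANN_CODES)]
  sym[is.na(sym)] <- "?"
  sym
}

#' Write a WFDB record
#'
#' Writes the `.hea`/`.dat`(/`.atr`) triplet for a multi-lead record, signal
#' format 16 (16-bit little-endian two's complement, sample-interleaved).
#' @param dir output directory.
#' @param name record name (file stem).
#' @param signals numeric matrix, samples x leads, in physical units (mV).
#' @param fs sampling frequency in Hz.
#' @param leads character vector of lead names, one per column.
#' @param gain ADC units per mV.
#' @param annotations optional data frame with columns `sample` (0-based
#'   indices, strictly increasing) and `symbol`.
#' @return the record path (without extension), invisibly.
#' @export
write_wfdb <- function(dir, name, signals, fs, leads,
                       gain = 200, annotations = NULL) {
  signals <- as.matrix(signals)
  nsig <- ncol(signals)
  nsamp <- nrow(signals)
  stopifnot(length(leads) == nsig)
  adc <- round(signals * gain)
  adc[adc > 32767] <- 32767
  adc[adc < -32768] <- -32768
  hea <- file.path(dir, paste0(name, ".hea"))
  lines <- sprintf("%s %d %g %d", name, nsig, fs, nsamp)
  for (s in seq_len(nsig)) {
    lines <- c(lines, sprintf("%s.dat 16 %g 16 0 %d 0 0 %s",
                              name, gain, as.integer(adc[1, s]), leads[s]))
  }
  writeLines(lines, hea)
  con <- file(file.path(dir, paste0(name, ".dat")), "wb")
  writeBin(as.integer(t(adc)), con, size = 2L, endian = "little")
  close(con)
  if (!is.null(annotations) && nrow(annotations) > 0) {
    write_mit_annotations(file.path(dir, paste0(name, ".atr")), annotations)
  }
  invisible(file.path(dir, name))
}

write_mit_annotations <- function(path, ann) {
  stopifnot(all(diff(ann$sample) > 0))
  codes <- MIT_ANN_CODES[as.character(ann$symbol)]
  if (anyNA(codes)) stop("unknown annotation symbol(s): ",
                         paste(unique(ann$symbol[is.na(codes)]), collapse = ", "))
  words <- integer(0)
  prev <- 0
  for (i in seq_along(codes)) {
    delta <- ann$sample[i] - prev
    prev <- ann$sample[i]
    if (delta >= 1024) {
      # SKIP escape: code 59 with zero delta, then the 32-bit interval
      # (high 16 bits first), then the annotation word with zero delta
      words <- c(words, bitwShiftL(59L, 10L),
                 bitwAnd(bitwShiftR(delta, 16L), 0xFFFFL),
                 bitwAnd(delta, 0xFFFFL),
                 bitwShiftL(codes[i], 10L))
    } else {
      words <- c(words, bitwOr(bitwShiftL(codes[i], 10L), delta))
    }
  }
  words <- c(words, 0L) # terminator
  words[words > 32767L] <- words[words > 32767L] - 65536L # to signed int16
  con <- file(path, "wb")
  writeBin(as.integer(words), con, size = 2L, endian = "little")
  close(con)
}

read_mit_annotations <- function(path) {
  raw <- readBin(path, "integer", n = file.size(path) %/% 2L,
                 size = 2L, signed = FALSE, endian = "little")
  samples <- integer(0); symbols <- character(0)
  t <- 0; i <- 1L
  while (i <= length(raw)) {
    w <- raw[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == 59L) {       # SKIP: 32-bit interval follows
      hi <- raw[i + 1L]; lo <- raw[i + 2L]
      t <- t + hi * 65536 + lo
      i <- i + 3L
      next
    } else if (code == 63L) { # AUX: skip payload (padded to even length)
      i <- i + 1L + (delta + delta %% 2L) %/% 2L
      next
    } else if (code %in% c(60L, 61L, 62L)) { # NUM/SUB/CHN: no time
      i <- i + 1L
      next
    }
    t <- t + delta
    samples <- c(samples, t)
    symbols <- c(symbols, mit_code_to_symbol(code))
    i <- i + 1L
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

parse_hea <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  head_f <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  nsig <- as.integer(head_f[2])
  fs <- if (length(head_f) >= 3) as.numeric(sub("/.*", "", head_f[3])) else 250
  nsamp <- if (length(head_f) >= 4) as.numeric(head_f[4]) else NA
  sig <- lapply(seq_len(nsig), function(s) {
    f <- strsplit(trimws(lines[1 + s]), "\\s+")[[1]]
    fmt <- as.integer(sub("x.*|:.*|\\+.*", "", f[2]))
    gain <- if (length(f) >= 3) as.numeric(sub("\\(.*", "", sub("/.*", "", f[3]))) else 200
    if (is.na(gain) || gain == 0) gain <- 200
    baseline <- 0
    if (length(f) >= 3 && grepl("\\(", f[3])) {
      baseline <- as.numeric(sub(".*\\(([-0-9]+)\\).*", "\\1", f[3]))
    }
    desc <- if (length(f) >= 9) paste(f[9:length(f)], collapse = " ") else paste0("sig", s)
    list(file = f[1], fmt = fmt, gain = gain, baseline = baseline, desc = desc)
  })
  list(name = head_f[1], nsig = nsig, fs = fs, nsamp = nsamp, signals = sig)
}

read_dat_samples <- function(path, fmt, nsig) {
  if (fmt == 16L) {
    v <- readBin(path, "integer", n = file.size(path) %/% 2L,
                 size = 2L, signed = TRUE, endian = "little")
    matrix(v, ncol = nsig, byrow = TRUE)
  } else if (fmt == 212L) {
    b <- as.integer(readBin(path, "raw", n = file.size(path)))
    n3 <- (length(b) %/% 3L) * 3L
    b <- b[seq_len(n3)]
    b1 <- b[seq(1, n3, 3)]; b2 <- b[seq(2, n3, 3)]; b3 <- b[seq(3, n3, 3)]
    s1 <- b1 + bitwShiftL(bitwAnd(b2, 0x0FL), 8L)
    s2 <- b3 + bitwShiftL(bitwAnd(bitwShiftR(b2, 4L), 0x0FL), 8L)
    s1 <- ifelse(s1 > 2047L, s1 - 4096L, s1)
    s2 <- ifelse(s2 > 2047L, s2 - 4096L, s2)
    v <- as.vector(rbind(s1, s2))
    matrix(v[seq_len((length(v) %/% nsig) * nsig)], ncol = nsig, byrow = TRUE)
  } else {
    stop("unsupported WFDB signal format: ", fmt)
  }
}

#' Read one lead of a WFDB record with its beat annotations
#'
#' @param path record path without extension (e.g. `"data/100"`); the `.hea`,
#'   `.dat` and (if present) `.atr` files are read from there.
#' @param lead lead (signal description) to extract, e.g. `"MLII"`.
#' @return an `ecg_record` list: `signal` (mV), `lead`, `fs`,
#'   `annotations` (data frame of 0-based `sample` and `symbol`), `record`.
#' @export
read_record <- function(path, lead = "MLII") {
  hea_path <- paste0(path, ".hea")
  if (!file.exists(hea_path)) stop("header not found: ", hea_path)
  h <- parse_hea(hea_path)
  descs <- vapply(h$signals, function(s) s$desc, character(1))
  idx <- match(lead, descs)
  if (is.na(idx)) {
    stop("lead '", lead, "' not present in record ", h$name,
         "; available leads: ", paste(descs, collapse = ", "))
  }
  fmts <- unique(vapply(h$signals, function(s) s$fmt, integer(1)))
  if (length(fmts) != 1) stop("mixed-format records are not supported")
  adc <- read_dat_samples(paste0(path, ".dat"), fmts, h$nsig)
  s <- h$signals[[idx]]
  sigv <- (adc[, idx] - s$baseline) / s$gain
  atr_path <- paste0(path, ".atr")
  ann <- if (file.exists(atr_path)) read_mit_annotations(atr_path)
  else data.frame(sample = integer(0), symbol = character(0))
  if (nrow(ann) > 1 && any(diff(ann$sample) <= 0)) {
    stop("annotation sample indices are not strictly increasing in ", atr_path)
  }
  if (nrow(ann) > 0 && (min(ann$sample) < 0 || max(ann$sample) >= length(sigv))) {
    stop("annotation indices outside signal bounds in ", atr_path)
  }
  structure(list(signal = sigv, lead = lead, fs = h$fs,
                 annotations = ann, record = h$name),
            class = "ecg_record")
}
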