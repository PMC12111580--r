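test_that("WFDB fixtures round-trip through the reader with lead selection and ordered annotations", {
  d <- withr::local_tempdir()
  spec <- synthetic_ecg_spec()
  p <- gen_wfdb_fixture(spec, 20, d, seed = 3)
  rec <- read_record(p, "MLII")
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$fs, 360)
  expect_equal(nrow(rec$annotations), 20)
  expect_true(all(diff(rec$annotations$sample) >= 324))
  v5 <- read_record(p, "V5")
  expect_lt(max(abs(v5$signal - 0.6 * rec$signal)), 0.02) # ADC quantization
  expect_error(read_record(p, "V1"), "available leads: MLII, V5")
  expect_error(read_record(file.path(d, "nosuch")), "header not found")
})

test_that("annotation symbols map onto the AAMI classes with non-beat codes excluded", {
  expect_equal(map_beat_labels("N"), "N")
  expect_equal(map_beat_labels(c("L", "R", "e", "j")), rep("N", 4))
  expect_equal(map_beat_labels(c("A", "a", "J", "S")), rep("SVEB", 4))
  expect_equal(map_beat_labels(c("V", "E")), rep("VEB", 2))
  expect_equal(map_beat_labels("F"), "F")
  expect_equal(map_beat_labels(c("/", "f", "Q")), rep("Q", 3))
  expect_equal(map_beat_labels(c("+", "~", "|", "zz")), rep("excluded", 4))
})

test_that("beat extraction windows are 324 samples with boundary drops counted", {
  fs <- 360
  sig <- stats::rnorm(fs * 10)
  ann <- data.frame(sample = c(100L, 1000L, 2000L, 3000L),
                    symbol = c("N", "V", "+", "A"))
  rec <- structure(list(signal = sig, lead = "MLII", fs = fs,
                        annotations = ann, record = "toy"),
                   class = "ecg_record")
  beats <- extract_beats(rec)
  counts <- attr(beats, "counts")
  # beat at 100 < 180 is dropped; '+' is excluded; 1000 and 3500 survive
  expect_equal(length(beats), 2)
  expect_equal(unname(counts["labeled"]), 3)
  expect_equal(unname(counts["excluded"]), 1)
  expect_equal(unname(counts["dropped_boundary"]), 1)
  expect_true(all(vapply(beats, function(b) length(b$samples), numeric(1)) == 324))
  # half-open window [r-180, r+144): 0-based sample r-180 is the first entry
  expect_equal(beats[[1]]$samples, sig[(1000 - 180 + 1):(1000 + 144)])
  expect_equal(beats[[1]]$label, "VEB")
})

test_that("baseline removal strongly attenuates slow drift and is linear", {
  fs <- 360
  tt <- seq(0, 10, by = 1 / fs)
  drift <- sin(2 * pi * 0.2 * tt)
  expect_gte(1 - max(abs(remove_baseline(drift))), 0.90)
  expect_equal(remove_baseline(numeric(324)), numeric(324))
  expect_equal(length(suppressMessages(remove_baseline(stats::rnorm(324)))), 324)
  expect_equal(length(remove_baseline(stats::rnorm(20000))), 20000)
  set.seed(50)
  a <- stats::rnorm(2000); b <- stats::rnorm(2000)
  expect_max_diff(remove_baseline(a + 2 * b),
                  remove_baseline(a) + 2 * remove_baseline(b), 1e-9)
})

test_that("the 60 Hz notch removes powerline tones but passes cardiac-band content", {
  fs <- 360
  tt <- seq(0, 10, by = 1 / fs)
  core <- 500:3100
  tone60 <- sin(2 * pi * 60 * tt)
  r60 <- remove_powerline(tone60, fs)
  expect_lte(max(abs(r60[core])), 0.10)            # >= 20 dB attenuation
  tone5 <- sin(2 * pi * 5 * tt)
  r5 <- remove_powerline(tone5, fs)
  ratio5 <- max(abs(r5[core])) / 1
  expect_gt(ratio5, 10^(-1 / 20))                  # < 1 dB change
  expect_lt(ratio5, 10^(1 / 20))
  expect_equal(remove_powerline(numeric(500), fs), numeric(500))
})

test_that("beats convert to normalized tiled network inputs", {
  b <- list(samples = stats::rnorm(324), label = "N", record = "x", r_index = 180)
  out <- beat_to_input(b)
  expect_equal(dim(out), c(3, 224, 224))
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(max(out), 1)
  expect_equal(min(out), 0)
  # all rows and channels carry the same trace
  expect_identical(out[1, 1, ], out[3, 117, ])
  const <- beat_to_input(list(samples = rep(2, 324)), size = 16)
  expect_true(all(const == 0.5))
  ramp <- beat_to_input(list(samples = seq_len(324)), size = 8)
  expect_equal(ramp[1, 5, ], seq(0, 1, length.out = 8), tolerance = 1e-9)
})

test_that("dataset splits hit the stated ratios, are disjoint and seed-stable", {
  s <- split_dataset(100, "supervised", seed = 9)
  expect_equal(length(s$train), 80)
  expect_equal(length(s$test), 20)
  labs <- rep(AAMI_CLASSES, each = 20)
  s2 <- split_dataset(100, "ssl", seed = 9, stratify_labels = labs)
  expect_equal(vapply(s2[c("labeled", "unlabeled", "validation")], length,
                      numeric(1)),
               c(labeled = 50, unlabeled = 40, validation = 10))
  # stratification: each class contributes proportionally
  for (cl in AAMI_CLASSES) {
    expect_equal(sum(labs[s2$labeled] == cl), 10)
  }
  expect_identical(split_dataset(100, "ssl", seed = 9, stratify_labels = labs)[1:3],
                   s2[1:3])
  all_idx <- c(s2$labeled, s2$unlabeled, s2$validation)
  expect_equal(sort(all_idx), 1:100)
  expect_warning(split_dataset(5, "ssl", seed = 1, stratify_labels = c(1, 1, 2, 2, 2)),
                 "stratification degraded")
  expect_error(split_dataset(1, "ssl"), "at least")
})

test_that("full preprocessing of a fixture is reproducible bitwise and writes a manifest", {
  d <- withr::local_tempdir()
  p <- gen_wfdb_fixture(synthetic_ecg_spec(), 15, d, seed = 21)
  out1 <- file.path(d, "o1"); out2 <- file.path(d, "o2")
  r1 <- preprocess_records(d, out1, scheme = "supervised", seed = 5)
  r2 <- preprocess_records(d, out2, scheme = "supervised", seed = 5)
  expect_identical(lapply(r1$beats, `[[`, "samples"),
                   lapply(r2$beats, `[[`, "samples"))
  expect_identical(r1$split$train, r2$split$train)
  man <- utils::read.csv(file.path(out1, "manifest.csv"))
  expect_equal(nrow(man), length(r1$beats))
  expect_setequal(unique(man$split), c("train", "test"))
  expect_true(file.exists(file.path(out1, "beats.rds")))
  expect_true(file.exists(file.path(out1, "meta.json")))
})
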