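test_that("beat template validates R-wave dominance", {
  expect_s3_class(beat_template(), "beat_template")
  expect_error(
    beat_template(waves = list(P = c(-0.2, 0.025, 1.5), Q = c(-0.04, 0.01, -0.1),
                               R = c(0, 0.012, 1.0), S = c(0.04, 0.01, -0.15),
                               T = c(0.25, 0.06, 0.3))),
    "config error")
})

test_that("clean segment rendering is deterministic and R-peaked", {
  g1 <- gen_clean_segments(1, seed = 1, jitter = FALSE)
  g2 <- gen_clean_segments(1, seed = 1, jitter = FALSE)
  expect_identical(g1$segments, g2$segments)
  x <- g1$segments[1, ]
  expect_length(x, 512)
  tpl <- beat_template()
  # peak amplitude within 1% of the configured R amplitude
  expect_lt(abs(max(x) - tpl$waves$R[3]) / tpl$waves$R[3], 0.01)
  # peak sits at an R-wave centre (integer multiple of the RR interval)
  fs <- tpl$sampling_rate; rr <- 60 / tpl$heart_rate
  t_peak <- (which.max(x) - 1) / fs
  expect_lt(min(abs(t_peak - c(0, rr, 2 * rr))), 1.5 / fs)
})

test_that("records carry distinct jittered morphologies", {
  g <- gen_clean_segments(20, seed = 3, segments_per_record = 5)
  expect_length(unique(g$record_id), 4)
  # different records differ; segments exist for every record
  r1 <- g$segments[g$record_id == unique(g$record_id)[1], ]
  r2 <- g$segments[g$record_id == unique(g$record_id)[2], ]
  expect_gt(max(abs(colMeans(r1) - colMeans(r2))), 1e-4)
})

test_that("noise generators are zero-mean, reproducible and spectrally placed", {
  for (kind in c("baseline_wander", "emg", "powerline")) {
    n1 <- gen_noise(kind, 1024, seed = 5)
    n2 <- gen_noise(kind, 1024, seed = 5)
    expect_identical(n1, n2)
    expect_lt(abs(mean(n1)), 0.01 * sqrt(mean(n1^2)))
  }
  expect_error(gen_noise("cosmic_rays", 100), "config error")

  # powerline: dominant periodogram bin exactly at the line frequency
  fs <- 250; n <- 1000
  pl <- gen_noise("powerline", n, seed = 6, params = list(fs = fs))
  spec <- Mod(fft(pl))[1:(n / 2)]
  freq <- (seq_len(n / 2) - 1) * fs / n
  expect_equal(freq[which.max(spec)], 50)
  pl60 <- gen_noise("powerline", n, seed = 6,
                    params = list(fs = fs, line_freq = 60))
  spec60 <- Mod(fft(pl60))[1:(n / 2)]
  expect_equal(freq[which.max(spec60)], 60)

  # baseline wander: >95% of power below 0.7 Hz (long window periodogram)
  bw <- gen_noise("baseline_wander", 50000, seed = 7, params = list(fs = fs))
  p <- Mod(fft(bw))[1:25000]^2
  f <- (seq_len(25000) - 1) * fs / 50000
  expect_gt(sum(p[f < 0.7]) / sum(p), 0.95)

  # emg: band-limited broadband - negligible power outside 15-120 Hz
  em <- gen_noise("emg", 5000, seed = 8, params = list(fs = fs))
  pe <- Mod(fft(em))[1:2500]^2
  fe <- (seq_len(2500) - 1) * fs / 5000
  expect_lt(sum(pe[fe < 14 | fe > 121]) / sum(pe), 1e-20)
})

test_that("mixing realises the amplitude factor exactly", {
  set.seed(16)
  clean <- gen_clean_segments(1, seed = 2, jitter = FALSE)$segments[1, ]
  noise <- gen_noise("emg", 512, seed = 9)
  for (f in c(0.2, 0.7, 2.0)) {
    pr <- mix_segments(clean, noise, f)
    expect_equal(max(abs(pr$noisy - pr$clean)), f * max(abs(clean)),
                 tolerance = 1e-12)
    expect_equal(pr$noisy - pr$clean, pr$scaled_noise, tolerance = 1e-12)
    expect_identical(pr$noise_amplitude_factor, f)
  }
  expect_error(mix_segments(clean, noise, 0.1), "invalid argument")
  expect_error(mix_segments(clean, noise[-1], 1), "shape error")
  expect_error(mix_segments(numeric(512), noise, 1), "degenerate input")
})

test_that("PRD of the noisy mixture increases with the amplitude factor", {
  clean <- gen_clean_segments(1, seed = 2, jitter = FALSE)$segments[1, ]
  noise <- gen_noise("baseline_wander", 512, seed = 10)
  prds <- vapply(seq(0.2, 2.0, length.out = 8),
                 function(f) metric_prd(clean, mix_segments(clean, noise, f)$noisy),
                 numeric(1))
  expect_true(all(diff(prds) > 0))
})

test_that("make_dataset produces hygienic record-disjoint splits", {
  ds <- make_dataset(10, 3, 4, seed = 21)
  m <- ds$meta
  expect_setequal(unique(m$split), c("train", "val", "test"))
  # 70/30 record split of the training pool: 10 records -> 3 val
  expect_length(unique(m$record_id[m$split == "val"]), 3)
  expect_length(unique(m$record_id[m$split == "train"]), 7)
  hy <- check_split_hygiene(ds)
  expect_true(hy$ok)
  expect_length(hy$record_overlaps, 0)
  expect_length(hy$noise_seed_overlaps, 0)
  expect_true(all(m$noise_amplitude_factor >= 0.2 & m$noise_amplitude_factor <= 2.0))
  # determinism
  ds2 <- make_dataset(10, 3, 4, seed = 21)
  expect_identical(ds$noisy, ds2$noisy)
  expect_identical(ds$meta, ds2$meta)
  expect_error(make_dataset(1, 1, 4), "config error")
})

test_that("the hygiene checker actually detects contamination", {
  ds <- make_dataset(10, 3, 4, seed = 22)
  ds$meta$record_id[ds$meta$split == "test"][1] <- ds$meta$record_id[1]
  expect_false(check_split_hygiene(ds)$ok)
  ds2 <- make_dataset(10, 3, 4, seed = 22)
  ds2$meta$noise_seed[ds2$meta$split == "test"][1] <- ds2$meta$noise_seed[1]
  expect_false(check_split_hygiene(ds2)$ok)
})

test_that("dataset CSV round trip preserves signals and metadata", {
  ds <- make_dataset(4, 2, 3, seed = 23, n_samples = 128L)
  dir <- file.path(tempdir(), "kandiff-ds-test")
  man <- write_segment_dataset(ds, dir, extra = list(seed = 23))
  expect_true(all(file.exists(file.path(dir, c("clean.csv", "noisy.csv",
                                               "meta.csv", "manifest.json")))))
  back <- read_segment_dataset(dir)
  expect_equal(unname(back$clean), unname(ds$clean), tolerance = 1e-12)
  expect_equal(unname(back$noisy), unname(ds$noisy), tolerance = 1e-12)
  expect_equal(back$meta$record_id, ds$meta$record_id)
  expect_equal(man$n_segments, nrow(ds$clean))
  unlink(dir, recursive = TRUE)
})
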