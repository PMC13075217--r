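#' Clean PQRST beat template
#'
#' Parameterises one synthetic heartbeat as a sum of five Gaussian bumps
#' (P, Q, R, S, T), each with a centre offset relative to the R peak
#' (seconds), a width (seconds, the Gaussian sd) and an amplitude (mV).
#' Default morphology is a textbook single-lead beat: dominant 1 mV R wave,
#' small negative Q/S, rounded P and T.  Per-record jitter parameters control
#' the morphological identity given to each synthetic record (multiplicative
#' amplitude/width noise) and the per-beat timing jitter.
#'
#' @param sampling_rate Hz (default 250; 512 samples then span ~2 s).
#' @param heart_rate Beats per minute (default 75).
#' @param waves Named list of `c(center, width, amplitude)` triples for
#'   P, Q, R, S, T.
#' @param amp_jitter_sd,width_jitter_sd Standard deviation of the per-record
#'   log-normal multiplicative jitter on amplitudes and widths.
#' @param timing_jitter_sd Per-beat centre jitter, seconds.
#' @return Object of class `"beat_template"`.
#' @export
beat_template <- function(sampling_rate = 250,
                          heart_rate = 75,
                          waves = list(
                            P = c(-0.20, 0.025, 0.15),
                            Q = c(-0.04, 0.010, -0.10),
                            R = c( 0.00, 0.012, 1.00),
                            S = c( 0.04, 0.010, -0.15),
                            T = c( 0.25, 0.060, 0.30)),
                          amp_jitter_sd = 0.10,
                          width_jitter_sd = 0.05,
                          timing_jitter_sd = 0.01) {
  stopifnot(all(c("P", "Q", "R", "S", "T") %in% names(waves)))
  ra <- abs(waves$R[3])
  others <- vapply(waves[setdiff(names(waves), "R")], function(w) abs(w[3]), numeric(1))
  if (any(others >= ra))
    stop("config error: R amplitude must dominate all other waves", call. = FALSE)
  structure(list(sampling_rate = sampling_rate, heart_rate = heart_rate,
                 waves = waves, amp_jitter_sd = amp_jitter_sd,
                 width_jitter_sd = width_jitter_sd,
                 timing_jitter_sd = timing_jitter_sd),
            class = "beat_template")
}

# Render one 512-sample segment for a (possibly jittered) template.
render_segment <- function(template, n_samples = 512L, phase = 0,
                           beat_jitter = NULL) {
  fs <- template$sampling_rate
  tt <- (seq_len(n_samples) - 1) / fs
  rr <- 60 / template$heart_rate
  centers <- seq(-rr, max(tt) + rr, by = rr) + phase
  if (!is.null(beat_jitter)) centers <- centers + beat_jitter[seq_along(centers)]
  x <- numeric(n_samples)
  for (ci in centers) {
    for (w in template$waves) {
      x <- x + w[3] * exp(-((tt - ci - w[1])^2) / (2 * w[2]^2))
    }
  }
  x
}

# Per-record morphological identity: jitter the template once per record.
jitter_template <- function(template, jitter = TRUE) {
  if (!jitter) return(template)
  waves <- lapply(template$waves, function(w) {
    c(w[1],
      w[2] * exp(stats::rnorm(1, 0, template$width_jitter_sd)),
      w[3] * exp(stats::rnorm(1, 0, template$amp_jitter_sd)))
  })
  template$heart_rate <- template$heart_rate * exp(stats::rnorm(1, 0, 0.05))
  template$waves <- waves
  template
}

#' Generate clean synthetic ECG segments
#'
#' Renders `n` 512-sample clean segments grouped into records: every record
#' gets its own jittered copy of the beat template (its morphological
#' identity), so record-disjoint splitting carries real signal.  With
#' `jitter = FALSE` and one record the rendering is deterministic.
#'
#' @param n Number of segments (>= 1).
#' @param seed Integer seed.
#' @param template A [beat_template()].
#' @param segments_per_record Segments rendered per record id.
#' @param n_samples Samples per segment (default 512).
#' @param record_prefix Prefix for generated record ids.
#' @param jitter Apply per-record/per-beat jitter (default `TRUE`).
#' @return List with `segments` (`n x n_samples` matrix) and `record_id`
#'   (character vector of length `n`).
#' @export
gen_clean_segments <- function(n, seed = 1L, template = beat_template(),
                               segments_per_record = 8L, n_samples = 512L,
                               record_prefix = "rec", jitter = TRUE) {
  stopifnot(n >= 1)
  set.seed(as.integer(seed))
  n_records <- ceiling(n / segments_per_record)
  segs <- matrix(0, n, n_samples)
  ids <- character(n)
  i <- 0L
  for (r in seq_len(n_records)) {
    tpl <- jitter_template(template, jitter)
    rr <- 60 / tpl$heart_rate
    for (s in seq_len(segments_per_record)) {
      if (i >= n) break
      i <- i + 1L
      phase <- if (jitter) stats::runif(1, 0, rr) else 0
      bj <- if (jitter) stats::rnorm(16L, 0, tpl$timing_jitter_sd) else NULL
      segs[i, ] <- render_segment(tpl, n_samples, phase, bj)
      ids[i] <- sprintf("%s%03d", record_prefix, r)
    }
  }
  list(segments = segs, record_id = ids)
}

#' Generate one synthetic noise segment
#'
#' Three clinical noise classes at sampling rate `fs`:
#' * `baseline_wander` — a random mixture of sinusoids below 0.5 Hz
#'   (respiration/motion drift; >95% of power below 0.7 Hz);
#' * `emg` — broadband muscle noise: white noise band-limited to
#'   15-120 Hz in the frequency domain;
#' * `powerline` — a pure mains sinusoid (50 or 60 Hz) with random phase.
#' All outputs are exactly zero-mean and reproducible from `seed`.
#'
#' @param kind One of `"baseline_wander"`, `"emg"`, `"powerline"`.
#' @param length Number of samples.
#' @param seed Integer seed.
#' @param params List of kind-specific parameters: `fs` (default 250),
#'   `line_freq` (50 or 60, default 50), `n_components` (baseline wander,
#'   default 4), `band` (emg, default `c(15, 120)` Hz).
#' @return Numeric zero-mean noise vector.
#' @export
gen_noise <- function(kind, length, seed = 1L, params = list()) {
  set.seed(as.integer(seed))
  fs <- params$fs %||% 250
  tt <- (seq_len(length) - 1) / fs
  x <- switch(kind,
    baseline_wander = {
      nc <- params$n_components %||% 4L
      freqs <- stats::runif(nc, 0.05, 0.45)
      amps <- stats::runif(nc, 0.3, 1.0)
      phases <- stats::runif(nc, 0, 2 * pi)
      rowSums(vapply(seq_len(nc),
                     function(j) amps[j] * sin(2 * pi * freqs[j] * tt + phases[j]),
                     numeric(length)))
    },
    emg = {
      band <- params$band %||% c(15, 120)
      w <- stats::rnorm(length)
      sp <- stats::fft(w)
      freq <- (seq_len(length) - 1) * fs / length
      freq <- pmin(freq, fs - freq)              # two-sided spectrum
      sp[freq < band[1] | freq > band[2]] <- 0
      Re(stats::fft(sp, inverse = TRUE)) / length
    },
    powerline = {
      f <- params$line_freq %||% 50
      sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    },
    stop("config error: unknown noise kind '", kind, "'", call. = FALSE)
  )
  x - mean(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mix clean and noise segments at a controlled amplitude factor
#'
#' The noise is peak-normalised, rescaled so that its peak equals
#' `amplitude_factor` times the clean signal's peak, and added:
#' `noisy = clean + factor * (noise / max|noise|) * max|clean|`.  The factor
#' is therefore the ratio of scaled-noise peak amplitude to clean peak
#' amplitude — the stratification variable of the noise-interval evaluation.
#'
#' @param clean,noise Equal-length numeric vectors.
#' @param amplitude_factor Real in `[0.2, 2.0]`.
#' @return Object of class `"segment_pair"`: list with `clean`, `noisy`,
#'   `scaled_noise`, `noise_amplitude_factor`.
#' @export
mix_segments <- function(clean, noise, amplitude_factor) {
  if (length(clean) != length(noise))
    stop("shape error: clean and noise lengths differ", call. = FALSE)
  if (amplitude_factor < 0.2 || amplitude_factor > 2.0)
    stop("invalid argument: amplitude_factor must lie in [0.2, 2.0]", call. = FALSE)
  pc <- max(abs(clean)); pn <- max(abs(noise))
  if (pc == 0 || pn == 0)
    stop("degenerate input: zero-peak clean or noise segment", call. = FALSE)
  scaled <- amplitude_factor * (noise / pn) * pc
  structure(list(clean = clean, noisy = clean + scaled, scaled_noise = scaled,
                 noise_amplitude_factor = amplitude_factor),
            class = "segment_pair")
}

#' Build a record-disjoint synthetic train/val/test dataset
#'
#' Emulates the clean-beats + clinical-noise mixing protocol: clean segments
#' are generated per record (each record with its own jittered morphology),
#' training records are split 70/30 into train/validation *by record name*,
#' test records are generated separately, and the noise seeds used for the
#' test split are disjoint from those of train/val (emulating spatially and
#' temporally separated noise epochs).  Amplitude factors are drawn uniformly
#' on `[0.2, 2.0]`.
#'
#' @param n_records_train Records in the training pool (>= 2; split 70/30
#'   into train/val by record).
#' @param n_records_test Test records (>= 1).
#' @param segments_per_record Segments per record.
#' @param seed Master seed; the dataset is a pure function of it.
#' @param template A [beat_template()].
#' @param noise_kinds Noise classes cycled over segments.
#' @param n_samples Samples per segment (default 512).
#' @return Object of class `"segment_dataset"`: list with matrices `clean`,
#'   `noisy` (one segment per row) and `meta` (data frame with `record_id`,
#'   `split`, `noise_amplitude_factor`, `noise_kind`, `noise_seed`).
#' @export
make_dataset <- function(n_records_train = 30L, n_records_test = 6L,
                         segments_per_record = 10L, seed = 1L,
                         template = beat_template(),
                         noise_kinds = c("baseline_wander", "emg", "powerline"),
                         n_samples = 512L) {
  if (n_records_train < 2 || n_records_test < 1 || segments_per_record < 1)
    stop("config error: need >= 2 train records and >= 1 test record", call. = FALSE)
  seed <- as.integer(seed)
  n_train <- n_records_train * segments_per_record
  n_test <- n_records_test * segments_per_record
  tr <- gen_clean_segments(n_train, seed = seed, template = template,
                           segments_per_record = segments_per_record,
                           n_samples = n_samples, record_prefix = "train_rec")
  te <- gen_clean_segments(n_test, seed = seed + 104729L, template = template,
                           segments_per_record = segments_per_record,
                           n_samples = n_samples, record_prefix = "test_rec")
  clean <- rbind(tr$segments, te$segments)
  record_id <- c(tr$record_id, te$record_id)
  n <- nrow(clean)

  # 70/30 record-name split of the training pool into train/val
  train_recs <- unique(tr$record_id)
  n_val_recs <- max(1L, round(0.3 * length(train_recs)))
  set.seed(seed + 7L)
  val_recs <- sample(train_recs, n_val_recs)
  split <- c(ifelse(tr$record_id %in% val_recs, "val", "train"),
             rep("test", n_test))

  # disjoint noise seed ranges per split (spatial/temporal noise separation)
  base <- (seed %% 10000L) * 100000L
  noise_seed <- integer(n)
  noise_seed[split != "test"] <- base + seq_len(sum(split != "test"))
  noise_seed[split == "test"] <- base + 50000L + seq_len(n_test)

  set.seed(seed + 13L)
  factors <- stats::runif(n, 0.2, 2.0)
  kinds <- rep_len(noise_kinds, n)[sample.int(n)]

  noisy <- matrix(0, n, n_samples)
  for (i in seq_len(n)) {
    nz <- gen_noise(kinds[i], n_samples, seed = noise_seed[i],
                    params = list(fs = template$sampling_rate))
    noisy[i, ] <- mix_segments(clean[i, ], nz, factors[i])$noisy
  }
  structure(
    list(clean = clean, noisy = noisy,
         meta = data.frame(record_id = record_id, split = split,
                           noise_amplitude_factor = factors,
                           noise_kind = kinds, noise_seed = noise_seed,
                           stringsAsFactors = FALSE)),
    class = "segment_dataset"
  )
}

#' @export
print.segment_dataset <- function(x, ...) {
  tab <- table(x$meta$split)
  cat(sprintf("segment_dataset: %d segments x %d samples (%s)\n",
              nrow(x$clean), ncol(x$clean),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Check record- and noise-seed disjointness across splits
#'
#' @param dataset A [make_dataset()] result.
#' @return List with `record_overlaps` and `noise_seed_overlaps` (character /
#'   integer vectors; both empty for a hygienic dataset) and logical `ok`.
#' @export
check_split_hygiene <- function(dataset) {
  m <- dataset$meta
  splits <- unique(m$split)
  rec_overlap <- character(0)
  seed_overlap <- integer(0)
  for (i in seq_along(splits)) for (j in seq_along(splits)) {
    if (i < j) {
      rec_overlap <- c(rec_overlap,
                       intersect(m$record_id[m$split == splits[i]],
                                 m$record_id[m$split == splits[j]]))
      # noise separation contract: test noise never seen in train/val
      if (xor(splits[i] == "test", splits[j] == "test"))
        seed_overlap <- c(seed_overlap,
                          intersect(m$noise_seed[m$split == splits[i]],
                                    m$noise_seed[m$split == splits[j]]))
    }
  }
  list(record_overlaps = unique(rec_overlap),
       noise_seed_overlaps = unique(seed_overlap),
       ok = length(rec_overlap) == 0 && length(seed_overlap) == 0)
}

#' Write / read a segment dataset as CSV
#'
#' Writes `clean.csv` and `noisy.csv` (one row per segment, one column per
#' sample) plus a `meta.csv` sidecar and a `manifest.json` with counts and
#' MD5 checksums.
#'
#' @param dataset A [make_dataset()] result.
#' @param dir Output directory (created if missing).
#' @param extra Optional named list merged into the manifest.
#' @return Invisibly, the manifest list.
#' @export
write_segment_dataset <- function(dataset, dir, extra = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clean.csv", "noisy.csv", "meta.csv"))
  data.table::fwrite(data.table::as.data.table(dataset$clean), paths[1])
  data.table::fwrite(data.table::as.data.table(dataset$noisy), paths[2])
  data.table::fwrite(dataset$meta, paths[3])
  manifest <- c(list(
    n_segments = nrow(dataset$clean),
    n_samples = ncol(dataset$clean),
    splits = as.list(table(dataset$meta$split)),
    checksums = stats::setNames(
      lapply(paths, function(p) digest::digest(file = p)),
      basename(paths))
  ), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' @rdname write_segment_dataset
#' @export
read_segment_dataset <- function(dir) {
  structure(
    list(clean = as.matrix(data.table::fread(file.path(dir, "clean.csv"))),
         noisy = as.matrix(data.table::fread(file.path(dir, "noisy.csv"))),
         meta = as.data.frame(data.table::fread(file.path(dir, "meta.csv")))),
    class = "segment_dataset"
  )
}
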