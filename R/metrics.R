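check_pair <- function(x, xhat) {
  if (length(x) != length(xhat))
    stop("shape error: signals have different lengths", call. = FALSE)
}

#' Sum of squared distances
#'
#' `SSD = sum_n (x(n) - xhat(n))^2`, in mV^2 for mV signals.
#' @param x Clean reference segment.
#' @param xhat Denoised estimate, same length.
#' @return Non-negative scalar.
#' @export
metric_ssd <- function(x, xhat) { check_pair(x, xhat); sum((x - xhat)^2) }

#' Maximum absolute distance
#'
#' `MAD = max_n |x(n) - xhat(n)|`, in mV.
#' @inheritParams metric_ssd
#' @return Non-negative scalar.
#' @export
metric_mad <- function(x, xhat) { check_pair(x, xhat); max(abs(x - xhat)) }

#' Percentage root-mean-square difference
#'
#' `PRD = 100 * sqrt( sum (x - xhat)^2 / sum (x - mean(x))^2 )`, in percent.
#' The denominator subtracts the clean-signal mean (the normalised "PRDN"
#' form); [metric_prd_raw()] gives the non-mean-subtracted variant for
#' cross-study comparability.
#'
#' @inheritParams metric_ssd
#' @return Non-negative scalar (percent).
#' @export
metric_prd <- function(x, xhat) {
  check_pair(x, xhat)
  den <- sum((x - mean(x))^2)
  if (den <= 0)
    stop("undefined denominator: constant reference signal", call. = FALSE)
  100 * sqrt(sum((x - xhat)^2) / den)
}

#' PRD without mean subtraction
#'
#' `100 * sqrt( sum (x - xhat)^2 / sum x^2 )`.
#' @inheritParams metric_ssd
#' @return Non-negative scalar (percent).
#' @export
metric_prd_raw <- function(x, xhat) {
  check_pair(x, xhat)
  den <- sum(x^2)
  if (den <= 0) stop("undefined denominator: zero reference signal", call. = FALSE)
  100 * sqrt(sum((x - xhat)^2) / den)
}

#' Cosine similarity
#'
#' Inner product of the two segments over the product of their norms;
#' dimensionless in `[-1, 1]`.
#' @inheritParams metric_ssd
#' @return Scalar in `[-1, 1]`.
#' @export
metric_cossim <- function(x, xhat) {
  check_pair(x, xhat)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(xhat^2))
  if (nx == 0 || ny == 0)
    stop("undefined: zero-norm input to cosine similarity", call. = FALSE)
  sum(x * xhat) / (nx * ny)
}

#' Mean per-segment inference time
#'
#' Arithmetic mean of per-sample processing times, in seconds.
#' @param times Numeric vector of per-segment times (length >= 1).
#' @return Scalar mean time.
#' @export
mean_inference_time <- function(times) {
  stopifnot(length(times) >= 1)
  mean(times)
}

#' Per-segment metrics table
#'
#' Convenience wrapper: computes SSD/MAD/PRD/CosSim for each row pair of two
#' segment matrices.
#'
#' @param clean,denoised Matrices with one segment per row.
#' @param factors Optional noise amplitude factors (one per row), carried
#'   into the result for stratification.
#' @return `data.frame` with one row per segment.
#' @export
segment_metrics <- function(clean, denoised, factors = NULL) {
  stopifnot(nrow(clean) == nrow(denoised))
  out <- data.frame(
    ssd = vapply(seq_len(nrow(clean)), function(i) metric_ssd(clean[i, ], denoised[i, ]), numeric(1)),
    mad = vapply(seq_len(nrow(clean)), function(i) metric_mad(clean[i, ], denoised[i, ]), numeric(1)),
    prd = vapply(seq_len(nrow(clean)), function(i) metric_prd(clean[i, ], denoised[i, ]), numeric(1)),
    cossim = vapply(seq_len(nrow(clean)), function(i) metric_cossim(clean[i, ], denoised[i, ]), numeric(1))
  )
  if (!is.null(factors)) out$noise_amplitude_factor <- factors
  out
}

noise_bins <- function() {
  list(breaks = c(0.2, 0.6, 1.0, 1.5, 2.0),
       labels = c("0.2-0.6", "0.6-1.0", "1.0-1.5", "1.5-2.0"))
}

#' Stratify per-segment metrics by noise amplitude interval
#'
#' Bins segments by their noise amplitude factor into the four evaluation
#' intervals 0.2-0.6, 0.6-1.0, 1.0-1.5, 1.5-2.0 (left-closed, right-open;
#' the last interval also closed on the right) and averages each metric per
#' bin.  Factors outside `[0.2, 2.0]` raise a warning and are excluded.
#'
#' @param metrics A data frame as from [segment_metrics()], with a
#'   `noise_amplitude_factor` column.
#' @return Data frame: one row per interval with mean metrics and count `n`.
#' @export
stratify_by_noise_level <- function(metrics) {
  stopifnot(is.data.frame(metrics), "noise_amplitude_factor" %in% names(metrics))
  f <- metrics$noise_amplitude_factor
  bins <- noise_bins()
  out_of_range <- f < bins$breaks[1] | f > bins$breaks[length(bins$breaks)]
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " segment(s) with noise factor outside [0.2, 2.0] excluded")
    metrics <- metrics[!out_of_range, , drop = FALSE]
    f <- f[!out_of_range]
  }
  idx <- findInterval(f, bins$breaks, rightmost.closed = TRUE)
  cols <- intersect(c("ssd", "mad", "prd", "cossim", "time"), names(metrics))
  res <- lapply(seq_along(bins$labels), function(b) {
    sel <- metrics[idx == b, cols, drop = FALSE]
    cbind(data.frame(noise_interval = bins$labels[b], n = nrow(sel)),
          as.data.frame(lapply(sel, function(v) if (nrow(sel)) mean(v) else NA_real_)))
  })
  do.call(rbind, res)
}
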