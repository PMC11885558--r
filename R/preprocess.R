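# Preprocessing pipeline: long windowing -> zero-phase low-pass ->
# polyphase resampling -> smoothness-priors detrending -> short
# windowing -> IQR outlier rejection -> min-max normalisation.

#' Preprocessing configuration
#'
#' Defaults follow the pipeline this package implements end to end:
#' 50 s long windows, a zero-phase order-4 Butterworth low-pass at
#' 30 Hz, resampling to 100 Hz, smoothness-priors detrending
#' (lambda = 500, a sub-hertz effective cutoff at 100 Hz), 10 s short
#' windows, Tukey-fence outlier rejection (k = 1.5) on per-segment
#' peak-to-peak amplitude, and min-max normalisation to \[0, 1\].
#'
#' @param window_long_s long window length (s); must be an integer
#'   multiple of `window_short_s`.
#' @param lpf_cutoff_hz,lpf_order low-pass cutoff (Hz) and Butterworth
#'   order (applied forward-backward, so the effective attenuation is
#'   the squared magnitude response).
#' @param fs_target target sampling rate (Hz) after downsampling.
#' @param detrend_lambda smoothness-priors regularisation, >= 0.
#' @param window_short_s short (segment) window length (s).
#' @param iqr_k Tukey fence multiplier.
#' @param iqr_feature segment statistic screened for outliers:
#'   `"peak_to_peak"` (default) or `"sd"`.
#' @param label_policy segment labelling policy, see [label_segment()].
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(window_long_s = 50, lpf_cutoff_hz = 30,
                              lpf_order = 4, fs_target = 100,
                              detrend_lambda = 500, window_short_s = 10,
                              iqr_k = 1.5,
                              iqr_feature = c("peak_to_peak", "sd"),
                              label_policy = "majority") {
  iqr_feature <- match.arg(iqr_feature)
  if (window_long_s %% window_short_s != 0)
    rlang::abort("window_long_s must be an integer multiple of window_short_s.")
  if (lpf_cutoff_hz >= fs_target / 2)
    rlang::abort("lpf_cutoff_hz must be below the target Nyquist frequency.")
  structure(list(window_long_s = window_long_s, lpf_cutoff_hz = lpf_cutoff_hz,
                 lpf_order = lpf_order, fs_target = fs_target,
                 detrend_lambda = detrend_lambda,
                 window_short_s = window_short_s, iqr_k = iqr_k,
                 iqr_feature = iqr_feature, label_policy = label_policy),
            class = "preprocess_config")
}

#' Split a signal into consecutive fixed-length windows
#'
#' Non-overlapping windows of exactly `fs * length_s` samples; a trailing
#' remainder shorter than one window is dropped. A signal shorter than
#' one window yields an empty list.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param length_s window duration (s); `fs * length_s` must be a
#'   positive integer.
#' @return List of numeric vectors.
#' @export
ecg_window <- function(signal, fs, length_s) {
  w <- fs * length_s
  if (w <= 0 || abs(w - round(w)) > 1e-9)
    rlang::abort("fs * length_s must be a positive integer.")
  w <- as.integer(round(w))
  k <- length(signal) %/% w
  if (k == 0L) return(list())
  lapply(seq_len(k), function(i) signal[((i - 1L) * w + 1L):(i * w)])
}

#' Zero-phase Butterworth low-pass filter
#'
#' Order-`order` Butterworth design applied forward and backward
#' (zero phase, squared magnitude response). Edge transients are
#' controlled by odd reflection padding of three filter-order lengths
#' before filtering, removed afterwards.
#'
#' @param signal numeric vector.
#' @param fs sampling rate (Hz).
#' @param cutoff_hz -3 dB cutoff of the one-pass design (Hz), must be
#'   below `fs/2`.
#' @param order filter order (default 4).
#' @return Filtered signal, same length as the input.
#' @export
ecg_lowpass <- function(signal, fs, cutoff_hz = 30, order = 4) {
  if (cutoff_hz >= fs / 2)
    rlang::abort("cutoff_hz must be below the Nyquist frequency fs/2.")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  filtfilt_reflect(bf$b, bf$a, signal)
}

# forward-backward filtering with odd-reflection edge padding
filtfilt_reflect <- function(b, a, x) {
  n <- length(x)
  npad <- min(max(3L * (max(length(a), length(b)) - 1L) * 10L, 50L), n - 1L)
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  xp <- c(pre, x, post)
  y <- signal::filter(b, a, xp)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(npad + 1L):(npad + n)]
}

#' Polyphase rational-ratio resampling
#'
#' Downsample `fs_in -> fs_out` by rational factor `p/q` (reduced):
#' zero-stuff by `p`, apply an anti-aliasing linear-phase FIR low-pass at
#' the tighter of the two Nyquist limits, compensate the filter's group
#' delay, and keep every `q`-th sample. `fs_in == fs_out` is the
#' identity. Output length is `round(n * fs_out / fs_in)`.
#'
#' @param signal numeric vector.
#' @param fs_in,fs_out source and target rates (Hz); `fs_out <= fs_in`.
#' @return Resampled numeric vector.
#' @export
ecg_resample <- function(signal, fs_in, fs_out) {
  if (fs_out > fs_in) rlang::abort("upsampling (fs_out > fs_in) is out of scope.")
  if (fs_out <= 0) rlang::abort("fs_out must be positive.")
  if (fs_in == fs_out) return(signal)
  g <- rational_ratio(fs_out, fs_in)
  p <- g[1]; q <- g[2]
  n_out <- round(length(signal) * fs_out / fs_in)
  # anti-alias FIR on the upsampled grid; cutoff at min(pi/p, pi/q)
  ntaps <- 10L * max(p, q) + 1L
  fc <- 1 / max(p, q)                       # fraction of upsampled Nyquist
  h <- signal::fir1(ntaps - 1L, fc, type = "low") * p
  up <- numeric(length(signal) * p)
  up[seq(1L, length(up), by = p)] <- signal
  delay <- (ntaps - 1L) / 2
  # pad with odd reflection to absorb FIR edges
  npad <- ntaps
  pre <- 2 * up[1] - up[(npad + 1L):2L]
  post <- 2 * up[length(up)] - up[(length(up) - 1L):(length(up) - npad)]
  y <- stats::filter(c(pre, up, post), h, method = "convolution", sides = 1)
  y <- as.numeric(y)[(npad + 1L + delay):(npad + delay + length(up))]
  idx <- seq(1L, by = q, length.out = n_out)
  y[idx]
}

rational_ratio <- function(a, b) {
  # reduce a/b to smallest integers (rates may be non-integer, e.g. 257/2)
  scale <- 1
  while (abs(a * scale - round(a * scale)) > 1e-9 ||
         abs(b * scale - round(b * scale)) > 1e-9) scale <- scale * 10
  ai <- round(a * scale); bi <- round(b * scale)
  g <- gcd_int(ai, bi)
  c(ai / g, bi / g)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Smoothness-priors detrending
#'
#' Removes the low-frequency trend `t = (I + lambda^2 D2' D2)^-1 z`
#' (with `D2` the (N-2) x N second-difference operator) and returns
#' `z - t`. Affine signals lie in the null space of `D2`, so they are
#' annihilated exactly for every lambda; `lambda = 0` returns all zeros.
#' Solved through the banded sparse structure, never a dense inverse.
#'
#' @param signal numeric vector, length >= 3.
#' @param lambda regularisation parameter >= 0; larger lambda keeps a
#'   smoother (lower-frequency) trend. Default 500 corresponds to a
#'   sub-hertz effective cutoff at 100 Hz sampling.
#' @return Detrended signal, same length.
#' @export
detrend_sp <- function(signal, lambda = 500) {
  n <- length(signal)
  if (n < 3) rlang::abort("detrend_sp needs at least 3 samples.")
  if (lambda < 0) rlang::abort("lambda must be >= 0.")
  if (lambda == 0) return(signal * 0)
  d2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  a <- Matrix::Diagonal(n) + lambda^2 * Matrix::crossprod(d2)
  trend <- as.numeric(Matrix::solve(a, signal, sparse = TRUE))
  signal - trend
}

segment_feature <- function(samples, feature) {
  switch(feature,
         peak_to_peak = diff(range(samples)),
         sd = stats::sd(samples))
}

#' Tukey-fence outlier rejection over a set of segments
#'
#' Computes one scalar feature per segment (default peak-to-peak
#' amplitude), the 25th/75th percentiles (linear interpolation,
#' `quantile` type 7) and the Tukey fences `[Q1 - k IQR, Q3 + k IQR]`;
#' segments outside the fences are rejected. Fewer than 4 segments: all
#' kept (quartiles are not meaningful).
#'
#' @param segments list of numeric vectors.
#' @param k fence multiplier (default 1.5).
#' @param feature `"peak_to_peak"` or `"sd"`.
#' @return Logical vector, `TRUE` = keep, same order as `segments`.
#' @export
iqr_keep <- function(segments, k = 1.5, feature = "peak_to_peak") {
  if (length(segments) < 4L) return(rep(TRUE, length(segments)))
  r <- vapply(segments, segment_feature, numeric(1), feature = feature)
  qs <- stats::quantile(r, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  r >= qs[1] - k * iqr & r <= qs[2] + k * iqr
}

#' Min-max normalisation to \[0, 1\]
#'
#' `x -> (x - min) / (max - min)`. A constant segment maps to all zeros
#' with the `degenerate` attribute set (such segments are excluded from
#' training by default).
#'
#' @param x numeric vector.
#' @return Normalised vector with attribute `degenerate` (logical).
#' @export
minmax <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    out <- rep(0, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (x - rng[1]) / (rng[2] - rng[1])
  attr(out, "degenerate") <- FALSE
  out
}

#' Run the full preprocessing pipeline on one record
#'
#' Applies, in order: long windowing (50 s) -> zero-phase low-pass ->
#' resampling to `fs_target` -> smoothness-priors detrending -> short
#' windowing (10 s) -> IQR outlier rejection (per record) -> min-max
#' normalisation. Beat annotations are carried into the 100 Hz time base
#' (index scaling by `fs_target/fs`, round-half-even) and each segment is
#' labelled with [label_segment()].
#'
#' @param record a `raw_record` (see [read_record()] / [synth_record()]).
#' @param config a [preprocess_config()].
#' @param scheme a [class_scheme()].
#' @return A tibble with one row per emitted segment: `record_id`,
#'   `start_time_s`, `label`, `kept` (IQR), `degenerate`, and a `samples`
#'   list-column of normalised numeric vectors (length
#'   `window_short_s * fs_target`). Rejected segments are retained in the
#'   manifest with `kept = FALSE`.
#' @export
run_pipeline <- function(record, config = preprocess_config(),
                         scheme = class_scheme("mitbih")) {
  stopifnot(inherits(record, "raw_record"))
  if (record$fs < config$fs_target)
    rlang::abort("record sampling rate is below fs_target.")
  longs <- ecg_window(record$samples, record$fs, config$window_long_s)
  if (length(longs) == 0L) return(empty_segment_tbl())
  n_short <- as.integer(config$window_short_s * config$fs_target)
  per_long <- as.integer(config$window_long_s / config$window_short_s)
  ann <- record$annotations
  ann$class <- map_symbol(ann$symbol, scheme)
  ann <- ann[!is.na(ann$class), , drop = FALSE]
  # annotation indices rescaled into the target time base (0-based)
  ann_idx <- round(ann$sample_index * config$fs_target / record$fs)

  rows <- list()
  for (iw in seq_along(longs)) {
    x <- longs[[iw]]
    x <- ecg_lowpass(x, record$fs, config$lpf_cutoff_hz, config$lpf_order)
    x <- ecg_resample(x, record$fs, config$fs_target)
    x <- detrend_sp(x, config$detrend_lambda)
    shorts <- ecg_window(x, config$fs_target, config$window_short_s)
    long_t0 <- (iw - 1L) * config$window_long_s
    long_i0 <- (iw - 1L) * per_long * n_short   # 0-based in target base
    for (is in seq_along(shorts)) {
      s0 <- long_i0 + (is - 1L) * n_short
      inside <- ann_idx >= s0 & ann_idx < s0 + n_short
      lab <- label_segment(ann$class[inside], scheme, config$label_policy)
      rows[[length(rows) + 1L]] <- list(
        record_id = record$record_id,
        start_time_s = long_t0 + (is - 1L) * config$window_short_s,
        label = lab,
        samples = shorts[[is]]
      )
    }
  }
  segs <- lapply(rows, `[[`, "samples")
  kept <- iqr_keep(segs, config$iqr_k, config$iqr_feature)
  normed <- lapply(segs, minmax)
  tibble::tibble(
    record_id = vapply(rows, `[[`, character(1), "record_id"),
    start_time_s = vapply(rows, `[[`, numeric(1), "start_time_s"),
    label = vapply(rows, `[[`, character(1), "label"),
    kept = kept,
    degenerate = vapply(normed, function(s) attr(s, "degenerate"), logical(1)),
    samples = lapply(normed, as.numeric)
  )
}

empty_segment_tbl <- function() {
  tibble::tibble(record_id = character(), start_time_s = numeric(),
                 label = character(), kept = logical(),
                 degenerate = logical(), samples = list())
}
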