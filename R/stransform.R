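# Discrete Stockwell transform, band-limited, plus its brute-force oracle.

#' Stockwell transform configuration
#'
#' @param fmin_hz,fmax_hz inclusive frequency band in Hz (defaults 0 and
#'   15; high-frequency muscle/ESU artifacts sit above 15 Hz, and all
#'   diagnostic ECG energy retained by the preprocessing pipeline lies
#'   below it).
#' @param zero_freq_rule convention for the 0 Hz row: `"mean"` (signal
#'   mean replicated across time, the default) or `"zero"`.
#' @return An `st_config` list.
#' @export
st_config <- function(fmin_hz = 0, fmax_hz = 15,
                      zero_freq_rule = c("mean", "zero")) {
  zero_freq_rule <- match.arg(zero_freq_rule)
  if (!(fmin_hz >= 0 && fmin_hz < fmax_hz))
    rlang::abort("need 0 <= fmin_hz < fmax_hz.")
  structure(list(fmin_hz = fmin_hz, fmax_hz = fmax_hz,
                 zero_freq_rule = zero_freq_rule),
            class = "st_config")
}

st_band_bins <- function(n, fs, config) {
  if (config$fmax_hz > fs / 2)
    rlang::abort("fmax_hz exceeds the Nyquist frequency.")
  lo <- ceiling(config$fmin_hz * n / fs)
  hi <- floor(config$fmax_hz * n / fs)
  if (hi < lo) rlang::abort("frequency band contains no DFT bins.")
  lo:hi
}

# Symmetric alias of DFT bin indices m = 0..N-1: m for m <= N/2, m - N above.
symmetric_alias <- function(m, n) ifelse(m <= n / 2, m, m - n)

#' Band-limited discrete Stockwell transform
#'
#' Frequency-domain Gaussian-voice algorithm. With `X = DFT(x)` (and the
#' 1/N factor carried by the inverse transform), the row for in-band bin
#' `v > 0` is
#' `S[k, v] = (1/N) * sum_m X[(m+v) mod N] * exp(-2 pi^2 mt^2 / v^2) * exp(+i 2 pi m k / N)`
#' where `mt` is the symmetric alias of `m` (`m` for `m <= N/2`, else
#' `m - N`). The Gaussian voice narrows as 1/f in time — the window's
#' frequency-domain factor is `exp(-2 pi^2 m^2 / v^2)` — giving the
#' transform its multi-resolution character while retaining absolutely
#' referenced Fourier phase. The 0 Hz row follows
#' `config$zero_freq_rule`. Cost is O(rows * N log N).
#'
#' @param x real signal of length N >= 2.
#' @param fs sampling rate (Hz).
#' @param config an [st_config()].
#' @return An `st_matrix`: list with complex `values` (rows = frequency
#'   bins, columns = the N time samples), `freqs_hz`, `fs`.
#' @examples
#' s <- stockwell(cos(2 * pi * 5 * (0:199) / 100), fs = 100)
#' dim(s$values)
#' @export
stockwell <- function(x, fs, config = st_config()) {
  n <- length(x)
  if (n < 2) rlang::abort("signal must have at least 2 samples.")
  bins <- st_band_bins(n, fs, config)
  X <- stats::fft(x) / n
  m <- 0:(n - 1)
  mt <- symmetric_alias(m, n)
  vals <- matrix(0 + 0i, nrow = length(bins), ncol = n)
  pos <- bins[bins > 0]
  if (length(pos)) {
    # one shifted-spectrum * Gaussian column per voice, inverse FFTs batched
    shift_idx <- (outer(m, pos, `+`) %% n) + 1L          # [n, voices]
    gauss <- exp(-2 * pi^2 * outer(mt^2, pos^2, `/`))     # [n, voices]
    ymat <- matrix(X[shift_idx], nrow = n) * gauss
    rows <- t(stats::mvfft(ymat, inverse = TRUE))  # inverse w/o 1/N: X has it
    vals[match(pos, bins), ] <- rows
  }
  if (0 %in% bins && config$zero_freq_rule == "mean")
    vals[match(0, bins), ] <- mean(x) + 0i
  structure(list(values = vals, freqs_hz = bins * fs / n, fs = fs),
            class = "st_matrix")
}

#' Brute-force Stockwell transform (equivalence oracle)
#'
#' Same quantity as [stockwell()], evaluated by direct summation (DFT by
#' explicit nested sums via a full exponential matrix, no FFT anywhere).
#' Guarded to N <= 512; intended only for verification.
#'
#' @inheritParams stockwell
#' @export
brute_stockwell <- function(x, fs, config = st_config()) {
  n <- length(x)
  if (n < 2) rlang::abort("signal must have at least 2 samples.")
  if (n > 512) rlang::abort("brute_stockwell is guarded to N <= 512.")
  bins <- st_band_bins(n, fs, config)
  j <- 0:(n - 1)
  # direct forward DFT: X[k] = (1/N) sum_j x[j] e^{-i 2 pi k j / N}
  Ef <- exp(-2i * pi * outer(j, j) / n)
  X <- as.vector(Ef %*% x) / n
  mt <- symmetric_alias(j, n)
  Eb <- exp(+2i * pi * outer(j, j) / n)   # [k, m]
  vals <- matrix(0 + 0i, nrow = length(bins), ncol = n)
  for (r in seq_along(bins)) {
    v <- bins[r]
    if (v == 0) {
      if (config$zero_freq_rule == "mean") vals[r, ] <- mean(x) + 0i
    } else {
      y <- X[((j + v) %% n) + 1L] * exp(-2 * pi^2 * mt^2 / v^2)
      vals[r, ] <- as.vector(Eb %*% y)
    }
  }
  structure(list(values = vals, freqs_hz = bins * fs / n, fs = fs),
            class = "st_matrix")
}

#' Split an st_matrix into real/imaginary channels
#'
#' @param s an `st_matrix`.
#' @return A real array `[2, rows, cols]`: channel 1 the real part,
#'   channel 2 the imaginary part. Lossless; [st_recombine()] inverts it.
#' @export
to_channels <- function(s) {
  stopifnot(inherits(s, "st_matrix"))
  v <- s$values
  out <- array(0, dim = c(2, nrow(v), ncol(v)))
  out[1, , ] <- Re(v)
  out[2, , ] <- Im(v)
  out
}

#' Recombine real/imaginary channels into a complex matrix
#' @param ch an array `[2, rows, cols]` as produced by [to_channels()].
#' @export
st_recombine <- function(ch) {
  stopifnot(length(dim(ch)) == 3, dim(ch)[1] == 2)
  matrix(complex(real = ch[1, , ], imaginary = ch[2, , ]),
         nrow = dim(ch)[2])
}

#' @export
print.st_matrix <- function(x, ...) {
  cat(sprintf("<st_matrix> %d frequency rows (%.2f-%.2f Hz) x %d time samples @ %g Hz\n",
              nrow(x$values), min(x$freqs_hz), max(x$freqs_hz),
              ncol(x$values), x$fs))
  invisible(x)
}

#' Spectrogram-style plot of an S-transform magnitude
#'
#' @param object an `st_matrix`.
#' @param ... unused.
#' @export
autoplot.st_matrix <- function(object, ...) {
  mag <- Mod(object$values)
  df <- data.frame(
    time_s = rep((seq_len(ncol(mag)) - 1) / object$fs, each = nrow(mag)),
    freq_hz = rep(object$freqs_hz, times = ncol(mag)),
    magnitude = as.vector(mag)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$freq_hz,
                                   fill = .data$magnitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "|S|", title = "Stockwell transform magnitude") +
    ggplot2::theme_minimal()
}
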