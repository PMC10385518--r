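#' One-sided amplitude and power spectrum of a single channel
#'
#' Computes the rectangular-window FFT amplitude spectrum y(f) and the
#' corresponding power spectrum P(f) on the uniform grid 0, df, ..., fs/2
#' with df = fs / n_samples. Amplitudes use the peak-amplitude convention: a
#' unit sinusoid sitting exactly on a bin has y = 1 at that bin. Power uses
#' the mean-square convention (P = y^2 / 2 away from DC and Nyquist), so that
#' sum(P) equals the mean square of the signal (Parseval).
#'
#' @param x Numeric vector of samples.
#' @param sfreq Sampling rate in Hz.
#' @return A tibble of class `ssvep_spectrum` with columns `freq`, `amplitude`
#'   and `power`, plus attributes `df` and `sfreq`.
#' @export
amplitude_spectrum <- function(x, sfreq) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("input contains non-finite samples",
                               call. = FALSE)
  n <- length(x)
  X <- stats::fft(x)
  half <- floor(n / 2)                 # index of Nyquist bin when n is even
  mag <- Mod(X[seq_len(half + 1L)]) / n
  amp <- mag
  interior <- 2:(half + 1L)
  if (n %% 2 == 0) interior <- interior[-length(interior)]  # true Nyquist bin
  amp[interior] <- 2 * amp[interior]
  pow <- amp^2
  pow[interior] <- pow[interior] / 2
  out <- tibble::tibble(
    freq = (0:half) * sfreq / n,
    amplitude = amp,
    power = pow
  )
  attr(out, "df") <- sfreq / n
  attr(out, "sfreq") <- sfreq
  class(out) <- c("ssvep_spectrum", class(out))
  out
}

# Nearest grid index for a frequency; warns (once, via attribute on result)
# when the requested frequency is off-grid by more than df/2 is impossible by
# construction, so the caller checks misalignment itself.
nearest_bin <- function(spec, f0) {
  df <- attr(spec, "df")
  i <- which.min(abs(spec$freq - f0))
  if (abs(spec$freq[i] - f0) > df / 2 + 1e-12) {
    warning(sprintf("frequency %.4g Hz is off the spectral grid (df = %.4g Hz); using nearest bin %.4g Hz",
                    f0, df, spec$freq[i]), call. = FALSE)
  }
  i
}

#' Narrowband signal-to-noise ratio at a stimulation frequency
#'
#' The ratio, in dB, of the amplitude-spectrum value at the stimulation
#' frequency to the summed amplitudes of the neighbouring bins within 1 Hz on
#' either side:
#' \deqn{SNRt = 20 \log_{10} \frac{y(f_0)}{\sum_{k=1}^{1/df} y(f_0 - k\,df) + y(f_0 + k\,df)}}
#' All bins are read at the nearest grid point. A zero denominator (no noise
#' in the +-1 Hz band) returns `Inf`.
#'
#' @param spec An [amplitude_spectrum()] result.
#' @param f0 Stimulation frequency in Hz; `f0` and `f0 +- 1` Hz must lie on
#'   the grid span.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_narrowband <- function(spec, f0) {
  df <- attr(spec, "df")
  if (f0 - 1 < 0 || f0 + 1 > max(spec$freq) + df / 2) {
    stop("f0 and f0 +- 1 Hz must lie within the spectral grid", call. = FALSE)
  }
  i0 <- nearest_bin(spec, f0)
  kmax <- floor(1 / df + 1e-9)
  if (kmax < 1L) return(Inf)       # grid coarser than the 1 Hz neighbourhood
  ks <- seq_len(kmax)
  lo <- i0 - ks
  hi <- i0 + ks
  keep_lo <- lo >= 1L
  keep_hi <- hi <= nrow(spec)
  denom <- sum(spec$amplitude[lo[keep_lo]]) + sum(spec$amplitude[hi[keep_hi]])
  num <- spec$amplitude[i0]
  if (denom <= num * 1e-12) return(Inf)   # numerically zero neighbourhood
  20 * log10(num / denom)
}

#' Wideband signal-to-noise ratio of the stimulation response
#'
#' The ratio, in dB, of the summed power at the stimulation frequency and its
#' first `Nh` harmonics to the remaining broadband power between 1 Hz and the
#' Nyquist frequency:
#' \deqn{SNRw = 20 \log_{10} \frac{\sum_{k=1}^{N_h} P(k f_0)}{\sum_{f=1}^{f_s/2} P(f) - \sum_{k=1}^{N_h} P(k f_0)}}
#' Harmonic bins are read at the nearest grid points; the broadband sum runs
#' over all grid points in the interval [1 Hz, fs/2].
#'
#' @param spec An [amplitude_spectrum()] result.
#' @param f0 Stimulation frequency in Hz.
#' @param Nh Number of harmonics (including the fundamental). Default 5.
#' @return SNR in dB (`Inf` when all in-band power sits on the harmonics).
#' @export
snr_wideband <- function(spec, f0, Nh = 5) {
  sfreq <- attr(spec, "sfreq")
  if (Nh * f0 >= sfreq / 2) {
    stop(sprintf("harmonic %d x %.4g Hz = %.4g Hz is at or above Nyquist (%.4g Hz)",
                 Nh, f0, Nh * f0, sfreq / 2), call. = FALSE)
  }
  hbins <- vapply(seq_len(Nh) * f0, function(f) nearest_bin(spec, f),
                  integer(1))
  wide <- which(spec$freq >= 1 - 1e-12)
  num <- sum(spec$power[hbins])
  denom <- sum(spec$power[wide]) - sum(spec$power[intersect(hbins, wide)])
  if (denom <= num * 1e-12) return(Inf)   # all in-band power on harmonics
  20 * log10(num / denom)
}

#' Trial-averaged narrowband SNR per target
#'
#' Trials of the same target are averaged in the time domain first (coherent
#' averaging, which suppresses the non-phase-locked background), then the
#' narrowband SNR is computed at the chosen channel for each target's
#' stimulation frequency.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param channel Channel name or index to evaluate; defaults to the channel
#'   marked as the signal channel by the synthetic generator, else the first.
#' @return A tibble with one row per target (`target`, `frequency`,
#'   `snrt_db`) and attribute `mean_db` / `sd_db`.
#' @export
snr_narrowband_avg <- function(epochs, channel = NULL) {
  ch <- resolve_channel(epochs, channel)
  cb <- epochs$codebook
  rows <- purrr::map_dfr(seq_len(n_targets(cb)), function(tg) {
    idx <- which(epochs$labels == tg)
    if (length(idx) == 0L) {
      stop("no trials for target ", tg, call. = FALSE)
    }
    avg <- colMeans(epochs$data[idx, ch, , drop = FALSE], dims = 2)
    spec <- amplitude_spectrum(as.numeric(avg), epochs$sfreq)
    tibble::tibble(target = tg, frequency = cb$frequency[tg],
                   snrt_db = snr_narrowband(spec, cb$frequency[tg]))
  })
  finite <- rows$snrt_db[is.finite(rows$snrt_db)]
  attr(rows, "mean_db") <- mean(finite)
  attr(rows, "sd_db") <- stats::sd(finite)
  rows
}

#' Trial-averaged wideband SNR per target
#'
#' Same averaging convention as [snr_narrowband_avg()], applied to the
#' wideband ratio of [snr_wideband()].
#'
#' @inheritParams snr_narrowband_avg
#' @param Nh Number of harmonics. Default 5.
#' @return A tibble (`target`, `frequency`, `snrw_db`) with `mean_db` /
#'   `sd_db` attributes.
#' @export
snr_wideband_avg <- function(epochs, channel = NULL, Nh = 5) {
  ch <- resolve_channel(epochs, channel)
  cb <- epochs$codebook
  rows <- purrr::map_dfr(seq_len(n_targets(cb)), function(tg) {
    idx <- which(epochs$labels == tg)
    if (length(idx) == 0L) stop("no trials for target ", tg, call. = FALSE)
    avg <- colMeans(epochs$data[idx, ch, , drop = FALSE], dims = 2)
    spec <- amplitude_spectrum(as.numeric(avg), epochs$sfreq)
    tibble::tibble(target = tg, frequency = cb$frequency[tg],
                   snrw_db = snr_wideband(spec, cb$frequency[tg], Nh))
  })
  finite <- rows$snrw_db[is.finite(rows$snrw_db)]
  attr(rows, "mean_db") <- mean(finite)
  attr(rows, "sd_db") <- stats::sd(finite)
  rows
}

resolve_channel <- function(epochs, channel) {
  if (is.null(channel)) {
    sig <- attr(epochs, "signal_channel")
    if (!is.null(sig)) return(sig)
    oz <- match("Oz", epochs$channel_names)
    return(if (is.na(oz)) 1L else oz)
  }
  if (is.character(channel)) {
    i <- match(channel, epochs$channel_names)
    if (is.na(i)) {
      stop("channel \"", channel, "\" not found; available: ",
           paste(epochs$channel_names, collapse = ", "), call. = FALSE)
    }
    return(i)
  }
  ch <- as.integer(channel)
  if (ch < 1L || ch > n_channels(epochs)) {
    stop("channel index out of range", call. = FALSE)
  }
  ch
}
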