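#' Specification for the synthetic SSVEP generator
#'
#' Describes a frequency-phase-coded SSVEP recording to simulate: a steady
#' sinusoidal response at each target's frequency (plus harmonics with
#' decaying amplitude), delayed by the visual latency, projected across
#' channels with smooth gains peaking at an occipital-like signal channel,
#' and buried in pink + white background noise at a controlled narrowband
#' SNR.
#'
#' @param codebook Stimulus codebook from [make_codebook()].
#' @param n_blocks Number of blocks (repetitions of the full target set).
#' @param trials_per_target Trials per target within each block. Default 1.
#' @param n_channels Number of channels. Default 8.
#' @param sfreq Sampling rate, Hz. Default 250.
#' @param duration Epoch length in seconds, measured from stimulus onset;
#'   must give a whole number of samples. Default 3, typical of the public
#'   recordings and fine enough (df = 1/3 Hz) to resolve the 1 Hz
#'   neighbourhood of the narrowband SNR.
#' @param harmonic_amplitudes Relative gains of the fundamental and
#'   harmonics, fundamental first. Default `1 / (1:5)` (decaying harmonic
#'   energy, the standard SSVEP stylisation).
#' @param latency Visual response onset delay in seconds. Default 0.14, the
#'   latency the public wearable recordings document.
#' @param noise_pink_exponent Spectral exponent of the pink noise component
#'   (PSD proportional to 1/f^exponent). Default 1.
#' @param snr_db Target narrowband SNR (dB) at the signal channel, in
#'   expectation over noise realisations; `Inf` switches noise off.
#'   Default 0.
#' @param amplitude_jitter_sd Standard deviation of the per-trial
#'   multiplicative (lognormal) response amplitude jitter. Default 0.05.
#' @param signal_channel Index of the channel where the response peaks.
#'   Default: the channel closest to 3/4 of the montage.
#' @param seed Integer seed; generation is fully reproducible given the spec.
#'
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(codebook, n_blocks = 6, trials_per_target = 1,
                       n_channels = 8, sfreq = 250, duration = 3,
                       harmonic_amplitudes = 1 / (1:5), latency = 0.14,
                       noise_pink_exponent = 1, snr_db = 0,
                       amplitude_jitter_sd = 0.05,
                       signal_channel = NULL, seed = 1L) {
  if (!inherits(codebook, "ssvep_codebook")) {
    stop("`codebook` must be an ssvep_codebook", call. = FALSE)
  }
  n_samp <- duration * sfreq
  if (abs(n_samp - round(n_samp)) > 1e-9) {
    stop("duration x sfreq must be a whole number of samples (got ",
         n_samp, ")", call. = FALSE)
  }
  if (n_blocks < 1 || trials_per_target < 1) {
    stop("`n_blocks` and `trials_per_target` must be positive counts",
         call. = FALSE)
  }
  if (length(harmonic_amplitudes) == 0 || any(harmonic_amplitudes < 0)) {
    stop("`harmonic_amplitudes` must be non-empty and non-negative",
         call. = FALSE)
  }
  if (is.na(snr_db) || (!is.finite(snr_db) && snr_db < 0)) {
    stop("`snr_db` must be finite or +Inf", call. = FALSE)
  }
  structure(list(
    codebook = codebook, n_blocks = as.integer(n_blocks),
    trials_per_target = as.integer(trials_per_target),
    n_channels = as.integer(n_channels), sfreq = sfreq, duration = duration,
    harmonic_amplitudes = harmonic_amplitudes, latency = latency,
    noise_pink_exponent = noise_pink_exponent, snr_db = snr_db,
    amplitude_jitter_sd = amplitude_jitter_sd,
    signal_channel = as.integer(signal_channel %||%
                                  max(1L, round(n_channels * 0.75))),
    seed = as.integer(seed)
  ), class = "synth_spec")
}

#' Generate frequency-phase coded SSVEP epochs
#'
#' Simulates `trials_per_target x n_blocks x N` epochs according to a
#' [synth_spec()]. Each trial's response at the signal channel is
#' \deqn{s(t) = \sum_k a_k \sin(2\pi k f (t - \tau) + k\phi), \quad t \ge \tau,}
#' zero before the latency \eqn{\tau}, scaled so that the expected narrowband
#' SNR at the signal channel matches `snr_db`. The response is projected
#' onto the other channels with fixed smooth gains; every channel receives
#' independent pink + white noise (80% / 20% variance split). The epoch's
#' decoding origin is placed at stimulus onset + latency (`t0_offset =
#' -latency`), so extracted windows begin where the response does.
#'
#' @param spec A [synth_spec()].
#' @return An [ssvep_epochs()] object with attribute `signal_channel`.
#' @export
generate_epochs <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, generate_epochs_impl(spec))
}

generate_epochs_impl <- function(spec) {
  cb <- spec$codebook
  N <- n_targets(cb)
  n_trials <- spec$trials_per_target * spec$n_blocks * N
  ns <- round(spec$duration * spec$sfreq)
  nc <- spec$n_channels
  t <- (seq_len(ns) - 1) / spec$sfreq

  # unit-scale responses per target (signal channel waveform)
  sig <- matrix(0, N, ns)
  active <- t >= spec$latency
  for (tg in seq_len(N)) {
    f <- cb$frequency[tg]; ph <- cb$phase[tg]
    for (k in seq_along(spec$harmonic_amplitudes)) {
      if (k * f >= spec$sfreq / 2) next
      sig[tg, active] <- sig[tg, active] + spec$harmonic_amplitudes[k] *
        sin(2 * pi * k * f * (t[active] - spec$latency) + k * ph)
    }
  }

  # smooth channel gains peaking at the signal channel
  gains <- 0.25 + 0.75 * exp(-((seq_len(nc) - spec$signal_channel)^2) / 8)
  gains <- gains / gains[spec$signal_channel]

  noisy <- is.finite(spec$snr_db)
  noise <- array(0, c(n_trials, nc, ns))
  if (noisy) {
    for (i in seq_len(n_trials)) {
      for (ch in seq_len(nc)) {
        noise[i, ch, ] <- pink_white_noise(ns, spec$sfreq,
                                           spec$noise_pink_exponent)
      }
    }
  }

  # layout: blocks outermost, then repetition, then target
  labels <- rep(rep(seq_len(N), times = spec$trials_per_target),
                times = spec$n_blocks)
  blocks <- rep(seq_len(spec$n_blocks),
                each = N * spec$trials_per_target)

  alpha <- if (noisy) {
    calibrate_snr(sig, noise[, spec$signal_channel, , drop = FALSE], cb, spec)
  } else 1

  jitter <- if (spec$amplitude_jitter_sd > 0) {
    exp(stats::rnorm(n_trials, 0, spec$amplitude_jitter_sd))
  } else rep(1, n_trials)

  data <- noise
  for (i in seq_len(n_trials)) {
    s <- alpha * jitter[i] * sig[labels[i], ]
    data[i, , ] <- data[i, , ] + outer(gains, s)
  }

  ep <- ssvep_epochs(data, spec$sfreq, labels, blocks, cb,
                     channel_names = paste0("ch", seq_len(nc)),
                     t0_offset = -spec$latency)
  attr(ep, "signal_channel") <- spec$signal_channel
  ep
}

# Seeded pink + white noise with unit variance: pink part built in the
# frequency domain with random phases and amplitude f^(-exponent/2).
pink_white_noise <- function(n, sfreq, exponent, white_frac = 0.2) {
  half <- floor(n / 2)
  f <- (1:half) * sfreq / n
  mag <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  X <- complex(modulus = mag, argument = phase)
  full <- complex(real = numeric(n))
  full[2:(half + 1)] <- X
  if (n %% 2 == 0) full[half + 1] <- complex(real = mag[half])  # real Nyquist
  full[n:(n - half + 2)] <- Conj(X[seq_len(half - 1)])
  pink <- Re(stats::fft(full, inverse = TRUE)) / n
  pink <- pink / stats::sd(pink)
  white <- stats::rnorm(n)
  sqrt(1 - white_frac) * pink + sqrt(white_frac) * white
}

# Solve for the signal scale alpha so that the expected Eq.-(1)-style
# narrowband SNR at the signal channel matches spec$snr_db. Expectation over
# noise realisations: the per-bin amplitude of signal + independent noise is
# approximated in quadrature against the ensemble-mean noise spectrum.
calibrate_snr <- function(sig, sig_noise, cb, spec) {
  ns <- ncol(sig)
  n_trials <- dim(sig_noise)[1]
  # ensemble-mean noise amplitude spectrum (quadratic mean per bin)
  pow_acc <- NULL
  take <- seq_len(min(n_trials, 64L))
  for (i in take) {
    sp <- amplitude_spectrum(as.numeric(sig_noise[i, 1, ]), spec$sfreq)
    pow_acc <- if (is.null(pow_acc)) sp$amplitude^2 else
      pow_acc + sp$amplitude^2
  }
  noise_amp <- sqrt(pow_acc / length(take))
  grid_spec <- amplitude_spectrum(sig[1, ], spec$sfreq)  # for the grid
  df <- attr(grid_spec, "df")
  # at least the adjacent bins, so very short epochs still calibrate
  kmax <- max(1L, floor(1 / df + 1e-9))

  target_ratio <- 10^(spec$snr_db / 20)
  # expected SNR ratio at scale alpha, averaged over targets (linear domain)
  ratio_at <- function(alpha) {
    vals <- vapply(seq_len(nrow(sig)), function(tg) {
      samp <- amplitude_spectrum(alpha * sig[tg, ], spec$sfreq)$amplitude
      i0 <- which.min(abs(grid_spec$freq - cb$frequency[tg]))
      ks <- seq_len(kmax)
      nb <- c(i0 - ks, i0 + ks)
      nb <- nb[nb >= 1 & nb <= length(samp)]
      num <- sqrt(samp[i0]^2 + noise_amp[i0]^2)
      den <- sum(sqrt(samp[nb]^2 + noise_amp[nb]^2))
      num / den
    }, numeric(1))
    mean(vals)
  }
  fn <- function(la) log(ratio_at(exp(la))) - log(target_ratio)
  lo <- log(1e-8); hi <- log(1e8)
  if (fn(lo) >= 0) {
    # even a vanishing signal sits above the requested SNR: the narrowband
    # ratio has a noise floor of ~ -20*log10(2/df) dB set by the neighbour
    # bin count, which short epochs cannot go below
    warning("requested snr_db is below the narrowband noise floor for this epoch length; generating with zero signal amplitude",
            call. = FALSE)
    return(0)
  }
  if (fn(hi) <= 0) {
    # spectral leakage of the response itself bounds the achievable SNR
    warning("requested snr_db exceeds the leakage-limited ceiling; saturating the signal amplitude",
            call. = FALSE)
    return(exp(hi))
  }
  exp(stats::uniroot(fn, lower = lo, upper = hi, tol = 1e-10)$root)
}
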