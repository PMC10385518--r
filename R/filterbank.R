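#' Filter-bank specification
#'
#' The sub-band decomposition used by FBCCA, eTRCA and TDCA: five zero-phase
#' Chebyshev-I band-pass filters with passbands [8 m, 88] Hz for
#' m = 1..5 and sub-band weights w(n) = n^(-a) + b with a = 1.25, b = 0.25
#' (the published constants of the reference filter-bank design).
#'
#' @param n_bands Number of sub-bands. Default 5.
#' @param band_edges Optional list of `c(low, high)` passband edges in Hz;
#'   defaults to `[8 m, 88]` for m = 1..n_bands.
#' @param weight_a,weight_b Weight-curve parameters. Defaults 1.25 / 0.25.
#' @return A list of class `filterbank_spec`.
#' @export
filterbank_spec <- function(n_bands = 5, band_edges = NULL,
                            weight_a = 1.25, weight_b = 0.25) {
  if (is.null(band_edges)) {
    band_edges <- lapply(seq_len(n_bands), function(m) c(8 * m, 88))
  }
  if (length(band_edges) != n_bands) {
    stop("`band_edges` must have one (low, high) pair per band",
         call. = FALSE)
  }
  w <- seq_len(n_bands)^(-weight_a) + weight_b
  if (any(w <= 0)) stop("sub-band weights must be positive", call. = FALSE)
  structure(list(n_bands = as.integer(n_bands), band_edges = band_edges,
                 weight_a = weight_a, weight_b = weight_b, weights = w),
            class = "filterbank_spec")
}

# Design the m-th zero-phase band-pass: Chebyshev-I, order from cheb1ord
# with stopband edges at low/1.25 and high*1.25 (capped below Nyquist) and
# >= 40 dB stopband attenuation per pass (filtfilt doubles it).
design_band <- function(edges, sfreq) {
  nyq <- sfreq / 2
  lo <- edges[1]; hi <- edges[2]
  if (hi >= nyq) {
    stop(sprintf("band edge %.4g Hz is at or above Nyquist (%.4g Hz)",
                 hi, nyq), call. = FALSE)
  }
  wp <- c(lo, hi) / nyq
  ws <- c(max(lo / 1.25, 0.1), min(hi * 1.25, 0.98 * nyq)) / nyq
  ord <- signal::cheb1ord(Wp = wp, Ws = ws, Rp = 0.5, Rs = 40)
  signal::cheby1(ord)
}

#' Apply the filter bank to an epoch array
#'
#' Zero-phase band-pass filters every trial and channel per sub-band by
#' applying the squared magnitude response of the designed Chebyshev-I
#' filter in the frequency domain (the exact zero-phase equivalent of
#' forward-backward filtering, numerically stable at any filter order).
#' Signals are odd-reflection padded to suppress edge transients; length is
#' preserved.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param spec A [filterbank_spec()].
#' @return A list with one band-filtered [ssvep_epochs()] per sub-band.
#' @export
apply_filter_bank <- function(epochs, spec = filterbank_spec()) {
  stopifnot(inherits(epochs, "ssvep_epochs"),
            inherits(spec, "filterbank_spec"))
  d <- dim(epochs$data)
  # samples x (trials * channels) matrix, filtered column-wise in one pass
  M <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = d[3])
  lapply(seq_len(spec$n_bands), function(m) {
    filt <- design_band(spec$band_edges[[m]], epochs$sfreq)
    out <- epochs
    filtered <- zero_phase_cols(M, filt)
    out$data <- aperm(array(filtered, c(d[3], d[1], d[2])), c(2, 3, 1))
    out
  })
}

# zero-phase |H|^2 filtering of the columns of M, with odd-reflection
# padding of (nrow - 1) samples on both ends
zero_phase_cols <- function(M, filt) {
  n <- nrow(M)
  P <- n - 1L
  K <- ncol(M)
  top <- 2 * matrix(M[1L, ], P, K, byrow = TRUE) -
    M[(P + 1L):2L, , drop = FALSE]
  bot <- 2 * matrix(M[n, ], P, K, byrow = TRUE) -
    M[(n - 1L):(n - P), , drop = FALSE]
  Xp <- rbind(top, M, bot)
  nfft <- nrow(Xp)
  G <- zp_gain(filt, nfft)
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * G, inverse = TRUE)) / nfft
  Y[(P + 1L):(P + n), , drop = FALSE]
}

# squared magnitude response of an ARMA filter on the length-nfft DFT grid
zp_gain <- function(filt, nfft) {
  B <- stats::fft(c(filt$b, numeric(nfft - length(filt$b))))
  A <- stats::fft(c(filt$a, numeric(nfft - length(filt$a))))
  Mod(B / A)^2
}

# filter a channels x samples matrix with a prepared filter
filter_matrix <- function(X, filt) {
  t(zero_phase_cols(t(X), filt))
}

# prepared per-band filters for a given sampling rate
band_filters <- function(spec, sfreq) {
  lapply(spec$band_edges, design_band, sfreq = sfreq)
}
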