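#' Canonical sinusoidal reference signals
#'
#' Builds, for every codebook target, the 2*Nh x n_samples matrix of
#' sin/cos pairs at the target frequency and its harmonics:
#' row 2k-1 = sin(2 pi k f t + k phase), row 2k = cos(...). The phase term
#' is included when `use_phase` is `TRUE` and the codebook carries phases;
#' the training-free decoders are insensitive to it because sin/cos pairs
#' span every phase.
#'
#' @param codebook An [make_codebook()] codebook.
#' @param Nh Harmonic count (fundamental included). Default 5.
#' @param sfreq Sampling rate, Hz.
#' @param n_samples Number of samples on the grid t = 0, 1/fs, ...
#' @param use_phase Include the codebook phases. Default `TRUE`.
#' @return A list of class `reference_set`: per-target matrices plus the
#'   construction parameters.
#' @export
build_references <- function(codebook, Nh = 5, sfreq, n_samples,
                             use_phase = TRUE) {
  stopifnot(inherits(codebook, "ssvep_codebook"))
  bad <- which(Nh * codebook$frequency >= sfreq / 2)
  if (length(bad) > 0L) {
    stop(sprintf("harmonic %d of target %d (%.4g Hz -> %.4g Hz) is at or above Nyquist (%.4g Hz)",
                 Nh, bad[1], codebook$frequency[bad[1]],
                 Nh * codebook$frequency[bad[1]], sfreq / 2), call. = FALSE)
  }
  t <- (seq_len(n_samples) - 1) / sfreq
  refs <- lapply(seq_len(n_targets(codebook)), function(tg) {
    f <- codebook$frequency[tg]
    ph <- if (use_phase) codebook$phase[tg] else 0
    m <- matrix(0, 2 * Nh, n_samples)
    for (k in seq_len(Nh)) {
      m[2 * k - 1, ] <- sin(2 * pi * k * f * t + k * ph)
      m[2 * k, ] <- cos(2 * pi * k * f * t + k * ph)
    }
    m
  })
  # cache the reference-side CCA factors (centred rows and the inverse of
  # the ridged reference covariance) so classification reuses them
  prep <- lapply(refs, function(Y) {
    Yc <- Y - rowMeans(Y)
    Cyy <- ridge(tcrossprod(Yc) / n_samples)
    list(Yc = Yc, Myy = chol2inv(chol(Cyy)))
  })
  structure(list(refs = refs, prep = prep, Nh = Nh, sfreq = sfreq,
                 n_samples = n_samples, phases_used = use_phase,
                 codebook = codebook),
            class = "reference_set")
}
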