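# Shared fixtures, built in code and cached across test files.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

cb3 <- function() {
  make_codebook("custom", frequencies = c(10, 12, 15),
                phases = c(0, pi / 2, pi))
}

# noiseless 3-target recording long enough for 2 s windows
noiseless_epochs <- function() {
  cached("noiseless", {
    generate_epochs(synth_spec(cb3(), n_blocks = 4, duration = 2.2,
                               snr_db = Inf, seed = 42))
  })
}

# moderate-SNR 3-target recording for stochastic checks
midsnr_epochs <- function(seed = 7) {
  cached(paste0("midsnr", seed), {
    generate_epochs(synth_spec(cb3(), n_blocks = 6, duration = 1.5,
                               snr_db = 0, seed = seed))
  })
}

# dense grid-search oracle for the first canonical correlation of 2-row
# matrices: maximise |corr(a'X, b'Y)| over unit vectors a, b
cca_grid_oracle <- function(X, Y, K = 2000) {
  theta <- seq(0, pi, length.out = K)
  U <- rbind(cos(theta), sin(theta))
  proj <- function(A, M) {
    P <- crossprod(A, M)             # K x samples combinations
    P <- P - rowMeans(P)
    P / sqrt(rowSums(P^2))
  }
  Px <- proj(U, X)
  Py <- proj(U, Y)
  max(abs(tcrossprod(Px, Py)))
}

# literal bin-by-bin reimplementations of the two SNR definitions,
# independent of the package's vectorised versions
literal_snrt <- function(x, sfreq, f0) {
  n <- length(x)
  amp <- Mod(stats::fft(x))[1:(floor(n / 2) + 1)] / n
  idx <- 2:(floor(n / 2) + 1)
  if (n %% 2 == 0) idx <- idx[-length(idx)]
  amp[idx] <- 2 * amp[idx]
  freqs <- (0:floor(n / 2)) * sfreq / n
  df <- sfreq / n
  i0 <- which.min(abs(freqs - f0))
  den <- 0
  for (k in 1:floor(1 / df + 1e-9)) {
    if (i0 - k >= 1) den <- den + amp[i0 - k]
    if (i0 + k <= length(amp)) den <- den + amp[i0 + k]
  }
  20 * log10(amp[i0] / den)
}

literal_snrw <- function(x, sfreq, f0, Nh = 5) {
  n <- length(x)
  amp <- Mod(stats::fft(x))[1:(floor(n / 2) + 1)] / n
  idx <- 2:(floor(n / 2) + 1)
  if (n %% 2 == 0) idx <- idx[-length(idx)]
  amp[idx] <- 2 * amp[idx]
  pow <- amp^2
  pow[idx] <- pow[idx] / 2
  freqs <- (0:floor(n / 2)) * sfreq / n
  hb <- sapply(1:Nh, function(k) which.min(abs(freqs - k * f0)))
  num <- 0
  for (i in hb) num <- num + pow[i]
  den <- 0
  for (i in seq_along(freqs)) {
    if (freqs[i] >= 1 - 1e-12 && !(i %in% hb)) den <- den + pow[i]
  }
  20 * log10(num / den)
}

# exhaustive-scan oracles for the selection rules on an accuracy curve
oracle_t_best <- function(windows, accs) {
  for (i in seq_along(windows)) {
    if (accs[i] >= 0.9) return(windows[i])
  }
  0.9 * windows[length(windows)] / accs[length(accs)]
}

oracle_itr_best <- function(windows, accs, N) {
  best <- -Inf
  any_hit <- FALSE
  for (i in seq_along(windows)) {
    if (accs[i] >= 0.9) {
      any_hit <- TRUE
      v <- as.numeric(itr(N, accs[i], windows[i]))
      if (v > best) best <- v
    }
  }
  if (any_hit) return(best)
  as.numeric(itr(N, accs[length(accs)], windows[length(windows)]))
}
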