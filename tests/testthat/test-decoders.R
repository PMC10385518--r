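test_that("reference rows are exact sin/cos harmonics", {
  cb <- make_codebook("custom", frequencies = c(10, 11, 12),
                      phases = c(0, 0, 0))
  refs <- build_references(cb, Nh = 1, sfreq = 250, n_samples = 250)
  Y <- refs$refs[[1]]
  expect_equal(dim(Y), c(2, 250))
  # exactly 10 cycles in one second: endpoints wrap
  t <- (0:249) / 250
  expect_equal(Y[1, ], sin(2 * pi * 10 * t))
  expect_equal(Y[2, ], cos(2 * pi * 10 * t))
  # sin/cos rows of one harmonic are orthogonal on whole-cycle windows
  expect_lt(abs(sum(Y[1, ] * Y[2, ])), 1e-9)
})

test_that("harmonics above Nyquist are refused with the target named", {
  cb <- make_codebook("custom", frequencies = c(10, 120), phases = c(0, 0))
  expect_error(build_references(cb, Nh = 2, sfreq = 250, n_samples = 250),
               "target 2")
})

test_that("canonical correlation is exact on identity and invariant to mixing", {
  withr::with_seed(10, X <- matrix(stats::rnorm(2 * 80), 2))
  expect_equal(cca_correlation(X, X), 1, tolerance = 1e-6)
  withr::with_seed(11, {
    Y <- matrix(stats::rnorm(2 * 80), 2)
    A <- matrix(stats::rnorm(4), 2)
  })
  while (abs(det(A)) < 0.1) A <- matrix(stats::rnorm(4), 2)
  expect_equal(cca_correlation(A %*% X, Y), cca_correlation(X, Y),
               tolerance = 1e-6)
})

test_that("canonical correlation matches a dense grid-search oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      X <- matrix(stats::rnorm(2 * 40), 2)
      Y <- matrix(stats::rnorm(2 * 40), 2)
    })
    expect_equal(cca_correlation(X, Y), cca_grid_oracle(X, Y),
                 tolerance = 1e-3)
  }
})

test_that("CCA classification recovers pure and noiseless signals", {
  cb <- make_codebook("custom", frequencies = c(10, 11, 12),
                      phases = c(0, 0, 0))
  refs <- build_references(cb, Nh = 2, sfreq = 250, n_samples = 500)
  t <- (0:499) / 250
  epoch <- rbind(sin(2 * pi * 10 * t + 0.3), cos(2 * pi * 10 * t + 1.1))
  expect_equal(cca_classify(epoch, refs), 1L)
  expect_error(cca_classify(matrix(0, 2, 500), refs), "degenerate")
  expect_error(cca_classify(epoch[, 1:250],
                            refs), "samples")
})

test_that("filter-bank sub-bands attenuate out-of-band energy by 40 dB", {
  fs <- 250
  spec <- filterbank_spec()
  withr::with_seed(20, x <- stats::rnorm(8 * fs))
  # Hann-tapered periodograms: the rectangular window's leakage skirts
  # would otherwise mask the true stopband floor
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_along(x) / (length(x) + 1))
  for (m in c(2, 4)) {
    filt <- ssvepkit:::design_band(spec$band_edges[[m]], fs)
    y <- as.numeric(ssvepkit:::filter_matrix(matrix(x, 1), filt))
    spx <- amplitude_spectrum(x * hann, fs)
    spy <- amplitude_spectrum(y * hann, fs)
    lo <- spec$band_edges[[m]][1]
    pass <- spx$freq >= lo * 1.1 & spx$freq <= 80
    stopb <- spx$freq <= lo / 1.25 & spx$freq >= 1
    gain_pass <- sum(spy$power[pass]) / sum(spx$power[pass])
    gain_stop <- sum(spy$power[stopb]) / sum(spx$power[stopb])
    expect_gt(10 * log10(gain_pass / gain_stop), 40)
  }
})

test_that("DC input is suppressed by every sub-band", {
  cb <- cb3()
  ep <- ssvep_epochs(array(1, c(2, 2, 250)), 250, c(1, 2), c(1, 1), cb)
  out <- apply_filter_bank(ep, filterbank_spec())
  for (bep in out) {
    expect_lt(max(abs(bep$data)), 1e-6)
    expect_equal(dim(bep$data), dim(ep$data))
  }
})

test_that("band edges above Nyquist are refused", {
  ep <- noiseless_epochs()
  bad <- filterbank_spec(n_bands = 1, band_edges = list(c(8, 130)))
  expect_error(apply_filter_bank(ep, bad), "Nyquist")
})

test_that("single-band unit-weight FBCCA ranks exactly like CCA", {
  ep <- midsnr_epochs()
  w <- extract_window(ep, 0, 1)
  refs <- build_references(ep$codebook, 5, ep$sfreq, n_samples(w))
  one_band <- filterbank_spec(n_bands = 1,
                              band_edges = list(c(8, 88)),
                              weight_a = 0, weight_b = 0)
  one_band$weights <- 1
  filts <- ssvepkit:::band_filters(one_band, ep$sfreq)
  for (i in seq_len(n_trials(w))) {
    X <- ssvepkit:::trial_matrix(w, i)
    Xf <- ssvepkit:::filter_matrix(X, filts[[1]])
    expect_equal(fbcca_classify(X, refs, one_band, sfreq = ep$sfreq),
                 cca_classify(Xf, refs))
  }
})

test_that("all four decoders are perfect on noiseless data at 0.5/1/2 s", {
  ep <- noiseless_epochs()
  for (alg in c("cca", "fbcca", "etrca", "tdca")) {
    for (win in c(0.5, 1, 2)) {
      acc <- attr(crossval_accuracy(ep, alg, window = win),
                  "pooled_accuracy")
      expect_equal(acc, 1, info = paste(alg, win))
    }
  }
})

test_that("eTRCA needs two trials per target and weights the signal channel", {
  ep <- noiseless_epochs()
  single <- ssvepkit:::subset_trials(ep, which(ep$blocks == 1))
  expect_error(etrca_fit(extract_window(single, 0, 1)), "fewer than 2")

  # 2-channel toy: common signal on channel 1, independent noise on 2
  cb <- cb3()
  n <- 250; t <- (0:(n - 1)) / 250
  withr::with_seed(30, {
    dat <- array(0, c(6, 2, n))
    for (i in 1:6) {
      tg <- ((i - 1) %% 3) + 1
      s <- sin(2 * pi * cb$frequency[tg] * t) +
        0.5 * sin(2 * pi * 2 * cb$frequency[tg] * t)
      dat[i, 1, ] <- s + 0.05 * stats::rnorm(n)
      dat[i, 2, ] <- stats::rnorm(n)
    }
  })
  toy <- ssvep_epochs(dat, 250, rep(1:3, 2), rep(1:2, each = 3), cb)
  one_band <- filterbank_spec(n_bands = 1, band_edges = list(c(8, 88)))
  model <- etrca_fit(toy, one_band)
  W <- model$bands[[1]]$W
  expect_true(all(abs(W[1, ]) > abs(W[2, ])))
  # self-classification is perfect
  pred <- vapply(1:6, function(i) {
    etrca_classify(ssvepkit:::trial_matrix(toy, i), model)
  }, integer(1))
  expect_equal(pred, toy$labels)
})

test_that("degenerate epochs and length mismatches are refused", {
  ep <- noiseless_epochs()
  w <- extract_window(ep, 0, 1)
  model <- etrca_fit(ssvepkit:::subset_trials(w, which(w$blocks != 4)))
  expect_error(etrca_classify(matrix(0, 8, 250), model), "degenerate")
  expect_error(etrca_classify(matrix(1, 8, 100), model), "samples")
})

test_that("TDCA delay augmentation follows the 0.1 s step rule", {
  ep <- noiseless_epochs()
  # window 0.5 s + Np 0.5 s: delays 0.1..0.5 s, i.e. 5 delayed copies
  train <- extract_window(ep, 0, 1.0)
  model <- tdca_fit(train, Np = 0.5, n_components = 9,
                    spec = filterbank_spec(n_bands = 2))
  expect_equal(model$l, 5)
  expect_equal(model$n_samples, 125)
  expect_error(tdca_fit(extract_window(ep, 0, 0.3), Np = 0.5),
               "maximum supported Np")
  expect_error(tdca_fit(train, Np = 0.5, n_components = 100),
               "exceeds the augmented")
})

test_that("TDCA ranking is invariant to global amplitude scaling", {
  ep <- midsnr_epochs()
  w <- extract_window(ep, 0, 1)
  train <- ssvepkit:::subset_trials(ep, which(ep$blocks != 1))
  fb2 <- filterbank_spec(n_bands = 2)
  model <- tdca_fit(extract_window(train, 0, 1.3), Np = 0.3,
                    n_components = 9, spec = fb2)
  for (i in which(ep$blocks == 1)) {
    X <- ssvepkit:::trial_matrix(w, i)
    expect_equal(tdca_classify(X, model), tdca_classify(100 * X, model))
  }
})

test_that("classifiers are equivariant under codebook permutation", {
  ep <- midsnr_epochs()
  w <- extract_window(ep, 0, 1)
  perm <- c(3L, 1L, 2L)              # new index of each old target
  cbp <- make_codebook("custom",
                       frequencies = ep$codebook$frequency[order(perm)],
                       phases = ep$codebook$phase[order(perm)])
  refs <- build_references(ep$codebook, 5, ep$sfreq, n_samples(w))
  refsp <- build_references(cbp, 5, ep$sfreq, n_samples(w))
  for (i in seq_len(min(6, n_trials(w)))) {
    X <- ssvepkit:::trial_matrix(w, i)
    expect_equal(cca_classify(X, refsp), perm[cca_classify(X, refs)])
  }
})
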