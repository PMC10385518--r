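test_that("ITR reproduces the published worked values at 1 d.p.", {
  cells <- list(
    list(N = 40, P = 1.000, expected = 127.7),
    list(N = 12, P = 1.000, expected = 86.0),
    list(N = 9,  P = 1.000, expected = 76.1),
    list(N = 12, P = 0.378, expected = 11.4),
    list(N = 40, P = 0.650, expected = 60.9),
    list(N = 12, P = 0.956, expected = 76.1)
  )
  for (cell in cells) {
    expect_equal(round(as.numeric(itr(cell$N, cell$P, window = 2)), 1),
                 cell$expected)
  }
})

test_that("ITR limits and flags behave at the edges", {
  expect_equal(as.numeric(itr(12, 1 / 12, 2)), 0, tolerance = 1e-12)
  expect_equal(as.numeric(itr(40, 0, 2)),
               60 / 2.5 * (log2(40) + log2(1 / 39)), tolerance = 1e-12)
  # the bits term is convex with its minimum (exactly 0) at chance level,
  # so below-chance accuracies are flagged rather than negative
  below <- itr(12, 0.01, 2)
  expect_true(isTRUE(attr(below, "below_chance")))
  expect_gte(as.numeric(below), 0)
  expect_null(attr(itr(12, 0.5, 2), "below_chance"))
  expect_error(itr(1, 0.5, 2), ">= 2")
  expect_error(itr(12, 1.5, 2), "\\[0, 1\\]")
  expect_error(itr(12, 0.5, 0), "positive")
})

test_that("ITR is increasing in accuracy and decreasing in window", {
  N <- 12
  ps <- seq(1 / N + 0.01, 1, length.out = 50)
  vals <- vapply(ps, function(p) as.numeric(itr(N, p, 1)), numeric(1))
  expect_true(all(diff(vals) > 0))
  ws <- seq(0.2, 5, by = 0.2)
  vals <- vapply(ws, function(w) as.numeric(itr(N, 0.95, w)), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("T_best picks the first 90% crossing or extrapolates", {
  c1 <- ssvepkit:::new_accuracy_curve(seq(0.2, 1.2, 0.2),
                                      c(0.3, 0.5, 0.7, 0.85, 0.92, 0.95))
  expect_equal(t_best(c1), 1.0)
  c2 <- ssvepkit:::new_accuracy_curve(c(1, 2), c(0.4, 0.6))
  expect_equal(t_best(c2), 0.9 * 2 / 0.6)
  c3 <- ssvepkit:::new_accuracy_curve(seq(0.2, 1, 0.2), rep(1, 5))
  expect_equal(t_best(c3), 0.2)
  c4 <- ssvepkit:::new_accuracy_curve(c(1, 2), c(0, 0))
  expect_equal(t_best(c4), Inf)
})

test_that("selection rules agree with exhaustive-scan oracles on random curves", {
  withr::with_seed(99, {
    for (r in 1:200) {
      k <- sample(2:10, 1)
      windows <- sort(stats::runif(k, 0.2, 6))
      accs <- stats::runif(k)
      if (r %% 3 == 0) accs <- pmin(1, accs + 0.5)   # some high curves
      N <- sample(c(4, 9, 12, 40), 1)
      curve <- ssvepkit:::new_accuracy_curve(windows, accs)
      expect_equal(t_best(curve), oracle_t_best(windows, accs))
      expect_equal(itr_best(curve, N), oracle_itr_best(windows, accs, N))
    }
  })
})

test_that("accuracy curves are flat at 100% on noiseless data", {
  ep <- noiseless_epochs()
  curve <- accuracy_curve(ep, "fbcca", windows = c(0.5, 1, 2))
  expect_equal(curve$accuracy, c(1, 1, 1))
  expect_equal(attr(curve, "Tmax"), 2)
  expect_equal(t_best(curve), 0.5)
  expect_error(accuracy_curve(ep, "fbcca", windows = numeric(0)), "empty")
  expect_error(accuracy_curve(ep, "fbcca", windows = c(1, 0.5)),
               "increasing")
})

test_that("the standard accuracy uses a 2 s window, capped by the extent", {
  ep <- noiseless_epochs()          # extent 2.06 s
  a <- acc_standard(ep)
  expect_equal(attr(a, "window"), 2)
  expect_equal(as.numeric(a), 1)
  short <- extract_window(ep, 0, 1.9)
  a2 <- acc_standard(short)
  expect_equal(attr(a2, "window"), 1.9)
  # consistency with the curve at the same window
  curve <- accuracy_curve(short, "fbcca", windows = c(1, 1.9))
  expect_equal(as.numeric(a2), curve$accuracy[2])
})

test_that("the full index report holds together on noiseless data", {
  ep <- noiseless_epochs()
  rep <- evaluate_indexes(ep, windows = c(0.5, 1, 2))
  expect_equal(rep$acc_stand, 1)
  expect_equal(rep$t_best, 0.5)
  expect_equal(rep$n_targets, 3)
  # noise-free yet leakage-limited: off-grid stimulation frequencies leak
  # into the +-1 Hz neighbourhood, so the SNR is high but finite
  expect_gt(rep$snrt_db, 3)
  expect_equal(rep$itr_best, as.numeric(itr(3, 1, 0.5)))
})
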