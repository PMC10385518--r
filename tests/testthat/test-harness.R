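test_that("leave-one-block-out produces one fold per block, no leakage", {
  ep <- noiseless_epochs()
  cv <- crossval_accuracy(ep, "etrca", window = 1)
  expect_equal(nrow(cv), length(unique(ep$blocks)))
  preds <- attr(cv, "predictions")
  # every trial is tested exactly once, in the fold of its own block
  expect_setequal(preds$trial, seq_len(n_trials(ep)))
  blocks <- sort(unique(ep$blocks))
  expect_equal(preds$block, blocks[preds$fold])
  expect_equal(attr(cv, "pooled_accuracy"), 1)
})

test_that("training-free decoders run as a single fold on all trials", {
  ep <- noiseless_epochs()
  cv <- crossval_accuracy(ep, "cca", window = 0.5)
  expect_equal(nrow(cv), 1)
  expect_equal(cv$n_trials, n_trials(ep))
  expect_equal(attr(cv, "pooled_accuracy"), 1)
})

test_that("trained decoders refuse single-block recordings", {
  ep <- noiseless_epochs()
  single <- ssvepkit:::subset_trials(ep, which(ep$blocks == 1))
  expect_error(crossval_accuracy(single, "etrca", window = 1), "2 blocks")
})

test_that("pooled accuracy is invariant to trial order within blocks", {
  ep <- midsnr_epochs()
  withr::with_seed(55, perm <- sample(n_trials(ep)))
  shuffled <- ssvepkit:::subset_trials(ep, perm)
  a1 <- attr(crossval_accuracy(ep, "etrca", window = 1),
             "pooled_accuracy")
  a2 <- attr(crossval_accuracy(shuffled, "etrca", window = 1),
             "pooled_accuracy")
  expect_equal(a1, a2)
})

test_that("best/worst subject selection ranks by pooled accuracy", {
  results <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3"), 2),
    algorithm = rep(c("cca", "fbcca"), each = 3),
    accuracy = c(0.5, 0.9, 0.7, 0.6, 0.6, 0.95)
  )
  bw <- best_worst(results, N = 12, window = 2)
  cca_rows <- bw[bw$algorithm == "cca", ]
  expect_equal(cca_rows$subject[cca_rows$which == "worst"], "s1")
  expect_equal(cca_rows$subject[cca_rows$which == "best"], "s2")
  expect_true(all(bw$accuracy[bw$which == "best"] >=
                    bw$accuracy[bw$which == "worst"]))
  expect_equal(bw$itr[bw$algorithm == "cca" & bw$which == "best"],
               as.numeric(itr(12, 0.9, 2)))
  # ties break toward the first subject
  tied <- tibble::tibble(subject = c("s1", "s2"),
                         algorithm = "cca", accuracy = c(0.8, 0.8))
  bw2 <- best_worst(tied, 12, 2)
  expect_equal(unique(bw2$subject), "s1")
})

test_that("paired comparisons match a hand-computed t and Bonferroni", {
  # differences (0.10, 0.12, 0.08): t = 0.10 / (0.02 / sqrt(3)) = 8.660
  results <- tibble::tibble(
    subject = rep(c("s1", "s2", "s3"), 2),
    algorithm = rep(c("a", "b"), each = 3),
    accuracy = c(0.80, 0.85, 0.78, 0.70, 0.73, 0.70)
  )
  cmp <- compare_algorithms(results, bonferroni_m = 6)
  expect_equal(cmp$t, 8.660254, tolerance = 1e-6)
  expect_equal(cmp$p_corrected, min(1, 6 * cmp$p_raw))
  expect_gte(cmp$p_corrected, cmp$p_raw)

  same <- tibble::tibble(subject = rep(c("s1", "s2", "s3"), 2),
                         algorithm = rep(c("a", "b"), each = 3),
                         accuracy = rep(c(0.8, 0.9, 0.7), 2))
  cmp2 <- compare_algorithms(same)
  expect_equal(cmp2$p_raw, 1)
  expect_equal(cmp2$significance, "N.S.")

  expect_error(compare_algorithms(results[1:5, ]), "same subject")
  expect_error(compare_algorithms(results[c(1, 2, 4, 5), ]),
               "3 subjects")
})

test_that("end-to-end grading is deterministic and spans levels", {
  ep_hi <- cached("grade_hi", {
    generate_epochs(synth_spec(cb3(), n_blocks = 6, duration = 1.5,
                               snr_db = 10, seed = 70))
  })
  g1 <- evaluate_and_grade(ep_hi, windows = c(0.5, 1.0))
  g2 <- evaluate_and_grade(ep_hi, windows = c(0.5, 1.0))
  expect_identical(g1$scorecard$total, g2$scorecard$total)
  expect_s3_class(g1$scorecard, "scorecard")
  expect_true(g1$scorecard$level %in% LETTERS[1:5])
})

test_that("cohort grading supports both aggregation modes", {
  cohort <- cached("grade_cohort", {
    lapply(c(81, 82), function(s) {
      generate_epochs(synth_spec(cb3(), n_blocks = 4, duration = 1.5,
                                 snr_db = 5, seed = s))
    })
  })
  per <- evaluate_and_grade(cohort, aggregation = "per-subject",
                            windows = c(0.5, 1.0))
  pooled <- evaluate_and_grade(cohort, aggregation = "pooled",
                               windows = c(0.5, 1.0))
  expect_equal(nrow(per$report), 2)
  expect_s3_class(per$scorecard, "scorecard")
  expect_s3_class(pooled$scorecard, "scorecard")
  # per-subject total = mean of the subjects' totals
  cards <- vapply(seq_len(2), function(i) {
    grade_dataset(per$report[i, ])$total
  }, numeric(1))
  expect_equal(per$scorecard$total, mean(cards), tolerance = 1e-9)
})

test_that("tidy and glance surfaces expose the result tables", {
  ep <- noiseless_epochs()
  cv <- crossval_accuracy(ep, "cca", window = 0.5)
  expect_named(glance(cv), c("algorithm", "window", "n_folds", "accuracy"))
  curve <- ssvepkit:::new_accuracy_curve(c(0.5, 1), c(0.8, 0.95))
  expect_equal(nrow(tidy(curve)), 2)
  expect_equal(glance(curve)$t_best, 1)
  card <- total_and_level(10, 10, 20, 10, 20)
  td <- tidy(card)
  expect_equal(sum(td$points), glance(card)$total)
  expect_s3_class(autoplot(curve), "ggplot")
  expect_s3_class(autoplot(card), "ggplot")
})
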