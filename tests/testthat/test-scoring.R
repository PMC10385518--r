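test_that("score functions hit their printed boundary values", {
  expect_equal(score_snrt(-10), 0)
  expect_equal(round(score_snrt(10)), 20)
  expect_equal(score_snrt(12), 20)
  expect_equal(score_snrt(0), 15.1 * log10(11), tolerance = 1e-12)

  expect_equal(score_snrw(-40), 0)
  expect_equal(score_snrw(-10), 15)
  expect_equal(score_snrw(-25), 10 * log10(16), tolerance = 1e-12)

  expect_equal(score_acc(50), 0)
  expect_equal(score_acc(90), 25)
  expect_equal(score_acc(70), 15.5 * log10(21), tolerance = 1e-12)

  expect_equal(score_tbest(1.5, 40), 15)
  expect_equal(score_tbest(9, 40), 0)
  expect_equal(score_tbest(3, 40), 19 - 21.5 * log10(3) + log10(40),
               tolerance = 1e-12)

  expect_equal(score_itr(30), 0)
  expect_equal(score_itr(29), 0)
  expect_equal(score_itr(100), 25)   # 14 log10(71) = 25.9, clamped
  expect_equal(score_itr(60), 14 * log10(31), tolerance = 1e-12)
})

test_that("infinite sentinels map to the caps", {
  expect_equal(score_snrt(Inf), 20)
  expect_equal(score_snrw(Inf), 15)
  expect_equal(score_tbest(Inf, 40), 0)
  expect_equal(score_itr(Inf), 25)
})

test_that("each score is monotone and confined to its cap", {
  withr::with_seed(7, {
    snrts <- sort(stats::runif(100, -20, 20))
    expect_true(all(diff(vapply(snrts, score_snrt, numeric(1))) >= 0))
    snrws <- sort(stats::runif(100, -50, 5))
    expect_true(all(diff(vapply(snrws, score_snrw, numeric(1))) >= 0))
    accs <- sort(stats::runif(100, 0, 100))
    expect_true(all(diff(vapply(accs, score_acc, numeric(1))) >= 0))
    ts <- sort(stats::runif(100, 0.5, 10))
    s4 <- vapply(ts, score_tbest, numeric(1), C = 12)
    expect_true(all(diff(s4) <= 0))
    itrs <- sort(stats::runif(100, 0, 150))
    expect_true(all(diff(vapply(itrs, score_itr, numeric(1))) >= 0))
  })
  # score4 nondecreasing in the target count
  expect_true(all(diff(vapply(c(2, 10, 40, 160), score_tbest,
                              numeric(1), t = 4)) >= 0))
  expect_true(all(vapply(seq(-20, 20, 0.5), score_snrt,
                         numeric(1)) <= 20))
  expect_true(all(vapply(seq(0, 200, 5), score_itr, numeric(1)) <= 25))
})

test_that("the caps sum to a percentage scale", {
  expect_equal(score_snrt(Inf) + score_snrw(Inf) + score_acc(100) +
                 score_tbest(0.1, 2) + score_itr(Inf), 100)
})

test_that("published per-index scores total to the published grades", {
  card <- total_and_level(4.9, 0.4, 12.4, 8.9, 9.7)
  expect_equal(card$total, 36.3, tolerance = 1e-9)
  expect_equal(card$level, "E")
  card <- total_and_level(11.6, 5.6, 24.0, 13.8, 24.5)
  expect_equal(card$total, 79.5, tolerance = 1e-9)
  expect_equal(card$level, "B")
  card <- total_and_level(0, 0, 0, 0, 0)
  expect_equal(card$total, 0)
  expect_equal(card$level, "E")
})

test_that("difficulty bins partition [0, 100] without gaps", {
  expect_equal(difficulty_level(100), "A")
  expect_equal(difficulty_level(85), "A")
  expect_equal(difficulty_level(84.999), "B")
  expect_equal(difficulty_level(70), "B")
  expect_equal(difficulty_level(69.999), "C")
  expect_equal(difficulty_level(55), "C")
  expect_equal(difficulty_level(54.999), "D")
  expect_equal(difficulty_level(40), "D")
  expect_equal(difficulty_level(39.999), "E")
  expect_equal(difficulty_level(0), "E")
  expect_error(difficulty_level(101), "\\[0, 100\\]")
  expect_error(total_and_level(25, 0, 0, 0, 0), "cap")
})

test_that("grading composes the five curves and is monotone", {
  rep <- tibble::tibble(snrt_db = 10, snrw_db = -10, acc_stand = 0.95,
                        t_best = 1, itr_best = 120, n_targets = 40)
  card <- grade_dataset(rep)
  expect_equal(card$total, 100)      # every index at or beyond its cap
  expect_equal(card$level, "A")

  low <- tibble::tibble(snrt_db = -10, snrw_db = -40, acc_stand = 0.3,
                        t_best = 9, itr_best = 10, n_targets = 40)
  expect_equal(grade_dataset(low)$total, 0)
  expect_equal(grade_dataset(low)$level, "E")

  expect_error(grade_dataset(rep[, -1]), "snrt_db")

  # improving any single index never lowers the total
  withr::with_seed(17, {
    for (r in 1:40) {
      base <- tibble::tibble(
        snrt_db = stats::runif(1, -15, 15),
        snrw_db = stats::runif(1, -45, 0),
        acc_stand = stats::runif(1),
        t_best = stats::runif(1, 0.5, 9),
        itr_best = stats::runif(1, 0, 150),
        n_targets = 12
      )
      t0 <- grade_dataset(base)$total
      for (col in c("snrt_db", "snrw_db", "acc_stand", "itr_best")) {
        up <- base
        up[[col]] <- up[[col]] + stats::runif(1, 0.1, 5)
        if (col == "acc_stand") up[[col]] <- min(1, base[[col]] +
                                                   stats::runif(1, 0.01, 0.2))
        expect_gte(grade_dataset(up)$total, t0 - 1e-9)
      }
      faster <- base
      faster$t_best <- base$t_best * 0.8
      expect_gte(grade_dataset(faster)$total, t0 - 1e-9)
    }
  })
})
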