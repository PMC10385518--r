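#' Per-trial predictions for one algorithm at one window length
#'
#' Applies a decoder to every trial of `epochs` at the given stimulus-locked
#' window. Training-free decoders (CCA, FBCCA) need no `train` set; eTRCA
#' and TDCA are fitted on `train` (which must not share trials with
#' `epochs` for an honest estimate - [crossval_accuracy()] arranges that).
#'
#' @param epochs Test trials, an [ssvep_epochs()] object.
#' @param algorithm `"cca"`, `"fbcca"`, `"etrca"` or `"tdca"`.
#' @param window Window length in seconds; default the full usable extent.
#' @param train Training trials for eTRCA/TDCA.
#' @param Nh Reference harmonics. Default 5.
#' @param fb Filter bank. Default [filterbank_spec()].
#' @param Np TDCA delay span (s); default `min(1, window)` capped by the
#'   training extent.
#' @param n_components TDCA discriminant components. Default 9, reduced to
#'   the augmented-channel rank when smaller.
#' @return A tibble: `trial`, `block`, `truth`, `predicted`, `correct`.
#' @export
decode_trials <- function(epochs, algorithm = c("cca", "fbcca", "etrca",
                                                "tdca"),
                          window = NULL, train = NULL, Nh = 5,
                          fb = filterbank_spec(), Np = NULL,
                          n_components = 9) {
  algorithm <- match.arg(algorithm)
  window <- window %||% epoch_extent(epochs)
  test <- extract_window(epochs, 0, window)
  preds <- switch(algorithm,
    cca = {
      refs <- build_references(epochs$codebook, Nh, epochs$sfreq,
                               n_samples(test))
      vapply(seq_len(n_trials(test)), function(i) {
        cca_classify(trial_matrix(test, i), refs)
      }, integer(1))
    },
    fbcca = {
      refs <- build_references(epochs$codebook, Nh, epochs$sfreq,
                               n_samples(test))
      filts <- band_filters(fb, epochs$sfreq)
      vapply(seq_len(n_trials(test)), function(i) {
        fbcca_classify_prepared(trial_matrix(test, i), refs, fb, filts)
      }, integer(1))
    },
    etrca = {
      if (is.null(train)) stop("eTRCA needs a training set", call. = FALSE)
      model <- etrca_fit(extract_window(train, 0, window), fb)
      vapply(seq_len(n_trials(test)), function(i) {
        etrca_classify(trial_matrix(test, i), model)
      }, integer(1))
    },
    tdca = {
      if (is.null(train)) stop("TDCA needs a training set", call. = FALSE)
      Np <- Np %||% default_np(window, epoch_extent(train))
      l <- round(Np / 0.1)
      A <- (l + 1L) * n_channels(train)
      k <- min(n_components, A)
      model <- tdca_fit(extract_window(train, 0, window + Np), Np = Np,
                        n_components = k, spec = fb, Nh = Nh)
      vapply(seq_len(n_trials(test)), function(i) {
        tdca_classify(trial_matrix(test, i), model)
      }, integer(1))
    }
  )
  tibble::tibble(
    trial = seq_len(n_trials(test)),
    block = test$blocks,
    truth = test$labels,
    predicted = preds,
    correct = preds == test$labels
  )
}

# Default TDCA delay span: for windows under 1 s, the maximum the window
# supports; for longer windows, 0.5 s (mid-range of the customary 0.1-1 s
# tuning interval; large spans relative to the window degrade the
# zero-padded test-time augmentation). Always capped by the training
# extent, in 0.1 s steps.
default_np <- function(window, extent) {
  base <- if (window < 1) window else 0.5
  np <- min(base, floor((extent - window) / 0.1 + 1e-9) * 0.1)
  if (np < 0.1 - 1e-9) 0 else np
}

#' Cross-validated recognition accuracy
#'
#' Training decoders are evaluated with leave-one-block-out folds: the
#' model is fitted on all other blocks and tested on the held-out block, so
#' test trials never inform training. Training-free decoders are applied to
#' every trial in a single fold. Accuracy bookkeeping is exact
#' (correct / total per fold).
#'
#' @inheritParams decode_trials
#' @param seed Integer seed (all decoders here are deterministic; the seed
#'   is recorded for provenance).
#' @return A tibble of class `ssvep_eval` with per-fold rows (`fold`,
#'   `n_correct`, `n_trials`, `accuracy`); pooled accuracy, the per-trial
#'   prediction table, the algorithm and window are attached as attributes.
#' @export
crossval_accuracy <- function(epochs, algorithm = c("cca", "fbcca", "etrca",
                                                    "tdca"),
                              window = NULL, seed = 1L, Nh = 5,
                              fb = filterbank_spec(), Np = NULL,
                              n_components = 9) {
  algorithm <- match.arg(algorithm)
  trained <- algorithm %in% c("etrca", "tdca")
  blocks <- sort(unique(epochs$blocks))
  if (trained && length(blocks) < 2L) {
    stop(algorithm, " needs at least 2 blocks for leave-one-block-out ",
         "cross-validation", call. = FALSE)
  }
  window <- window %||% epoch_extent(epochs)
  if (!trained) {
    preds <- decode_trials(epochs, algorithm, window, Nh = Nh, fb = fb)
    preds$fold <- 1L
    folds <- tibble::tibble(fold = 1L, n_correct = sum(preds$correct),
                            n_trials = nrow(preds),
                            accuracy = mean(preds$correct))
  } else {
    # band-filter the analysis windows once; folds then only subset
    wtest <- extract_window(epochs, 0, window)
    fb_test <- apply_filter_bank(wtest, fb)
    filts <- band_filters(fb, epochs$sfreq)
    if (algorithm == "tdca") {
      Np <- Np %||% default_np(window, epoch_extent(epochs))
      l <- round(Np / 0.1)
      k_comp <- min(n_components, (l + 1L) * n_channels(epochs))
      fb_train_src <- if (Np > 0) {
        apply_filter_bank(extract_window(epochs, 0, window + Np), fb)
      } else fb_test
    } else {
      fb_train_src <- fb_test
    }
    all_preds <- list()
    folds <- purrr::map_dfr(seq_along(blocks), function(k) {
      b <- blocks[k]
      tr_idx <- epochs$blocks != b
      te_idx <- which(epochs$blocks == b)
      banded_train <- lapply(fb_train_src, subset_trials, idx = tr_idx)
      model <- if (algorithm == "etrca") {
        etrca_fit_prefiltered(banded_train, fb, filts)
      } else {
        tdca_fit_prefiltered(banded_train, Np = Np, n_components = k_comp,
                             spec = fb, Nh = Nh, filts = filts)
      }
      pred <- vapply(te_idx, function(i) {
        band_mats <- lapply(fb_test, function(bep) trial_matrix(bep, i))
        if (algorithm == "etrca") etrca_classify_banded(band_mats, model)
        else tdca_classify_banded(band_mats, model)
      }, integer(1))
      p <- tibble::tibble(trial = te_idx, block = epochs$blocks[te_idx],
                          truth = epochs$labels[te_idx], predicted = pred,
                          correct = pred == epochs$labels[te_idx],
                          fold = k)
      all_preds[[k]] <<- p
      tibble::tibble(fold = k, n_correct = sum(p$correct),
                     n_trials = nrow(p), accuracy = mean(p$correct))
    })
    preds <- dplyr::bind_rows(all_preds)
  }
  out <- folds
  attr(out, "algorithm") <- algorithm
  attr(out, "window") <- window %||% epoch_extent(epochs)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "predictions") <- preds
  attr(out, "pooled_accuracy") <- sum(folds$n_correct) / sum(folds$n_trials)
  class(out) <- c("ssvep_eval", class(out))
  out
}

#' Accuracy of several algorithms across a cohort of subjects
#'
#' @param cohort A named list of [ssvep_epochs()] objects, one per subject.
#' @param algorithms Character vector of decoder names.
#' @param window Window length in seconds.
#' @param ... Passed to [crossval_accuracy()].
#' @return A tibble: `subject`, `algorithm`, `accuracy`.
#' @export
cohort_accuracy <- function(cohort, algorithms = c("cca", "fbcca", "etrca",
                                                   "tdca"),
                            window = NULL, ...) {
  if (is.null(names(cohort))) {
    names(cohort) <- paste0("s", seq_along(cohort))
  }
  tidyr::expand_grid(subject = names(cohort), algorithm = algorithms) |>
    dplyr::mutate(accuracy = purrr::map2_dbl(.data$subject, .data$algorithm,
      function(s, a) {
        attr(crossval_accuracy(cohort[[s]], a, window, ...),
             "pooled_accuracy")
      }))
}

#' Best and worst subjects per algorithm
#'
#' Identifies, for each algorithm, the subjects with the lowest and highest
#' pooled accuracy (ties broken toward the lowest subject index) and
#' reports their accuracy and [itr()] at the stated window.
#'
#' @param results A [cohort_accuracy()] tibble.
#' @param N Number of stimulation targets.
#' @param window Recognition window used, seconds.
#' @param gaze_shift Seconds added for the ITR. Default 0.5.
#' @return A tibble with one row per algorithm and `which` in
#'   `c("worst", "best")`.
#' @export
best_worst <- function(results, N, window, gaze_shift = 0.5) {
  results |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::reframe(
      which = c("worst", "best"),
      subject = c(.data$subject[which.min(.data$accuracy)],
                  .data$subject[which.max(.data$accuracy)]),
      accuracy = c(min(.data$accuracy), max(.data$accuracy))
    ) |>
    dplyr::mutate(itr = purrr::map_dbl(.data$accuracy, function(p) {
      as.numeric(itr(N, p, window, gaze_shift))
    }))
}

#' Pairwise algorithm comparison by paired t-test
#'
#' Paired t-tests on per-subject accuracies for every algorithm pair, with
#' Bonferroni correction over the family of pairs (6 for four algorithms).
#' Significance marks follow the usual reporting: `***` for corrected
#' p < 0.001, `**` for p < 0.01, `N.S.` otherwise.
#'
#' @param results A [cohort_accuracy()] tibble with >= 3 subjects and the
#'   same subject set for every algorithm.
#' @param bonferroni_m Correction factor; defaults to the number of pairs.
#' @return A tibble: `algorithm1`, `algorithm2`, `mean_diff`, `t`,
#'   `p_raw`, `p_corrected`, `significance`.
#' @export
compare_algorithms <- function(results, bonferroni_m = NULL) {
  wide <- tidyr::pivot_wider(results, names_from = "algorithm",
                             values_from = "accuracy")
  algs <- setdiff(names(wide), "subject")
  if (any(!stats::complete.cases(wide))) {
    stop("all algorithms must be evaluated on the same subject set",
         call. = FALSE)
  }
  if (nrow(wide) < 3L) stop("need at least 3 subjects", call. = FALSE)
  pairs <- utils::combn(algs, 2, simplify = FALSE)
  m <- bonferroni_m %||% length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    x <- wide[[pr[1]]]; y <- wide[[pr[2]]]
    if (isTRUE(all.equal(x, y))) {
      tt <- list(statistic = 0, p.value = 1)
    } else {
      tt <- stats::t.test(x, y, paired = TRUE)
    }
    p_raw <- as.numeric(tt$p.value)
    p_corr <- min(1, m * p_raw)
    tibble::tibble(
      algorithm1 = pr[1], algorithm2 = pr[2],
      mean_diff = mean(x) - mean(y),
      t = as.numeric(tt$statistic),
      p_raw = p_raw, p_corrected = p_corr,
      significance = if (p_corr < 0.001) "***"
                     else if (p_corr < 0.01) "**"
                     else "N.S."
    )
  })
}

#' Evaluate and grade a dataset end-to-end
#'
#' Runs the full pipeline on one recording or a cohort: the five indexes
#' via [evaluate_indexes()], then the five score functions and the A-E
#' difficulty level via [grade_dataset()]. For a cohort (a list of
#' per-subject epoch objects), the default aggregation computes scores per
#' subject and averages them; `"pooled"` averages the indexes first and
#' scores the means (the two differ because the score curves are
#' nonlinear).
#'
#' @param epochs An [ssvep_epochs()] object or a list of them (a cohort).
#' @param aggregation `"per-subject"` (default) or `"pooled"`; only used
#'   for cohorts.
#' @param ... Passed to [evaluate_indexes()].
#' @return A list with elements `report` (index tibble; one row per
#'   subject for cohorts) and `scorecard`.
#' @export
evaluate_and_grade <- function(epochs, aggregation = c("per-subject",
                                                       "pooled"), ...) {
  aggregation <- match.arg(aggregation)
  if (inherits(epochs, "ssvep_epochs")) {
    report <- evaluate_indexes(epochs, ...)
    return(list(report = report, scorecard = grade_dataset(report)))
  }
  stopifnot(is.list(epochs), length(epochs) > 0L)
  reports <- purrr::map_dfr(epochs, evaluate_indexes, ...)
  reports$subject <- names(epochs) %||% paste0("s", seq_len(nrow(reports)))
  if (aggregation == "pooled") {
    mean_report <- dplyr::summarise(reports, dplyr::across(
      c("snrt_db", "snrw_db", "acc_stand", "t_best", "itr_best"), mean),
      n_targets = .data$n_targets[1])
    card <- grade_dataset(mean_report)
  } else {
    cards <- purrr::map_dfr(seq_len(nrow(reports)), function(i) {
      grade_dataset(reports[i, ])
    })
    mean_scores <- colMeans(cards[, c("score1", "score2", "score3",
                                      "score4", "score5")])
    card <- total_and_level(mean_scores[1], mean_scores[2], mean_scores[3],
                            mean_scores[4], mean_scores[5])
  }
  list(report = reports, scorecard = card)
}
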