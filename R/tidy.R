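#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an accuracy curve
#' @param x An [accuracy_curve()].
#' @param ... Unused.
#' @return A tibble with `window` (s) and `accuracy`.
#' @method tidy accuracy_curve
#' @export
tidy.accuracy_curve <- function(x, ...) {
  tibble::tibble(window = x$window, accuracy = x$accuracy)
}

#' @rdname tidy.accuracy_curve
#' @method glance accuracy_curve
#' @export
glance.accuracy_curve <- function(x, ...) {
  tibble::tibble(Tmax = attr(x, "Tmax"),
                 acc_at_Tmax = attr(x, "acc_at_Tmax"),
                 t_best = t_best(x))
}

#' Tidy a scorecard into long form
#' @param x A [total_and_level()] scorecard.
#' @param ... Unused.
#' @return A tibble with one row per index score (`score`, `points`,
#'   `cap`).
#' @method tidy scorecard
#' @export
tidy.scorecard <- function(x, ...) {
  tibble::tibble(
    score = names(score_caps),
    index = c("snrt", "snrw", "acc_stand", "t_best", "itr_best"),
    points = as.numeric(x[1, names(score_caps)]),
    cap = as.numeric(score_caps)
  )
}

#' @rdname tidy.scorecard
#' @method glance scorecard
#' @export
glance.scorecard <- function(x, ...) {
  tibble::tibble(total = x$total, level = x$level)
}

#' Tidy a cross-validation result
#' @param x A [crossval_accuracy()] result.
#' @param ... Unused.
#' @return The per-fold tibble.
#' @method tidy ssvep_eval
#' @export
tidy.ssvep_eval <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("fold", "n_correct", "n_trials",
                                 "accuracy")])
}

#' @rdname tidy.ssvep_eval
#' @method glance ssvep_eval
#' @export
glance.ssvep_eval <- function(x, ...) {
  tibble::tibble(algorithm = attr(x, "algorithm"),
                 window = attr(x, "window"),
                 n_folds = nrow(x),
                 accuracy = attr(x, "pooled_accuracy"))
}

#' Tidy an index report
#' @param x An [evaluate_indexes()] report.
#' @param ... Unused.
#' @return Long tibble with `index` and `value`.
#' @method tidy index_report
#' @export
tidy.index_report <- function(x, ...) {
  tidyr::pivot_longer(tibble::as_tibble(unclass(x)[c(
    "snrt_db", "snrw_db", "acc_stand", "t_best", "itr_best")]),
    dplyr::everything(), names_to = "index", values_to = "value")
}
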