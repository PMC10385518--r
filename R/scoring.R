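#' Score functions for the five dataset-difficulty indexes
#'
#' Each index maps through a calibrated piecewise-logarithmic curve to a
#' point score; the caps are 20 / 15 / 25 / 15 / 25 points (summing to 100)
#' for narrowband SNR, wideband SNR, standard accuracy, optimal response
#' time and best ITR respectively. The log10 shaping compresses the low end
#' so harder recordings still collect some points. All outputs are clamped
#' into their caps.
#'
#' @param snrt Narrowband SNR in dB.
#' @return Points.
#' @name score_functions
NULL

clamp <- function(x, lo, hi) min(max(x, lo), hi)

#' @rdname score_functions
#' @details `score_snrt`: 0 at or below -10 dB, `15.1 log10(SNRt + 11)` on
#'   (-10, 10) dB, 20 at or above 10 dB (the 15.1 factor calibrates the
#'   curve to reach ~20 at 10 dB).
#' @export
score_snrt <- function(snrt) {
  if (is.na(snrt)) stop("snrt is missing", call. = FALSE)
  if (snrt <= -10) return(0)
  if (snrt >= 10) return(20)
  clamp(15.1 * log10(snrt + 11), 0, 20)
}

#' @rdname score_functions
#' @param snrw Wideband SNR in dB.
#' @details `score_snrw`: 0 at or below -40 dB, `10 log10(SNRw + 41)` on
#'   (-40, -10) dB, 15 at or above -10 dB.
#' @export
score_snrw <- function(snrw) {
  if (is.na(snrw)) stop("snrw is missing", call. = FALSE)
  if (snrw <= -40) return(0)
  if (snrw >= -10) return(15)
  clamp(10 * log10(snrw + 41), 0, 15)
}

#' @rdname score_functions
#' @param acc Standard-algorithm accuracy in percent (0-100).
#' @details `score_acc`: 0 at or below 50%, `15.5 log10(ACC - 49)` on
#'   (50, 90)%, 25 at or above 90%.
#' @export
score_acc <- function(acc) {
  if (is.na(acc)) stop("acc is missing", call. = FALSE)
  if (acc <= 50) return(0)
  if (acc >= 90) return(25)
  clamp(15.5 * log10(acc - 49), 0, 25)
}

#' @rdname score_functions
#' @param t Optimal response time in seconds.
#' @param C Number of stimulation targets.
#' @details `score_tbest`: 15 at or below 2 s, 0 at or above 8 s,
#'   `19 - 21.5 log10(t) + log10(C)` in between (clamped to [0, 15]); more
#'   targets soften the penalty for a slow response.
#' @export
score_tbest <- function(t, C) {
  if (is.na(t) || is.na(C)) stop("t or C is missing", call. = FALSE)
  if (C < 1) stop("C must be >= 1", call. = FALSE)
  if (t <= 2) return(15)
  if (t >= 8) return(0)
  clamp(19 - 21.5 * log10(t) + log10(C), 0, 15)
}

#' @rdname score_functions
#' @param itr_bits Best ITR in bits/min.
#' @details `score_itr`: 0 below 30 bits/min, `14 log10(ITR - 29)` on
#'   (30, 100], 25 above 100 bits/min.
#' @export
score_itr <- function(itr_bits) {
  if (is.na(itr_bits)) stop("itr is missing", call. = FALSE)
  if (itr_bits < 30) return(0)
  if (itr_bits > 100) return(25)
  clamp(14 * log10(itr_bits - 29), 0, 25)
}

score_caps <- c(score1 = 20, score2 = 15, score3 = 25, score4 = 15,
                score5 = 25)

#' Total score and difficulty level
#'
#' Sums the five index scores and maps the total to a decoding-difficulty
#' level: [85, 100] -> A, [70, 85) -> B, [55, 70) -> C, [40, 55) -> D,
#' [0, 40) -> E. Higher totals mean easier decoding.
#'
#' @param score1,score2,score3,score4,score5 The five index scores, each
#'   within its cap (20 / 15 / 25 / 15 / 25).
#' @return A one-row tibble of class `scorecard` with the five scores,
#'   `total` and `level`.
#' @examples
#' total_and_level(4.9, 0.4, 12.4, 8.9, 9.7)   # total 36.3, level E
#' @export
total_and_level <- function(score1, score2, score3, score4, score5) {
  s <- c(score1, score2, score3, score4, score5)
  if (any(is.na(s))) stop("missing score", call. = FALSE)
  over <- which(s < 0 | s > score_caps + 1e-9)
  if (length(over) > 0L) {
    stop(names(score_caps)[over[1]], " = ", s[over[1]],
         " is outside its cap [0, ", score_caps[over[1]], "]",
         call. = FALSE)
  }
  total <- sum(s)
  out <- tibble::tibble(score1 = score1, score2 = score2, score3 = score3,
                        score4 = score4, score5 = score5, total = total,
                        level = difficulty_level(total))
  class(out) <- c("scorecard", class(out))
  out
}

#' Difficulty level for a total score
#' @param total Total score in [0, 100].
#' @return One of "A".."E".
#' @export
difficulty_level <- function(total) {
  if (is.na(total) || total < 0 || total > 100 + 1e-9) {
    stop("total must lie in [0, 100]", call. = FALSE)
  }
  if (total >= 85) "A"
  else if (total >= 70) "B"
  else if (total >= 55) "C"
  else if (total >= 40) "D"
  else "E"
}

#' Grade a dataset from its index report
#'
#' Applies the five score functions to a computed [evaluate_indexes()]
#' report and totals them into a difficulty level. `acc_stand` is converted
#' from fraction to percent for scoring; infinite SNR sentinels map to the
#' caps.
#'
#' @param report An [evaluate_indexes()] one-row report (or any data frame
#'   with columns `snrt_db`, `snrw_db`, `acc_stand`, `t_best`, `itr_best`,
#'   `n_targets`).
#' @param C Number of stimulation targets; defaults to `report$n_targets`.
#' @return A [total_and_level()] scorecard.
#' @export
grade_dataset <- function(report, C = NULL) {
  needed <- c("snrt_db", "snrw_db", "acc_stand", "t_best", "itr_best")
  missing_col <- setdiff(needed, names(report))
  if (length(missing_col) > 0L) {
    stop("index report is missing: ", paste(missing_col, collapse = ", "),
         call. = FALSE)
  }
  C <- C %||% report$n_targets
  if (is.null(C)) stop("target count C is required", call. = FALSE)
  total_and_level(
    score_snrt(report$snrt_db),
    score_snrw(report$snrw_db),
    score_acc(100 * report$acc_stand),
    score_tbest(report$t_best, C),
    score_itr(report$itr_best)
  )
}
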