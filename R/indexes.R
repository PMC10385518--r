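#' Information transfer rate of a BCI selection
#'
#' The standard Wolpaw-style rate in bits/min,
#' \deqn{ITR = \frac{60}{T}\left[\log_2 N + P \log_2 P + (1-P)\log_2\frac{1-P}{N-1}\right],}
#' where the response time `T` is the recognition window plus the gaze-shift
#' allowance (0.5 s by default) needed to move between targets. The
#' `P = 1` and `P = 0` entropy terms are evaluated in the limit. The bits
#' term is convex with its minimum (0) at chance level, so the rate is
#' never negative; accuracies below chance (P < 1/N), where the formula
#' rises again without the selections being useful, are flagged with
#' attribute `below_chance = TRUE`.
#'
#' @param N Number of stimulation targets (>= 2).
#' @param P Recognition accuracy, a fraction in [0, 1].
#' @param window Recognition window length, seconds.
#' @param gaze_shift Gaze-shift allowance added to the window, seconds.
#'   Default 0.5.
#' @return ITR in bits/min.
#' @examples
#' itr(40, 1.0, 2)   # 127.7 bits/min
#' itr(12, 1.0, 2)   # 86.0 bits/min
#' @export
itr <- function(N, P, window, gaze_shift = 0.5) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  if (P < 0 || P > 1) stop("P must lie in [0, 1]", call. = FALSE)
  if (window <= 0) stop("window must be positive", call. = FALSE)
  T_resp <- window + gaze_shift
  plogp <- function(p) if (p <= 0) 0 else p * log2(p)
  bits <- log2(N) + plogp(P) +
    if (P >= 1) 0 else (1 - P) * log2((1 - P) / (N - 1))
  out <- 60 / T_resp * bits
  if (P < 1 / N) attr(out, "below_chance") <- TRUE
  out
}

#' Recognition-accuracy curve over window lengths
#'
#' Evaluates a decoder at each window length and returns the mean
#' recognition accuracy. Training-free decoders (CCA, FBCCA) are applied to
#' every trial; training decoders (eTRCA, TDCA) are evaluated with
#' leave-one-block-out cross-validation.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param algorithm One of `"cca"`, `"fbcca"`, `"etrca"`, `"tdca"`.
#'   Default `"fbcca"`, the standard grading algorithm.
#' @param windows Increasing vector of window lengths in seconds. Default:
#'   0.2 s steps from 0.2 s up to the epoch extent.
#' @param ... Passed to [crossval_accuracy()] (e.g. `Nh`, `fb`, `Np`).
#' @return A tibble of class `accuracy_curve` with columns `window` and
#'   `accuracy`, plus attributes `Tmax` and `acc_at_Tmax`.
#' @export
accuracy_curve <- function(epochs, algorithm = "fbcca", windows = NULL,
                           ...) {
  if (is.null(windows)) {
    windows <- seq(0.2, floor(epoch_extent(epochs) / 0.2 + 1e-9) * 0.2,
                   by = 0.2)
  }
  if (length(windows) == 0L) stop("empty window list", call. = FALSE)
  if (any(diff(windows) <= 0)) {
    stop("`windows` must be strictly increasing", call. = FALSE)
  }
  acc <- vapply(windows, function(w) {
    attr(crossval_accuracy(epochs, algorithm, w, ...), "pooled_accuracy")
  }, numeric(1))
  new_accuracy_curve(windows, acc)
}

new_accuracy_curve <- function(windows, acc) {
  out <- tibble::tibble(window = as.numeric(windows),
                        accuracy = as.numeric(acc))
  attr(out, "Tmax") <- windows[length(windows)]
  attr(out, "acc_at_Tmax") <- acc[length(acc)]
  class(out) <- c("accuracy_curve", class(out))
  out
}

#' Optimal response time from an accuracy curve
#'
#' The smallest window length whose mean accuracy reaches 90%. When no
#' window does, the extrapolation
#' \deqn{T_{best} = 0.9 \cdot T_{max} / ACC(T_{max})}
#' is used, scaling the maximum supported window by the shortfall.
#'
#' @param curve An [accuracy_curve()].
#' @param threshold Accuracy threshold. Default 0.9.
#' @return T_best in seconds (`Inf` when ACC(Tmax) = 0).
#' @export
t_best <- function(curve, threshold = 0.9) {
  stopifnot(inherits(curve, "accuracy_curve"), nrow(curve) > 0L)
  hit <- which(curve$accuracy >= threshold)
  if (length(hit) > 0L) return(curve$window[hit[1]])
  acc_max <- attr(curve, "acc_at_Tmax")
  if (acc_max <= 0) return(Inf)
  threshold * attr(curve, "Tmax") / acc_max
}

#' Best information transfer rate from an accuracy curve
#'
#' The highest [itr()] among windows whose accuracy reaches 90%; when none
#' does, the ITR at the maximum supported window is reported.
#'
#' @param curve An [accuracy_curve()].
#' @param N Number of stimulation targets.
#' @param gaze_shift Seconds added to each window. Default 0.5.
#' @param threshold Accuracy threshold. Default 0.9.
#' @return ITR_best in bits/min.
#' @export
itr_best <- function(curve, N, gaze_shift = 0.5, threshold = 0.9) {
  stopifnot(inherits(curve, "accuracy_curve"), nrow(curve) > 0L)
  hit <- which(curve$accuracy >= threshold)
  if (length(hit) == 0L) {
    return(as.numeric(itr(N, attr(curve, "acc_at_Tmax"),
                          attr(curve, "Tmax"), gaze_shift)))
  }
  max(vapply(hit, function(i) {
    as.numeric(itr(N, curve$accuracy[i], curve$window[i], gaze_shift))
  }, numeric(1)))
}

#' Standard-algorithm recognition accuracy
#'
#' FBCCA accuracy at a 2 s window, or at the maximum supported window when
#' the epochs are shorter than 2 s.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param ... Passed to [crossval_accuracy()] (`Nh`, `fb`).
#' @return Accuracy fraction in [0, 1], with attribute `window`.
#' @export
acc_standard <- function(epochs, ...) {
  w <- min(2, epoch_extent(epochs))
  out <- attr(crossval_accuracy(epochs, "fbcca", w, ...), "pooled_accuracy")
  attr(out, "window") <- w
  out
}

#' Compute the five dataset-evaluation indexes for one recording
#'
#' Produces the narrowband and wideband SNR (trial-averaged at the
#' occipital/signal channel), the standard-algorithm accuracy, the optimal
#' response time and the best ITR, all from one epoched recording.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param channel Channel for the SNR indexes; defaults to the designated
#'   signal channel (or "Oz" when present, else channel 1).
#' @param Nh Harmonics for the wideband SNR and decoder references.
#'   Default 5.
#' @param windows Window grid for the accuracy curve; default 0.2 s steps.
#' @param fb Filter bank for FBCCA. Default [filterbank_spec()].
#' @return A one-row tibble of class `index_report` with columns `snrt_db`,
#'   `snrw_db`, `acc_stand`, `t_best`, `itr_best`, `n_targets`; the
#'   accuracy curve and per-target SNR tables are attached as attributes.
#' @export
evaluate_indexes <- function(epochs, channel = NULL, Nh = 5,
                             windows = NULL, fb = filterbank_spec()) {
  snrt <- snr_narrowband_avg(epochs, channel)
  snrw <- snr_wideband_avg(epochs, channel, Nh)
  curve <- accuracy_curve(epochs, "fbcca", windows, Nh = Nh, fb = fb)
  accs <- acc_standard(epochs, Nh = Nh, fb = fb)
  N <- n_targets(epochs$codebook)
  out <- tibble::tibble(
    snrt_db = attr(snrt, "mean_db"),
    snrw_db = attr(snrw, "mean_db"),
    acc_stand = as.numeric(accs),
    t_best = t_best(curve),
    itr_best = itr_best(curve, N),
    n_targets = N
  )
  attr(out, "curve") <- curve
  attr(out, "snrt_by_target") <- snrt
  attr(out, "snrw_by_target") <- snrw
  class(out) <- c("index_report", class(out))
  out
}
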