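#' Axis layout of a public 4-D epoch array
#'
#' The public frequency-phase SSVEP datasets ship one 4-D array per subject
#' with axes channels / samples / targets / blocks (in varying orders). A
#' layout names the role of each axis and records the sampling rate, the cue
#' period before stimulus onset and the visual latency, which together place
#' the decoding origin inside the epoch.
#'
#' @param order Character vector of length 4: a permutation of
#'   `c("channels", "samples", "targets", "blocks")` giving the axis roles in
#'   storage order.
#' @param sfreq Sampling rate, Hz.
#' @param cue_offset Cue period before stimulus onset, seconds. Default 0.5.
#' @param latency Visual latency, seconds. Default 0.14 (the only latency
#'   the public datasets document explicitly).
#' @return A list of class `dataset_layout`.
#' @export
dataset_layout <- function(order = c("channels", "samples", "targets",
                                     "blocks"),
                           sfreq, cue_offset = 0.5, latency = 0.14) {
  roles <- c("channels", "samples", "targets", "blocks")
  if (length(order) != 4L || !setequal(order, roles)) {
    stop("`order` must name each of ", paste(roles, collapse = ", "),
         " exactly once", call. = FALSE)
  }
  if (cue_offset < 0 || latency < 0) {
    stop("`cue_offset` and `latency` must be non-negative", call. = FALSE)
  }
  structure(list(order = order, sfreq = sfreq, cue_offset = cue_offset,
                 latency = latency),
            class = "dataset_layout")
}

#' Write epochs to a self-describing portable container
#'
#' Saves the full epoch object (data, sampling rate, labels, blocks, channel
#' names, codebook and origin offset) as named variables in a MATLAB v5
#' container, so the file is readable by any MAT-capable tool and
#' round-trips losslessly through [load_epochs()].
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  if (n_trials(epochs) == 0L) stop("no trials", call. = FALSE)
  vars <- list(
    data = epochs$data,
    sfreq = epochs$sfreq,
    labels = as.numeric(epochs$labels),
    blocks = as.numeric(epochs$blocks),
    t0_offset = epochs$t0_offset,
    channel_names = epochs$channel_names,
    frequencies = epochs$codebook$frequency,
    phases = epochs$codebook$phase,
    codebook_name = attr(epochs$codebook, "name") %||% "custom"
  )
  sc <- attr(epochs, "signal_channel")
  if (!is.null(sc)) vars$signal_channel <- as.numeric(sc)
  write_mat5(vars, path)
  invisible(path)
}

#' Load epochs from a portable container or a public 4-D array
#'
#' Two on-disk shapes are understood. A container written by
#' [save_epochs()] is restored directly (all metadata travels with the
#' file). A public-dataset file holding a single 4-D array is reshaped
#' according to `layout`: the (target, block) axes are flattened into the
#' trial axis with labels and block indices preserved, and the origin offset
#' is set to `-(cue_offset + latency)` so window extraction is locked to the
#' stimulus response onset.
#'
#' @param path File path (.mat, v5 dialect).
#' @param layout A [dataset_layout()]; required for bare 4-D arrays.
#' @param codebook Codebook for the bare 4-D shape; its size must equal the
#'   target-axis length.
#' @return An [ssvep_epochs()] object.
#' @export
load_epochs <- function(path, layout = NULL, codebook = NULL) {
  vars <- read_mat5(path)
  if (all(c("data", "sfreq", "labels", "blocks") %in% names(vars))) {
    cb <- new_codebook(vars$frequencies, vars$phases,
                       name = vars$codebook_name %||% "custom")
    ep <- ssvep_epochs(vars$data, as.numeric(vars$sfreq),
                       vars$labels, vars$blocks, cb,
                       channel_names = vars$channel_names,
                       t0_offset = as.numeric(vars$t0_offset %||% 0))
    if (!is.null(vars$signal_channel)) {
      attr(ep, "signal_channel") <- as.integer(vars$signal_channel)
    }
    return(ep)
  }
  # bare public layout: exactly one array variable expected
  arrays <- Filter(function(v) is.array(v) || is.numeric(v), vars)
  if (length(arrays) != 1L) {
    stop("expected one 4-D array in the file, found ", length(arrays),
         " variables (", paste(names(vars), collapse = ", "), ")",
         call. = FALSE)
  }
  arr <- arrays[[1L]]
  if (!is.array(arr) || length(dim(arr)) != 4L) {
    stop("expected a rank-4 array (channels x samples x targets x blocks ",
         "in some order), got rank ",
         if (is.array(arr)) length(dim(arr)) else 1L, call. = FALSE)
  }
  if (is.null(layout) || is.null(codebook)) {
    stop("loading a bare 4-D array requires `layout` and `codebook`",
         call. = FALSE)
  }
  perm <- match(c("targets", "blocks", "channels", "samples"), layout$order)
  arr <- aperm(arr, perm)              # targets x blocks x channels x samples
  d <- dim(arr)
  if (d[1] != n_targets(codebook)) {
    stop("target-axis length (", d[1], ") does not match the codebook (",
         n_targets(codebook), " targets)", call. = FALSE)
  }
  n_tr <- d[1] * d[2]
  dat <- array(0, c(n_tr, d[3], d[4]))
  labels <- integer(n_tr); blocks <- integer(n_tr)
  i <- 0L
  for (b in seq_len(d[2])) {
    for (tg in seq_len(d[1])) {
      i <- i + 1L
      dat[i, , ] <- arr[tg, b, , ]
      labels[i] <- tg; blocks[i] <- b
    }
  }
  ssvep_epochs(dat, layout$sfreq, labels, blocks, codebook,
               t0_offset = -(layout$cue_offset + layout$latency))
}

#' Extract a stimulus-locked analysis window
#'
#' Cuts `length` seconds of every trial starting `start` seconds after the
#' decoding origin (stimulus onset + visual latency). Sample counts are
#' rounded half-to-even for cross-platform determinism.
#'
#' @param epochs An [ssvep_epochs()] object.
#' @param start Window start relative to the origin, seconds (>= 0).
#' @param length Window length, seconds.
#' @return An [ssvep_epochs()] with `round(length * sfreq)` samples per
#'   trial and `t0_offset = start`.
#' @export
extract_window <- function(epochs, start, length) {
  stopifnot(inherits(epochs, "ssvep_epochs"))
  if (start < 0) stop("`start` must be >= 0", call. = FALSE)
  fs <- epochs$sfreq
  first <- round((start - epochs$t0_offset) * fs) + 1L
  nsamp <- round(length * fs)
  if (nsamp < 1L) stop("window too short: no samples", call. = FALSE)
  avail <- n_samples(epochs)
  if (first + nsamp - 1L > avail) {
    stop(sprintf("window [%.3g, %.3g] s exceeds the available extent; at most %.4g s are available after `start`",
                 start, start + length,
                 (avail - first + 1L) / fs), call. = FALSE)
  }
  out <- ssvep_epochs(epochs$data[, , first:(first + nsamp - 1L),
                                  drop = FALSE],
                      fs, epochs$labels, epochs$blocks, epochs$codebook,
                      epochs$channel_names, t0_offset = start)
  attr(out, "signal_channel") <- attr(epochs, "signal_channel")
  out
}
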