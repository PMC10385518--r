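#' Epoched multichannel EEG container
#'
#' `ssvep_epochs` is the in-memory currency of the package: a dense
#' `trials x channels x samples` numeric array (microvolts) together with the
#' sampling rate, per-trial target labels, per-trial block indices, channel
#' names, the associated stimulus codebook, and `t0_offset`, the time of the
#' first stored sample relative to the decoding origin (stimulus onset plus
#' visual latency). A negative `t0_offset` means the array starts before the
#' origin; window extraction with [extract_window()] is always locked to the
#' origin, not to the array start.
#'
#' @param data Numeric array, `trials x channels x samples`.
#' @param sfreq Sampling rate in Hz (> 0).
#' @param labels Integer vector of per-trial target indices into `codebook`.
#' @param blocks Integer vector of per-trial block indices.
#' @param codebook An [make_codebook()] codebook.
#' @param channel_names Optional character vector, one name per channel.
#' @param t0_offset Seconds from the decoding origin to the first sample
#'   (typically `<= 0`). Default 0.
#'
#' @return An object of class `ssvep_epochs`.
#' @export
ssvep_epochs <- function(data, sfreq, labels, blocks, codebook,
                         channel_names = NULL, t0_offset = 0) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-D array (trials x channels x samples), got ",
         if (is.array(data)) paste0(length(dim(data)), " dimensions")
         else class(data)[1], call. = FALSE)
  }
  storage.mode(data) <- "double"
  d <- dim(data)
  if (d[1] == 0L) stop("no trials", call. = FALSE)
  if (d[3] == 0L) stop("epochs must contain at least one sample", call. = FALSE)
  if (!is.numeric(sfreq) || length(sfreq) != 1L || !is.finite(sfreq) ||
      sfreq <= 0) {
    stop("`sfreq` must be a single positive number (Hz)", call. = FALSE)
  }
  labels <- as.integer(labels)
  blocks <- as.integer(blocks)
  if (length(labels) != d[1] || length(blocks) != d[1]) {
    stop("`labels` and `blocks` must each have one entry per trial (",
         d[1], ")", call. = FALSE)
  }
  if (!inherits(codebook, "ssvep_codebook")) {
    stop("`codebook` must be an ssvep_codebook", call. = FALSE)
  }
  if (any(labels < 1L | labels > n_targets(codebook))) {
    stop("all trial labels must index a codebook target (1..",
         n_targets(codebook), ")", call. = FALSE)
  }
  if (is.null(channel_names)) {
    channel_names <- paste0("ch", seq_len(d[2]))
  }
  if (length(channel_names) != d[2]) {
    stop("`channel_names` must have one name per channel", call. = FALSE)
  }
  structure(
    list(data = data, sfreq = sfreq, labels = labels, blocks = blocks,
         codebook = codebook, channel_names = as.character(channel_names),
         t0_offset = as.numeric(t0_offset)),
    class = "ssvep_epochs"
  )
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<ssvep_epochs> ", d[1], " trials x ", d[2], " channels x ", d[3],
      " samples @ ", x$sfreq, " Hz\n", sep = "")
  cat("  codebook: ", attr(x$codebook, "name") %||% "custom", " (",
      n_targets(x$codebook), " targets), blocks: ",
      length(unique(x$blocks)), ", t0_offset: ", x$t0_offset, " s\n", sep = "")
  invisible(x)
}

#' Number of trials / channels / samples helpers
#' @param x An `ssvep_epochs`.
#' @return Integer count.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' @rdname n_trials
#' @export
n_channels <- function(x) dim(x$data)[2]

#' @rdname n_trials
#' @export
n_samples <- function(x) dim(x$data)[3]

#' Usable epoch extent in seconds, measured from the decoding origin
#' @param x An `ssvep_epochs`.
#' @return Seconds of signal available at and after the origin.
#' @export
epoch_extent <- function(x) {
  n_samples(x) / x$sfreq + x$t0_offset
}

#' Per-trial metadata as a tibble
#'
#' @param x An `ssvep_epochs`.
#' @param ... Unused.
#' @return A tibble with columns `trial`, `target`, `frequency`, `phase`,
#'   `block`.
#' @export
trial_info <- function(x, ...) {
  tibble::tibble(
    trial = seq_len(n_trials(x)),
    target = x$labels,
    frequency = x$codebook$frequency[x$labels],
    phase = x$codebook$phase[x$labels],
    block = x$blocks
  )
}

# Single trial as a channels x samples matrix.
trial_matrix <- function(x, i) {
  m <- x$data[i, , , drop = FALSE]
  dim(m) <- dim(x$data)[2:3]
  m
}

# Subset trials, keeping all metadata consistent.
subset_trials <- function(x, idx) {
  ssvep_epochs(x$data[idx, , , drop = FALSE], x$sfreq, x$labels[idx],
               x$blocks[idx], x$codebook, x$channel_names, x$t0_offset)
}
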