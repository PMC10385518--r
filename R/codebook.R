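#' Stimulus codebooks for frequency-phase coded SSVEP paradigms
#'
#' A codebook is the ordered list of stimulation targets, each defined by a
#' flicker frequency (Hz) and an initial phase (rad). It fixes the target
#' count `N` used by the information-transfer-rate formula and the decoders'
#' reference signals.
#'
#' @param preset One of `"benchmark40"`, `"wearable12"`, `"elder9"`,
#'   `"ucsd12"` or `"custom"`. The named presets mirror the geometries of the
#'   public frequency-phase paradigm datasets (40, 12, 9 and 12 targets);
#'   `"custom"` requires `frequencies` and `phases`.
#' @param frequencies,phases Numeric vectors (Hz, rad) for `preset = "custom"`.
#' @param name Optional codebook label; defaults to the preset name.
#'
#' @return A tibble of class `ssvep_codebook` with columns `target`,
#'   `frequency` and `phase`, one row per stimulation target.
#' @examples
#' make_codebook("benchmark40")
#' make_codebook("custom", frequencies = c(10, 12, 15), phases = c(0, 0, 0))
#' @export
make_codebook <- function(preset = c("benchmark40", "wearable12", "elder9",
                                     "ucsd12", "custom"),
                          frequencies = NULL, phases = NULL, name = NULL) {
  valid <- c("benchmark40", "wearable12", "elder9", "ucsd12", "custom")
  if (!is.character(preset) || length(preset) != 1L || !preset %in% valid) {
    stop("Unknown codebook preset ", deparse(substitute(preset)),
         "; valid presets are: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  if (preset == "custom") {
    if (is.null(frequencies) || is.null(phases)) {
      stop("preset = \"custom\" requires explicit `frequencies` and `phases`",
           call. = FALSE)
    }
  } else {
    geom <- switch(preset,
      # 40-target speller: 8.0-15.8 Hz in 0.2 Hz steps, phases advancing by
      # 0.5*pi along the frequency order (joint frequency-phase coding)
      benchmark40 = list(f = seq(8, 15.8, by = 0.2),
                         p = (0:39) * 0.5 * pi %% (2 * pi)),
      # 12-target wearable grid: 9.25-14.75 Hz in 0.5 Hz steps
      wearable12 = list(f = seq(9.25, 14.75, by = 0.5),
                        p = (0:11) * 0.5 * pi %% (2 * pi)),
      # 9-target keypad
      elder9 = list(f = seq(9, 13, by = 0.5),
                    p = (0:8) * 0.5 * pi %% (2 * pi)),
      # 12-target phone pad: three phase groups across 9.25-14.75 Hz
      ucsd12 = list(f = c(9.25, 11.25, 13.25, 9.75, 11.75, 13.75,
                          10.25, 12.25, 14.25, 10.75, 12.75, 14.75),
                    p = rep(c(0, 0.5, 1, 1.5) * pi, each = 3))
    )
    frequencies <- geom$f
    phases <- geom$p
  }
  new_codebook(frequencies, phases, name = name %||% preset)
}

new_codebook <- function(frequencies, phases, name = "custom") {
  frequencies <- as.numeric(frequencies)
  phases <- as.numeric(phases)
  if (length(frequencies) != length(phases)) {
    stop("`frequencies` and `phases` must have equal length", call. = FALSE)
  }
  if (length(frequencies) < 2L) {
    stop("a codebook needs at least 2 targets", call. = FALSE)
  }
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("all target frequencies must be finite and strictly positive",
         call. = FALSE)
  }
  out <- tibble::tibble(
    target = seq_along(frequencies),
    frequency = frequencies,
    phase = phases %% (2 * pi)
  )
  attr(out, "name") <- name
  class(out) <- c("ssvep_codebook", class(out))
  out
}

#' Number of stimulation targets in a codebook
#' @param codebook An `ssvep_codebook`.
#' @return Integer target count.
#' @export
n_targets <- function(codebook) nrow(codebook)

#' @export
print.ssvep_codebook <- function(x, ...) {
  cat("<ssvep_codebook> ", attr(x, "name") %||% "custom", ": ",
      nrow(x), " targets, ", min(x$frequency), "-", max(x$frequency),
      " Hz\n", sep = "")
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
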