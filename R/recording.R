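#' Uniformly sampled multichannel recording
#'
#' Light-weight container for a uniformly sampled signal: a numeric matrix
#' with one column per channel, a sampling rate in Hz and channel labels.
#' Sample `i` (1-based) covers the half-open interval
#' `[(i-1)/rate, i/rate)` seconds from recording start.
#'
#' @param samples numeric vector (one channel) or matrix (samples x channels).
#' @param rate sampling rate in Hz (> 0).
#' @param labels optional character vector of channel names; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param start_offset time of the first sample in seconds (default 0).
#' @return An object of class `"recording"` with elements `samples`
#'   (matrix), `rate`, `labels` and `start_offset`.
#' @examples
#' rec <- recording(sin(2 * pi * 10 * (0:999) / 250), rate = 250)
#' duration(rec)
#' @export
recording <- function(samples, rate, labels = NULL, start_offset = 0) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (is.null(labels)) labels <- paste0("ch", seq_len(ncol(samples)))
  if (length(labels) != ncol(samples))
    stop("`labels` must have one entry per channel")
  colnames(samples) <- labels
  structure(
    list(samples = samples, rate = as.numeric(rate),
         labels = as.character(labels),
         start_offset = as.numeric(start_offset)),
    class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channel(s) x %d samples @ %g Hz (%.1f s)\n",
              ncol(x$samples), nrow(x$samples), x$rate, duration(x)))
  cat("  channels:", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param x a [recording()].
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "recording"))
  nrow(x$samples) / x$rate
}

#' Extract one channel of a recording as a numeric vector
#' @param x a [recording()].
#' @param channel channel label or index.
#' @return Numeric vector of samples.
#' @export
channel <- function(x, channel = 1L) {
  stopifnot(inherits(x, "recording"))
  x$samples[, channel]
}

#' Frequency band definition
#'
#' @param name band name.
#' @param low_edge,high_edge band edges in Hz, `0 < low < high`.
#' @return Object of class `"band_definition"`.
#' @examples
#' band_definition("sigma", 10, 16)
#' @export
band_definition <- function(name, low_edge, high_edge) {
  if (!(low_edge > 0 && high_edge > low_edge))
    stop("band edges must satisfy 0 < low_edge < high_edge")
  structure(list(name = as.character(name), low_edge = low_edge,
                 high_edge = high_edge),
            class = "band_definition")
}

#' @export
print.band_definition <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low_edge, x$high_edge))
  invisible(x)
}

#' The canonical eight analysis bands
#'
#' Low delta (0.5-2 Hz), high delta (2-4), theta (4-7), alpha (7-10),
#' low sigma (10-12.5), high sigma (12.5-16), beta (16-30) and
#' gamma (30-49 Hz).
#'
#' @return Named list of eight [band_definition()] objects.
#' @export
canonical_bands <- function() {
  defs <- list(
    low_delta  = c(0.5, 2),
    high_delta = c(2, 4),
    theta      = c(4, 7),
    alpha      = c(7, 10),
    low_sigma  = c(10, 12.5),
    high_sigma = c(12.5, 16),
    beta       = c(16, 30),
    gamma      = c(30, 49))
  out <- lapply(names(defs), function(nm)
    band_definition(nm, defs[[nm]][1], defs[[nm]][2]))
  names(out) <- names(defs)
  out
}

#' Broad illustration bands (delta 1-4 Hz, sigma 10-16 Hz)
#'
#' The two broad bands used by the amplitude-modulation demonstration
#' signal: delta as 1-4 Hz and sigma as 10-16 Hz.
#'
#' @return Named list of two [band_definition()] objects.
#' @export
demo_bands <- function() {
  list(delta = band_definition("delta", 1, 4),
       sigma = band_definition("sigma", 10, 16))
}

#' Sleep-stage annotation on a 20-s epoch grid
#'
#' Stage labels use the vocabulary `W`, `N1`, `N2`, `N3`, `R`, `A`
#' (artifact) and `U` (unscored). Epoch `k` (1-based) covers
#' `[20*(k-1), 20*k)` seconds.
#'
#' @param stages character vector of per-epoch labels.
#' @return Object of class `"stage_annotation"`.
#' @export
stage_annotation <- function(stages) {
  stages <- as.character(stages)
  ok <- stages %in% c("W", "N1", "N2", "N3", "R", "A", "U")
  if (!all(ok))
    stop("unknown stage label(s): ", paste(unique(stages[!ok]), collapse = ", "))
  structure(list(stages = stages, epoch_seconds = 20), class = "stage_annotation")
}

#' Artifact mask on a 4-s cell grid
#'
#' Cell `k` (1-based) covers `[4*(k-1), 4*k)` seconds; `TRUE` marks an
#' artifactual cell.
#'
#' @param cells logical vector of per-cell artifact flags.
#' @return Object of class `"artifact_mask"`.
#' @export
artifact_mask <- function(cells) {
  structure(list(cells = as.logical(cells), cell_seconds = 4),
            class = "artifact_mask")
}

#' Does an epoch label belong to a vigilance state?
#'
#' NREM pools stages N1, N2 and N3; REM is stage R.
#'
#' @param stages character vector of stage labels.
#' @param state `"NREM"` or `"REM"`.
#' @return Logical vector.
#' @export
stage_in_state <- function(stages, state = c("NREM", "REM")) {
  state <- match.arg(state)
  if (state == "NREM") stages %in% c("N1", "N2", "N3") else stages == "R"
}
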