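# Welch-averaged one-sided PSD and cross-spectra over explicit segment
# starts; the building block for the ordinary signal spectrum and for
# magnitude-squared coherence.

welch_segments <- function(n, seg_len, overlap) {
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  starts
}

# averaged auto/cross periodograms of x (and optionally y) over segments
# given by 1-based start indices; returns one-sided spectra
welch_spectra <- function(x, y = NULL, rate, seg_len, starts) {
  w <- as.numeric(signal::hamming(seg_len))
  U <- rate * sum(w^2)
  nf <- seg_len %/% 2 + 1
  pxx <- numeric(nf); pyy <- numeric(nf); pxy <- complex(nf)
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1)]
    xs <- (xs - mean(xs)) * w
    X <- stats::fft(xs)[1:nf]
    pxx <- pxx + Mod(X)^2
    if (!is.null(y)) {
      ys <- y[s:(s + seg_len - 1)]
      ys <- (ys - mean(ys)) * w
      Y <- stats::fft(ys)[1:nf]
      pyy <- pyy + Mod(Y)^2
      pxy <- pxy + X * Conj(Y)
    }
  }
  k <- length(starts)
  scale1 <- c(1, rep(2, nf - 2), if (seg_len %% 2 == 0) 1 else 2)
  out <- list(freq = (0:(nf - 1)) * rate / seg_len,
              pxx = scale1 * pxx / (k * U))
  if (!is.null(y)) {
    out$pyy <- scale1 * pyy / (k * U)
    out$pxy <- scale1 * pxy / (k * U)
  }
  out
}

#' Welch power spectral density of a signal
#'
#' Hamming-tapered, segment-demeaned Welch estimate.
#'
#' @param x numeric vector.
#' @param rate sampling rate in Hz.
#' @param seg_seconds segment length in seconds (default 4, giving
#'   0.25 Hz resolution).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return List with `freq` and `density`.
#' @export
welch_psd <- function(x, rate, seg_seconds = 4, overlap = 0.5) {
  seg_len <- round(seg_seconds * rate)
  if (length(x) < seg_len) stop("signal shorter than one segment")
  sp <- welch_spectra(x, NULL, rate, seg_len,
                      welch_segments(length(x), seg_len, overlap))
  list(freq = sp$freq, density = sp$pxx)
}

#' Ordinary signal spectrum over clean in-state epochs
#'
#' Welch estimate of the (unfiltered) signal PSD restricted to
#' artifact-free, in-state data: 4-s Hamming-tapered epochs with 50%
#' overlap (0.25 Hz resolution), an epoch entering only when every 4-s
#' mask cell it touches is clean and in-state. The averaged density is
#' log10-transformed and reported on the 0-48 Hz grid (193 bins).
#'
#' @param rec a [recording()].
#' @param mask an [artifact_mask()]; `NULL` for all-clean.
#' @param stages a [stage_annotation()]; `NULL` to use all data.
#' @param state `"NREM"` or `"REM"` (ignored when `stages` is `NULL`).
#' @param max_hz upper frequency bound (default 48).
#' @return List with `freq`, `log_density` (channels in columns) and
#'   `n_epochs`.
#' @export
signal_psd_welch <- function(rec, mask = NULL, stages = NULL,
                             state = c("NREM", "REM"), max_hz = 48) {
  state <- match.arg(state)
  stopifnot(inherits(rec, "recording"))
  n <- nrow(rec$samples)
  seg_len <- round(4 * rec$rate)
  starts_t <- seq(0, duration(rec) - 4, by = 2)
  ok <- rep(TRUE, length(starts_t))
  if (!is.null(mask) || !is.null(stages)) {
    cell_ok <- rep(TRUE, ceiling(duration(rec) / 4))
    if (!is.null(mask)) cell_ok <- cell_ok & !mask$cells
    if (!is.null(stages))
      cell_ok <- cell_ok & rep(stage_in_state(stages$stages, state), each = 5)
    ok <- vapply(starts_t, function(s) {
      cells <- (floor(s / 4) + 1):(ceiling((s + 4) / 4))
      all(cell_ok[cells])
    }, TRUE)
  }
  if (!any(ok)) stop("no clean in-state 4-s epoch available")
  starts <- round(starts_t[ok] * rec$rate) + 1
  keep <- NULL
  out <- apply(rec$samples, 2, function(v) {
    sp <- welch_spectra(v, NULL, rec$rate, seg_len, starts)
    keep <<- sp$freq <= max_hz + 1e-9
    log10(sp$pxx[keep])
  })
  sp_freq <- (0:(seg_len %/% 2)) * rec$rate / seg_len
  list(freq = sp_freq[sp_freq <= max_hz + 1e-9],
       log_density = as.matrix(out), n_epochs = sum(ok))
}
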