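#' Plan artifact-adaptive ("colliding") sampling windows
#'
#' Places 100-s analysis windows on a 20-s grid over the artifact-free,
#' in-state parts of a recording. A window whose extent would run into an
#' artifact cell or a vigilance-state boundary is progressively shortened
#' to end at that obstruction, down to a minimum of 20 s; shorter
#' candidates are dropped and full-length placement resumes at the next
#' clean in-state grid point after the obstruction. The backward pass
#' mirrors this from the recording end, so data just after obstructions
#' (and at the recording tail) is covered as well; together the two
#' passes lose at most 20 s of clean signal around an isolated artifact.
#' Shortened windows carry weight `L/100` and cannot estimate frequencies
#' below `1/L` Hz.
#'
#' @param mask an [artifact_mask()] (4-s cells).
#' @param stages a [stage_annotation()] (20-s epochs) covering the same
#'   duration.
#' @param state `"NREM"` (pooling N1/N2/N3) or `"REM"`.
#' @param direction `"forward"`, `"backward"` or `"both"` (default; the
#'   two passes pooled, duplicate windows counted once).
#' @param window_seconds nominal window length (default 100).
#' @param step_seconds candidate grid step (default 20).
#' @param min_seconds minimum shortened length (default 20).
#' @return A data.frame with columns `start`, `length`, `direction`,
#'   `weight` (`length/window_seconds`) and `min_valid_freq` (`1/length`
#'   Hz); zero rows (with a warning) if no clean in-state run is long
#'   enough.
#' @export
plan_windows <- function(mask, stages, state = c("NREM", "REM"),
                         direction = c("both", "forward", "backward"),
                         window_seconds = 100, step_seconds = 20,
                         min_seconds = 20) {
  state <- match.arg(state)
  direction <- match.arg(direction)
  stopifnot(inherits(mask, "artifact_mask"), inherits(stages, "stage_annotation"))
  cell_s <- mask$cell_seconds
  dur <- length(mask$cells) * cell_s
  if (length(stages$stages) * stages$epoch_seconds != dur)
    stop("mask and stage annotation cover different durations")
  # validity at 4-s resolution: clean and in-state
  per_cell_state <- rep(stage_in_state(stages$stages, state),
                        each = stages$epoch_seconds / cell_s)
  valid <- !mask$cells & per_cell_state

  # run end (s) of the contiguous valid stretch containing each cell
  n_cells <- length(valid)
  run_end <- numeric(n_cells)
  nxt <- dur
  for (i in n_cells:1) {
    if (!valid[i]) nxt <- (i - 1) * cell_s
    run_end[i] <- nxt
  }

  emit_forward <- function() {
    starts <- seq(0, dur - min_seconds, by = step_seconds)
    out <- list()
    for (s in starts) {
      ci <- s %/% cell_s + 1
      if (ci > n_cells || !valid[ci]) next
      re <- run_end[ci]
      if (re >= s + window_seconds) {
        out[[length(out) + 1]] <- c(s, window_seconds)
      } else if (re < dur) {
        # obstructed by an artifact/state boundary: truncate
        L <- re - s
        if (L >= min_seconds) out[[length(out) + 1]] <- c(s, L)
      }
      # run ending at the recording end without room for a full window:
      # left to the backward pass
    }
    out
  }

  fw <- if (direction %in% c("forward", "both")) emit_forward() else list()
  bw <- list()
  if (direction %in% c("backward", "both")) {
    # mirror: reverse validity, plan forward, map back
    rev_mask <- artifact_mask(rev(mask$cells))
    rev_stages <- stage_annotation(rev(stages$stages))
    rev_pw <- suppressWarnings(
      plan_windows(rev_mask, rev_stages, state, "forward",
                   window_seconds, step_seconds, min_seconds))
    bw <- lapply(seq_len(nrow(rev_pw)), function(i)
      c(dur - rev_pw$start[i] - rev_pw$length[i], rev_pw$length[i]))
  }

  all <- c(fw, bw)
  dirs <- c(rep("forward", length(fw)), rep("backward", length(bw)))
  if (length(all) == 0) {
    warning(sprintf("no clean in-state run of >= %g s; no windows planned",
                    min_seconds))
    return(data.frame(start = numeric(0), length = numeric(0),
                      direction = character(0), weight = numeric(0),
                      min_valid_freq = numeric(0)))
  }
  df <- data.frame(start = vapply(all, `[`, 0, 1),
                   length = vapply(all, `[`, 0, 2),
                   direction = dirs)
  # duplicate windows from the two passes contribute once
  df <- df[!duplicated(df[, c("start", "length")]), , drop = FALSE]
  df <- df[order(df$start, df$length), , drop = FALSE]
  df$weight <- df$length / window_seconds
  df$min_valid_freq <- 1 / df$length
  rownames(df) <- NULL
  df
}

#' Total clean in-state signal left uncovered by a window plan
#'
#' @param windows window plan from [plan_windows()].
#' @param mask,stages,state as in [plan_windows()].
#' @return Uncovered clean in-state duration in seconds.
#' @export
uncovered_clean_seconds <- function(windows, mask, stages,
                                    state = c("NREM", "REM")) {
  state <- match.arg(state)
  cell_s <- mask$cell_seconds
  per_cell_state <- rep(stage_in_state(stages$stages, state),
                        each = stages$epoch_seconds / cell_s)
  valid <- !mask$cells & per_cell_state
  covered <- rep(FALSE, length(valid))
  for (i in seq_len(nrow(windows))) {
    a <- windows$start[i] %/% cell_s + 1
    b <- (windows$start[i] + windows$length[i]) %/% cell_s
    covered[a:b] <- TRUE
  }
  sum(valid & !covered) * cell_s
}

#' Single-window periodogram of an envelope segment on the 0.01 Hz grid
#'
#' The segment is linearly detrended (which also demeans it), tapered
#' with a Hamming window and its one-sided power spectral density is
#' evaluated on the fixed 0.01-4.00 Hz grid (400 bins) by zero-padded
#' DFT. Bins below `1/L` Hz (the window's minimum estimable frequency)
#' are marked invalid.
#'
#' @param segment numeric vector, an envelope slice of `L * rate` samples
#'   with `20 <= L <= 100` (seconds).
#' @param rate sampling rate in Hz.
#' @return List with `freq` (400 frequencies), `density` (PSD,
#'   amplitude^2 per Hz), `valid` (logical), `L` (seconds) and `weight`
#'   (`L/100`).
#' @export
window_psd <- function(segment, rate) {
  if (any(!is.finite(segment)))
    stop("segment contains non-finite values (artifact leakage upstream)")
  n <- length(segment)
  L <- n / rate
  if (L < 20 - 1e-9 || L > 100 + 1e-9)
    stop("segment length must be between 20 and 100 seconds")
  # linear detrend (includes demeaning)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), segment)
  x <- fit$residuals
  w <- as.numeric(signal::hamming(n))
  xw <- x * w
  nfft <- round(100 * rate)             # 0.01 Hz bin spacing
  X <- stats::fft(c(xw, numeric(nfft - n)))
  k <- 1:400                            # 0.01 .. 4.00 Hz
  dens <- 2 * Mod(X[k + 1])^2 / (rate * sum(w^2))
  kmin <- ceiling(100 / L - 1e-9)       # lowest valid bin: freq >= 1/L
  list(freq = k / 100, density = dens, valid = k >= kmin,
       L = L, weight = L / 100)
}

#' Weighted aggregation of single-window envelope spectra
#'
#' Per-frequency weighted mean over windows (forward and backward passes
#' pooled), each window weighted by `L/100` and contributing only at
#' frequencies at or above its minimum estimable frequency `1/L` Hz.
#'
#' @param wpsds list of single-window spectra from [window_psd()].
#' @return List of class `"envelope_psd_raw"` with `freq`, `density`
#'   (weighted mean; `NA` where no window was valid), `total_weight`
#'   per frequency and `n_windows`.
#' @export
aggregate_psd <- function(wpsds) {
  if (length(wpsds) < 1) stop("need at least one window")
  freq <- wpsds[[1]]$freq
  num <- numeric(length(freq))
  den <- numeric(length(freq))
  for (p in wpsds) {
    wv <- p$weight * p$valid
    num <- num + wv * ifelse(p$valid, p$density, 0)
    den <- den + wv
  }
  if (all(den == 0)) stop("all windows invalid at every frequency")
  density <- ifelse(den > 0, num / den, NA_real_)
  structure(list(freq = freq, density = density, total_weight = den,
                 n_windows = length(wpsds), stage = "raw-average"),
            class = "envelope_psd_raw")
}

#' Smooth, log-transform and z-normalize an aggregated envelope spectrum
#'
#' Savitzky-Golay smoothing (polynomial order 10, default frame 21 bins
#' = 0.21 Hz), 10-base log transform, then z-scoring across the
#' 0.01-2.00 Hz analysis sub-grid. Missing bins inside the analysis
#' sub-grid are linearly interpolated first (with a message); densities
#' that are non-positive after smoothing are clipped to the smallest
#' positive observed density (with a message).
#'
#' @param p an `"envelope_psd_raw"` from [aggregate_psd()].
#' @param sg_order Savitzky-Golay polynomial order (default 10).
#' @param sg_frame Savitzky-Golay frame length in bins (odd; default 21).
#' @param analysis_max_hz upper edge of the z-scored analysis sub-grid
#'   (default 2).
#' @return List of class `"envelope_psd_post"` with `freq`, `smoothed`
#'   (smoothed density), `log_density` (log10), `z` (z-scored values on
#'   the analysis sub-grid), `analysis_freq` and `stage = "z"`.
#' @export
postprocess_psd <- function(p, sg_order = 10, sg_frame = 21,
                            analysis_max_hz = 2) {
  stopifnot(inherits(p, "envelope_psd_raw"))
  d <- p$density
  sub <- which(p$freq <= analysis_max_hz + 1e-9)
  if (any(is.na(d[sub]))) {
    message("interpolating ", sum(is.na(d[sub])),
            " missing bin(s) inside the analysis sub-grid")
  }
  if (any(is.na(d))) {
    ok <- which(!is.na(d))
    d <- stats::approx(p$freq[ok], d[ok], xout = p$freq, rule = 2)$y
  }
  sm <- signal::sgolayfilt(d, p = sg_order, n = sg_frame)
  if (any(sm <= 0)) {
    floor_val <- min(sm[sm > 0], d[d > 0])
    if (!is.finite(floor_val)) stop("flat or non-positive density; cannot log-transform")
    message("clipping ", sum(sm <= 0), " non-positive smoothed bin(s)")
    sm[sm <= 0] <- floor_val
  }
  lg <- log10(sm)
  lsub <- lg[sub]
  s <- stats::sd(lsub) * sqrt((length(lsub) - 1) / length(lsub))
  if (s <= 1e-8 * (abs(mean(lsub)) + 1e-12))
    stop("degenerate (flat) spectrum: z-transform undefined")
  z <- (lsub - mean(lsub)) / s
  structure(list(freq = p$freq, smoothed = sm, log_density = lg,
                 z = z, analysis_freq = p$freq[sub],
                 total_weight = p$total_weight, stage = "z"),
            class = "envelope_psd_post")
}

#' Envelope power spectral density via the colliding-window method
#'
#' The full estimation path for one recording: for every band x channel,
#' zero-phase band filtering, Hilbert envelope of the continuous filtered
#' signal, artifact-adaptive window planning (forward and backward
#' passes), per-window periodograms on the 0.01 Hz grid, length-weighted
#' aggregation, and post-processing (Savitzky-Golay smoothing, log10,
#' z-scoring across the 0.01-2 Hz analysis sub-grid).
#'
#' @param rec a [recording()].
#' @param mask an [artifact_mask()].
#' @param stages a [stage_annotation()].
#' @param state `"NREM"` or `"REM"`.
#' @param bands named list of [band_definition()]s (default the canonical
#'   eight; see also [demo_bands()]).
#' @param keep_windows if `TRUE`, retain per-window spectra (needed for
#'   reliability analyses).
#' @param ... window parameters passed to [plan_windows()].
#' @return Object of class `"envelope_psd"`: `freq` (400 bins),
#'   `analysis_freq` (sub-grid), `raw`, `smoothed_log` (band x channel x
#'   400 arrays), `z` (band x channel x sub-grid array), `windows` (the
#'   plan), `state`, and if requested `window_psds` (band x channel list
#'   of per-window density matrices).
#' @export
envelope_spectrum <- function(rec, mask, stages, state = c("NREM", "REM"),
                              bands = canonical_bands(),
                              keep_windows = FALSE, ...) {
  state <- match.arg(state)
  stopifnot(inherits(rec, "recording"))
  win <- plan_windows(mask, stages, state, "both", ...)
  if (nrow(win) == 0) stop("no usable windows for state ", state)
  nb <- length(bands)
  nc <- ncol(rec$samples)
  bnames <- if (!is.null(names(bands))) names(bands) else
    vapply(bands, function(b) b$name, "")
  raw <- array(NA_real_, c(nb, nc, 400),
               dimnames = list(bnames, rec$labels, NULL))
  slog <- raw
  zarr <- NULL
  wlist <- if (keep_windows) vector("list", nb * nc) else NULL
  tw <- NULL
  for (bi in seq_len(nb)) {
    filt <- band_filter(rec, bands[[bi]])
    env <- hilbert_envelope(filt)
    for (ci in seq_len(nc)) {
      e <- env$samples[, ci]
      wp <- lapply(seq_len(nrow(win)), function(i) {
        a <- round(win$start[i] * rec$rate) + 1
        b <- round((win$start[i] + win$length[i]) * rec$rate)
        window_psd(e[a:b], rec$rate)
      })
      agg <- aggregate_psd(wp)
      post <- postprocess_psd(agg)
      if (is.null(zarr))
        zarr <- array(NA_real_, c(nb, nc, length(post$z)),
                      dimnames = list(bnames, rec$labels, NULL))
      raw[bi, ci, ] <- agg$density
      slog[bi, ci, ] <- post$log_density
      zarr[bi, ci, ] <- post$z
      tw <- agg$total_weight
      if (keep_windows)
        wlist[[(bi - 1) * nc + ci]] <-
          t(vapply(wp, function(p) p$density, numeric(400)))
    }
  }
  out <- list(freq = (1:400) / 100, analysis_freq = (1:dim(zarr)[3]) / 100,
              bands = bnames, channels = rec$labels,
              raw = raw, smoothed_log = slog, z = zarr,
              total_weight = tw, windows = win, state = state)
  if (keep_windows) {
    dim(wlist) <- c(nc, nb)  # filled channel-fastest
    out$window_psds <- wlist
  }
  structure(out, class = "envelope_psd")
}

#' @export
print.envelope_psd <- function(x, ...) {
  cat(sprintf("<envelope_psd> %s: %d band(s) x %d channel(s), %d windows\n",
              x$state, length(x$bands), length(x$channels), nrow(x$windows)))
  cat(sprintf("  grid 0.01-%.2f Hz (analysis sub-grid to %.2f Hz)\n",
              max(x$freq), max(x$analysis_freq)))
  sh <- x$windows$length < max(x$windows$length)
  cat(sprintf("  windows: %d full, %d shortened; total weight at 0.01 Hz: %.2f\n",
              sum(!sh), sum(sh), x$total_weight[1]))
  invisible(x)
}

#' @export
plot.envelope_psd <- function(x, band = 1, channel = 1,
                              stage = c("z", "raw"), ...) {
  stage <- match.arg(stage)
  if (stage == "z") {
    graphics::plot(x$analysis_freq, x$z[band, channel, ], type = "l",
                   xlab = "Envelope frequency (Hz)", ylab = "z(log10 PSD)",
                   main = sprintf("%s envelope spectrum (%s)",
                                  x$bands[band], x$state), ...)
  } else {
    graphics::plot(x$freq, x$raw[band, channel, ], type = "l", log = "y",
                   xlab = "Envelope frequency (Hz)", ylab = "PSD",
                   main = sprintf("%s envelope spectrum (%s)",
                                  x$bands[band], x$state), ...)
  }
  invisible(x)
}

#' Flag subjects with abnormal envelope spectra
#'
#' Reproducible surrogate for visual quality screening: within each band,
#' a subject is flagged when its log-spectrum deviates from the cohort
#' mean by more than `sd_limit` cohort SDs at more than `frac_limit` of
#' bins. Flagged subjects are reported, never dropped.
#'
#' @param spectra array subjects x bands x frequencies of log (or z)
#'   spectral values.
#' @param sd_limit deviation threshold in cohort SDs (default 5).
#' @param frac_limit fraction of deviant bins that triggers the flag
#'   (default 0.1).
#' @return Logical matrix subjects x bands.
#' @export
flag_abnormal_spectra <- function(spectra, sd_limit = 5, frac_limit = 0.1) {
  stopifnot(length(dim(spectra)) == 3)
  ns <- dim(spectra)[1]; nb <- dim(spectra)[2]
  out <- matrix(FALSE, ns, nb,
                dimnames = dimnames(spectra)[1:2])
  for (b in seq_len(nb)) {
    m <- apply(spectra[, b, , drop = FALSE], 3, mean)
    s <- apply(spectra[, b, , drop = FALSE], 3, stats::sd)
    s[s == 0] <- Inf
    for (i in seq_len(ns)) {
      dev <- abs(spectra[i, b, ] - m) / s
      out[i, b] <- mean(dev > sd_limit) > frac_limit
    }
  }
  out
}
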