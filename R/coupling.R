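#' Non-overlapping clean in-state 20-s segment starts
#'
#' @param mask an [artifact_mask()].
#' @param stages a [stage_annotation()].
#' @param state `"NREM"` or `"REM"`.
#' @param seg_seconds segment length (default 20).
#' @return Numeric vector of segment start times in seconds.
#' @export
segment_starts <- function(mask, stages, state = c("NREM", "REM"),
                           seg_seconds = 20) {
  state <- match.arg(state)
  cell_s <- mask$cell_seconds
  per_cell_state <- rep(stage_in_state(stages$stages, state),
                        each = stages$epoch_seconds / cell_s)
  valid <- !mask$cells & per_cell_state
  dur <- length(valid) * cell_s
  starts <- seq(0, dur - seg_seconds, by = seg_seconds)
  keep <- vapply(starts, function(s) {
    cells <- (s %/% cell_s + 1):((s + seg_seconds) %/% cell_s)
    all(valid[cells])
  }, TRUE)
  starts[keep]
}

# slice a numeric vector into per-segment pieces
slice_segments <- function(x, rate, starts, seg_seconds = 20) {
  lapply(starts, function(s) {
    a <- round(s * rate) + 1
    x[a:(a + round(seg_seconds * rate) - 1)]
  })
}

# demean + linear detrend
detrend_linear <- function(x) {
  n <- length(x)
  stats::lm.fit(cbind(1, seq_len(n)), x)$residuals
}

#' Coefficient-normalized cross-correlation of two segments
#'
#' Both inputs are demeaned and linearly detrended, then the
#' cross-correlation `r(lag) = sum(x[t] * y[t + lag])` normalized by the
#' square root of the product of the zero-lag energies is evaluated at
#' every integer-sample lag within `max_lag` seconds. A positive-lag
#' extremum means `y` trails `x`.
#'
#' @param x,y equal-length numeric vectors at the same rate.
#' @param rate sampling rate in Hz.
#' @param max_lag maximum lag in seconds (default 1).
#' @return List with `lag` (seconds) and `r` (in `[-1, 1]`; all `NA` if
#'   either input has zero variance).
#' @export
crosscorr_norm <- function(x, y, rate, max_lag = 1) {
  stopifnot(length(x) == length(y))
  L <- round(max_lag * rate)
  lags <- (-L):L
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(lag = lags / rate, r = rep(NA_real_, length(lags))))
  x <- detrend_linear(x); y <- detrend_linear(y)
  denom <- sqrt(sum(x^2) * sum(y^2))
  if (denom == 0)
    return(list(lag = lags / rate, r = rep(NA_real_, length(lags))))
  n <- length(x)
  # FFT cross-correlation: c(l) = sum_t x[t] y[t+l]
  nfft <- stats::nextn(n + L, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- stats::fft(c(y, numeric(nfft - n)))
  cc <- Re(stats::fft(Conj(X) * Y, inverse = TRUE)) / nfft
  r <- numeric(length(lags))
  pos <- lags >= 0
  r[pos] <- cc[lags[pos] + 1]
  r[!pos] <- cc[nfft + lags[!pos] + 1]
  list(lag = lags / rate, r = r / denom)
}

#' Magnitude-squared coherence between two segments
#'
#' Welch-type coherence using Hamming-tapered sub-windows (default 10 s
#' with 50% overlap inside a 20-s segment, the shortest configuration
#' with 0.1 Hz native resolution), evaluated at 0.1, 0.2, ..., 1.0 Hz.
#'
#' @param x,y equal-length numeric vectors.
#' @param rate sampling rate in Hz.
#' @param sub_seconds sub-window length in seconds (default 10).
#' @param overlap fractional sub-window overlap (default 0.5).
#' @param freqs evaluation frequencies in Hz (default `seq(0.1, 1, 0.1)`).
#' @return List with `freq` and `coherence` (in `[0, 1]`; `NA` on
#'   zero-variance input).
#' @export
mscoherence <- function(x, y, rate, sub_seconds = 10, overlap = 0.5,
                        freqs = seq(0.1, 1, by = 0.1)) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(freq = freqs, coherence = rep(NA_real_, length(freqs))))
  seg_len <- round(sub_seconds * rate)
  sp <- welch_spectra(x, y, rate, seg_len,
                      welch_segments(length(x), seg_len, overlap))
  idx <- match(round(freqs * sub_seconds), round(sp$freq * sub_seconds))
  if (any(is.na(idx)))
    stop("requested frequencies are not on the sub-window's native grid")
  coh <- Mod(sp$pxy[idx])^2 / (sp$pxx[idx] * sp$pyy[idx])
  list(freq = freqs, coherence = pmin(coh, 1))
}

#' Phase-binned amplitude profile (phase-amplitude coupling)
#'
#' Instantaneous phase of the demeaned `phase_signal` (analytic-signal
#' angle; phase 0 at its positive peak) is split into 12 bins of 30
#' degrees, `[0, 30), ..., [330, 360)`; the `amplitude` series is
#' z-scored within the segment and averaged per bin.
#'
#' @param amplitude numeric vector (e.g. a band envelope segment).
#' @param phase_signal numeric vector providing the phase (e.g. the
#'   band-smoothed firing proxy).
#' @param n_bins number of phase bins (default 12).
#' @return Numeric vector of `n_bins` mean z-scored amplitudes (in
#'   within-segment SD units); `NA` for empty bins.
#' @export
phase_amplitude_profile <- function(amplitude, phase_signal, n_bins = 12) {
  stopifnot(length(amplitude) == length(phase_signal))
  if (stats::sd(amplitude) == 0 || stats::sd(phase_signal) == 0)
    return(rep(NA_real_, n_bins))
  ph <- instantaneous_phase(phase_signal - mean(phase_signal))
  deg <- (ph * 180 / pi) %% 360
  z <- as.numeric(scale(amplitude))
  bin <- pmin(floor(deg / (360 / n_bins)) + 1, n_bins)
  out <- rep(NA_real_, n_bins)
  agg <- tapply(z, factor(bin, levels = seq_len(n_bins)), mean)
  out[] <- as.numeric(agg)
  out
}

#' Surrogate-based empirical p-values for segment-averaged statistics
#'
#' The observed statistic is the mean of `stat_fun(env[[i]], mua[[i]])`
#' over matched segments. Each of `n` surrogates re-pairs every envelope
#' segment with a uniformly random (with replacement, self-pairing
#' allowed) partner segment and recomputes the segment-averaged
#' statistic; the two-sided empirical p-value per statistic element is
#' `(1 + #(|surrogate| >= |observed|)) / (n + 1)`.
#'
#' Per-pair statistic values are cached, so the surrogate loop indexes a
#' pair matrix instead of recomputing; results are identical to direct
#' recomputation.
#'
#' @param stat_fun function of two segments returning a numeric scalar or
#'   vector (constant length).
#' @param env_segments,mua_segments lists of equal count (>= 2) of
#'   numeric segments.
#' @param n number of surrogates (default 1000).
#' @param seed integer seed for the random pairings.
#' @return List of class `"surrogate_null"` with `observed`, `p`,
#'   `surrogates` (n x K matrix) and `n`.
#' @export
surrogate_p <- function(stat_fun, env_segments, mua_segments, n = 1000,
                        seed = 1L) {
  N <- length(env_segments)
  stopifnot(N == length(mua_segments))
  if (N < 2) stop("need at least 2 segments")
  if (n < 1) stop("need at least 1 surrogate")
  pair_stat <- matrix(list(), N, N)
  get_stat <- function(i, j) {
    v <- pair_stat[[i, j]]
    if (is.null(v)) {
      v <- stat_fun(env_segments[[i]], mua_segments[[j]])
      pair_stat[[i, j]] <<- v
    }
    v
  }
  obs_terms <- lapply(seq_len(N), function(i) get_stat(i, i))
  K <- length(obs_terms[[1]])
  observed <- colMeans(do.call(rbind, obs_terms), na.rm = TRUE)
  set.seed(seed)
  surro <- matrix(NA_real_, n, K)
  for (s in seq_len(n)) {
    j <- sample.int(N, N, replace = TRUE)
    acc <- matrix(NA_real_, N, K)
    for (i in seq_len(N)) acc[i, ] <- get_stat(i, j[i])
    surro[s, ] <- colMeans(acc, na.rm = TRUE)
  }
  exceed <- colSums(abs(surro) >= matrix(abs(observed), n, K, byrow = TRUE))
  p <- (1 + exceed) / (n + 1)
  structure(list(observed = observed, p = p, surrogates = surro, n = n),
            class = "surrogate_null")
}

#' Pool per-subject empirical p-values via averaged normal deviates
#'
#' Each p-value is transformed to a standard normal deviate
#' `z = qnorm(1 - p)`, the deviates are averaged without weights across
#' subjects, and the mean is transformed back:
#' `pooled = 1 - pnorm(mean(z))`. Unweighted averaging keeps the pooled
#' test conservative: no subject gains influence from having more data,
#' and pooling does not add power beyond the individual subjects.
#'
#' @param p vector of p-values in `(0, 1]`; zeros are floored to
#'   `1/(n_surrogates + 1)` with a message.
#' @param n_surrogates surrogate count used for the floor (default 1000).
#' @return Pooled p-value.
#' @export
pool_pvalues <- function(p, n_surrogates = 1000) {
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    message("flooring ", sum(p == 0), " zero p-value(s) to 1/(n+1)")
    p[p == 0] <- 1 / (n_surrogates + 1)
  }
  z <- stats::qnorm(1 - p)
  1 - stats::pnorm(mean(z))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted p-values (via [stats::p.adjust()]) and the rejection
#' set at level `q`, applied within one test family.
#'
#' @param pvals vector of p-values.
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and `reject` (logical).
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (length(pvals) == 0)
    return(list(adjusted = numeric(0), reject = logical(0)))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, reject = adj <= q)
}

#' Envelope-firing coupling analysis for one channel pair
#'
#' Computes the three segment-averaged coupling statistics between a
#' band envelope and a firing proxy over non-overlapping 20-s clean
#' NREM segments: normalized cross-correlation (lags within 1 s),
#' magnitude-squared coherence (0.1-1 Hz) and the 12-bin phase-amplitude
#' profile (mean z-scored envelope amplitude by firing-proxy phase).
#' Optionally attaches surrogate-based empirical p-values per statistic
#' element.
#'
#' @param ecog single-channel [recording()] of the cortical signal.
#' @param mua single-channel [recording()] of the firing proxy (same
#'   rate), already rectified/low-passed (see [compute_mua()]).
#' @param band a [band_definition()].
#' @param mask,stages annotations; `NULL` treats the whole recording as
#'   clean NREM.
#' @param n_surrogates surrogate count (0 skips inference).
#' @param seed seed for surrogate pairings.
#' @return Object of class `"coupling_result"` with elements `lag`, `crosscorr`,
#'   `coh_freq`, `coherence`, `phase_profile`, segment count, and (when
#'   requested) `p_crosscorr`, `p_coherence`, `p_phase`.
#' @export
coupling_analysis <- function(ecog, mua, band, mask = NULL, stages = NULL,
                              n_surrogates = 0, seed = 1L) {
  stopifnot(inherits(ecog, "recording"), inherits(mua, "recording"),
            ecog$rate == mua$rate)
  rate <- ecog$rate
  if (is.null(mask) || is.null(stages)) {
    dur <- floor(duration(ecog) / 20) * 20
    ann <- make_mask_and_stages(dur, list(),
                                list(list(stage = "N2", start = 0, end = dur)))
    mask <- ann$mask; stages <- ann$stages
  }
  starts <- segment_starts(mask, stages, "NREM")
  if (length(starts) < 2) stop("need at least 2 clean NREM segments")
  filt <- band_filter(ecog, band)
  env_full <- hilbert_envelope(filt)$samples[, 1]
  mua_s <- smooth_mua_for_band(mua, band)$samples[, 1]
  env_seg <- slice_segments(env_full, rate, starts)
  mua_seg <- slice_segments(mua_s, rate, starts)

  cc_f <- function(e, m) crosscorr_norm(e, m, rate)$r
  coh_f <- function(e, m) mscoherence(e, m, rate)$coherence
  pac_f <- function(e, m) phase_amplitude_profile(e, m)

  seg_mean <- function(f) {
    vals <- do.call(rbind, Map(f, env_seg, mua_seg))
    colMeans(vals, na.rm = TRUE)
  }
  out <- list(
    lag = crosscorr_norm(env_seg[[1]], mua_seg[[1]], rate)$lag,
    crosscorr = seg_mean(cc_f),
    coh_freq = seq(0.1, 1, by = 0.1),
    coherence = seg_mean(coh_f),
    phase_bins = seq(0, 330, by = 30),
    phase_profile = seg_mean(pac_f),
    n_segments = length(starts),
    band = band$name)
  if (n_surrogates > 0) {
    out$p_crosscorr <- surrogate_p(cc_f, env_seg, mua_seg,
                                   n_surrogates, seed)$p
    out$p_coherence <- surrogate_p(coh_f, env_seg, mua_seg,
                                   n_surrogates, seed + 1L)$p
    out$p_phase <- surrogate_p(pac_f, env_seg, mua_seg,
                               n_surrogates, seed + 2L)$p
  }
  structure(out, class = "coupling_result")
}

#' @export
print.coupling_result <- function(x, ...) {
  pk <- which.max(abs(x$crosscorr))
  cat(sprintf("<coupling_result> band %s, %d segments\n",
              x$band, x$n_segments))
  cat(sprintf("  crosscorr extremum %.3f at lag %+.3f s\n",
              x$crosscorr[pk], x$lag[pk]))
  cat(sprintf("  mean coherence (0.1-1 Hz): %.3f\n", mean(x$coherence)))
  cat(sprintf("  phase profile max at [%d, %d) deg\n",
              x$phase_bins[which.max(x$phase_profile)],
              x$phase_bins[which.max(x$phase_profile)] + 30))
  invisible(x)
}

#' Normalized-entropy modulation index of a phase-binned profile
#'
#' Kullback-Leibler-based modulation index: the mean amplitude per phase
#' bin is normalized to a distribution P, and
#' `MI = (log(K) + sum(P log P)) / log(K)`; 0 for a flat profile, 1 for
#' amplitude concentrated in one bin. Requires non-negative amplitudes
#' and all bins occupied.
#'
#' @param amplitude non-negative numeric vector.
#' @param phase_signal numeric vector providing the phase.
#' @param n_bins number of phase bins (default 12).
#' @return Modulation index in `[0, 1]` (`NA` if any bin is empty).
#' @export
modulation_index <- function(amplitude, phase_signal, n_bins = 12) {
  if (stats::sd(phase_signal) == 0)
    stop("constant phase signal: phase undefined")
  ph <- instantaneous_phase(phase_signal - mean(phase_signal))
  deg <- (ph * 180 / pi) %% 360
  bin <- pmin(floor(deg / (360 / n_bins)) + 1, n_bins)
  m <- tapply(amplitude, factor(bin, levels = seq_len(n_bins)), mean)
  if (any(is.na(m)) || any(m < 0) || sum(m) == 0) return(NA_real_)
  P <- as.numeric(m) / sum(m)
  H <- -sum(ifelse(P > 0, P * log(P), 0))
  (log(n_bins) - H) / log(n_bins)
}

#' Coupling between a band envelope and respiratory activity
#'
#' Splits both series into 100-s windows with 50% overlap (artifact-free
#' when a mask is given), computes per-window magnitude-squared coherence
#' (averaged over `coh_freqs`) and the modulation index of envelope
#' amplitude by respiration phase, averages across windows, and derives
#' empirical p-values from window-shuffled surrogate pairings.
#'
#' @param env numeric vector, a band envelope.
#' @param resp numeric vector, respiration, same rate and length.
#' @param rate sampling rate in Hz.
#' @param window_seconds window length (default 100).
#' @param overlap fractional window overlap (default 0.5).
#' @param coh_freqs frequencies (Hz) over which window coherence is
#'   averaged (default 0.1-0.5 Hz, the respiratory range).
#' @param n_surrogates surrogate count (default 1000).
#' @param seed seed.
#' @param mask optional [artifact_mask()]; windows touching artifact
#'   cells are excluded.
#' @return List with `coherence`, `p_coherence`, `mi`, `p_mi`,
#'   `n_windows`.
#' @export
respiration_coupling <- function(env, resp, rate, window_seconds = 100,
                                 overlap = 0.5,
                                 coh_freqs = seq(0.1, 0.5, by = 0.1),
                                 n_surrogates = 1000, seed = 1L,
                                 mask = NULL) {
  stopifnot(length(env) == length(resp))
  if (stats::sd(resp) == 0) stop("constant respiration: phase undefined")
  dur <- length(env) / rate
  step <- window_seconds * (1 - overlap)
  starts <- seq(0, dur - window_seconds, by = step)
  if (!is.null(mask)) {
    keep <- vapply(starts, function(s) {
      cells <- (s %/% 4 + 1):((s + window_seconds) %/% 4)
      !any(mask$cells[cells])
    }, TRUE)
    starts <- starts[keep]
  }
  if (length(starts) < 1) return(list(coherence = NA_real_, p_coherence = NA_real_,
                                      mi = NA_real_, p_mi = NA_real_, n_windows = 0))
  env_w <- slice_segments(env, rate, starts, window_seconds)
  resp_w <- slice_segments(resp, rate, starts, window_seconds)
  coh_f <- function(e, r)
    mean(mscoherence(e, r, rate, sub_seconds = 20, freqs = coh_freqs)$coherence)
  mi_f <- function(e, r) modulation_index(e, r)
  if (length(starts) < 2) {
    return(list(coherence = coh_f(env_w[[1]], resp_w[[1]]), p_coherence = NA_real_,
                mi = mi_f(env_w[[1]], resp_w[[1]]), p_mi = NA_real_, n_windows = 1))
  }
  sc <- surrogate_p(coh_f, env_w, resp_w, n_surrogates, seed)
  sm <- surrogate_p(mi_f, env_w, resp_w, n_surrogates, seed + 1L)
  list(coherence = sc$observed, p_coherence = sc$p,
       mi = sm$observed, p_mi = sm$p, n_windows = length(starts))
}
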