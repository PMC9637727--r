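#' Least-squares linear-phase FIR design (type I)
#'
#' Designs an even-order, symmetric FIR filter minimizing the integrated
#' squared error between its amplitude response and a piecewise-linear
#' desired response, the classical least-squares design used for two-way
#' (zero-phase) EEG band filtering. Frequencies are normalized so that 1
#' is the Nyquist frequency.
#'
#' The symmetric impulse response is parameterized through
#' `A(f) = sum_k c_k cos(pi k f)`; setting the gradient of the integrated
#' squared error to zero gives a linear system `Q c = b` whose entries are
#' analytic cosine integrals over the specified bands.
#'
#' @param order filter order (number of taps minus one); rounded up to even.
#' @param freq vector of band-edge frequencies in `[0, 1]`, non-decreasing,
#'   of even length (pairs of band edges).
#' @param amp desired amplitude at each band edge (same length as `freq`);
#'   the desired response is linear between the two edges of each band and
#'   unconstrained in transition regions.
#' @return Numeric vector of `order + 1` filter taps.
#' @export
firls_design <- function(order, freq, amp) {
  if (length(freq) != length(amp) || length(freq) %% 2 != 0)
    stop("`freq` and `amp` must have equal, even length")
  if (any(diff(freq) < 0) || any(freq < 0) || any(freq > 1))
    stop("`freq` must be non-decreasing within [0, 1]")
  order <- as.integer(order)
  if (order %% 2 == 1) order <- order + 1L
  M <- order %/% 2

  # vectorized integral of cos(pi*n*f) over [a, b] for n = 0..nmax
  cosint_vec <- function(nmax, a, b) {
    n <- 0:nmax
    out <- (sin(pi * n * b) - sin(pi * n * a)) / (pi * n)
    out[1] <- b - a
    out
  }
  # vectorized integral of f * cos(pi*n*f) over [a, b]
  fcosint_vec <- function(nmax, a, b) {
    n <- 0:nmax
    pn <- pi * n
    out <- (b * sin(pn * b) - a * sin(pn * a)) / pn +
      (cos(pn * b) - cos(pn * a)) / pn^2
    out[1] <- (b^2 - a^2) / 2
    out
  }

  nb <- length(freq) %/% 2
  Ivec <- numeric(2 * M + 1)           # I[n+1] = sum over bands
  b <- numeric(M + 1)
  for (i in seq_len(nb)) {
    fl <- freq[2 * i - 1]; fr <- freq[2 * i]
    if (fr <= fl) next
    a0 <- amp[2 * i - 1]; a1 <- amp[2 * i]
    slope <- (a1 - a0) / (fr - fl)
    ci <- cosint_vec(2 * M, fl, fr)
    Ivec <- Ivec + ci
    b <- b + (a0 - slope * fl) * ci[1:(M + 1)] +
      slope * fcosint_vec(M, fl, fr)
  }
  # Q[k,m] = (I(|k-m|) + I(k+m)) / 2: Toeplitz plus Hankel
  idx <- 0:M
  Q <- 0.5 * (matrix(Ivec[abs(outer(idx, idx, "-")) + 1], M + 1) +
                matrix(Ivec[outer(idx, idx, "+") + 1], M + 1))
  c_ <- tryCatch(solve(Q, b), error = function(e) {
    # ill-conditioned normal equations (long filters with unconstrained
    # transition regions): fall back to a truncated-SVD least-squares
    # solution, the same resolution scipy/MATLAB designs apply
    s <- svd(Q)
    keep <- s$d > max(s$d) * 1e-12
    s$v[, keep] %*% ((t(s$u[, keep]) %*% b) / s$d[keep])
  })
  h <- numeric(order + 1)
  h[M + 1] <- c_[1]
  if (M > 0) {
    h[M + 1 + 1:M] <- c_[-1] / 2
    h[M + 1 - 1:M] <- c_[-1] / 2
  }
  h
}

# memoized filter designs (keyed on order and normalized band edges)
.design_cache <- new.env(parent = emptyenv())

# zero-phase (forward-backward) FIR application via FFT: multiplying the
# spectrum by |H|^2 is exactly the two-pass filter; reflection padding of
# one filter length per side suppresses circular wrap-around.
zero_phase_fir <- function(x, h) {
  nh <- length(h)
  n <- length(x)
  if (n < 3 * nh)
    stop("signal too short for zero-phase filtering (need >= 3 x filter ",
         "length = ", 3 * nh, " samples); pad the signal or use a shorter filter")
  pad <- nh
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[n] - rev(x[(n - pad):(n - 1)]))
  np <- length(xp)
  H <- stats::fft(c(h, numeric(np - nh)))
  y <- Re(stats::fft(stats::fft(xp) * (Mod(H)^2), inverse = TRUE)) / np
  y[(pad + 1):(pad + n)]
}

#' Zero-phase band-pass filtering of a recording
#'
#' Filters every channel to the requested band with a least-squares FIR
#' design applied in both directions (zero phase, squared magnitude
#' response). Transition bands extend 15% of each edge frequency beyond
#' the pass-band.
#'
#' @param x a [recording()].
#' @param band a [band_definition()]; must lie inside the Nyquist range.
#' @param order FIR order. The default `9 * rate / low_edge` taps (nine
#'   cycles of the lowest pass-band frequency) keeps the two-pass
#'   pass-band response flat to about one percent even for the narrow
#'   low-frequency bands, where a shorter design cannot realize the 15%
#'   transition bands.
#' @return A [recording()] of the band-limited signal.
#' @export
band_filter <- function(x, band, order = NULL) {
  stopifnot(inherits(x, "recording"), inherits(band, "band_definition"))
  ny <- x$rate / 2
  if (band$high_edge >= ny)
    stop(sprintf("band '%s' (%g-%g Hz) exceeds the Nyquist frequency %g Hz",
                 band$name, band$low_edge, band$high_edge, ny))
  if (is.null(order)) order <- round(9 * x$rate / band$low_edge)
  lo <- band$low_edge / ny
  hi <- band$high_edge / ny
  tl <- 0.15 * lo
  th <- min(0.15 * hi, (1 - hi) / 2)
  key <- paste(order, signif(c(lo, hi, tl, th), 12), collapse = "|")
  h <- .design_cache[[key]]
  if (is.null(h)) {
    h <- firls_design(order, c(0, lo - tl, lo, hi, hi + th, 1),
                      c(0, 0, 1, 1, 0, 0))
    .design_cache[[key]] <- h
  }
  y <- apply(x$samples, 2, zero_phase_fir, h = h)
  recording(y, rate = x$rate, labels = x$labels,
            start_offset = x$start_offset)
}

# analytic signal via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous amplitude (Hilbert envelope)
#'
#' Modulus of the analytic signal of each channel. The input should
#' already be band-limited; for `A * sin(2*pi*f*t)` the envelope is `A`
#' away from the recording edges.
#'
#' @param x a [recording()], typically output of [band_filter()].
#' @return A [recording()] holding the non-negative envelope.
#' @export
hilbert_envelope <- function(x) {
  stopifnot(inherits(x, "recording"))
  y <- apply(x$samples, 2, function(v) Mod(analytic_signal(v)))
  recording(y, rate = x$rate, labels = x$labels,
            start_offset = x$start_offset)
}

#' Instantaneous phase of the analytic signal
#'
#' Phase angle in radians in `(-pi, pi]`; phase 0 corresponds to the
#' positive peak of the real part by the analytic-signal convention.
#'
#' @param x numeric vector (demeaned, band-limited).
#' @return Numeric vector of phases.
#' @export
instantaneous_phase <- function(x) {
  Arg(analytic_signal(x))
}

#' Multi-unit activity from a high-rate intracortical recording
#'
#' Rectifies the raw signal and low-pass filters it at 20 Hz (zero-phase
#' FIR), yielding a non-negative firing-rate proxy.
#'
#' @param raw a [recording()] of the high-frequency (300-5000 Hz) stream.
#' @param cutoff low-pass cutoff in Hz (default 20).
#' @return A [recording()] of the firing proxy at the input rate.
#' @export
compute_mua <- function(raw, cutoff = 20) {
  stopifnot(inherits(raw, "recording"))
  if (raw$rate < 2 * cutoff)
    stop(sprintf("rate %g Hz cannot represent %g Hz content (need >= %g Hz)",
                 raw$rate, cutoff, 2 * cutoff))
  ny <- raw$rate / 2
  # window-method low-pass (monotone response), renormalized to an
  # exactly unit DC gain so constants pass through unchanged
  order <- 2 * max(round(1.65 * raw$rate / cutoff), 5)
  h <- as.numeric(signal::fir1(order, cutoff / ny, type = "low"))
  h <- h / sum(h)
  y <- apply(abs(raw$samples), 2, zero_phase_fir, h = h)
  recording(y, rate = raw$rate, labels = raw$labels,
            start_offset = raw$start_offset)
}

#' Band-matched smoothing of a firing-rate proxy
#'
#' Centered moving average over a window of `1/high_edge` seconds (the
#' period of the band's upper limit), removing firing fluctuations faster
#' than the fastest possible envelope oscillation of that band. Edges use
#' shrinking windows.
#'
#' @param m a [recording()] of the firing proxy (see [compute_mua()]).
#' @param band a [band_definition()].
#' @return A [recording()] of the smoothed proxy.
#' @export
smooth_mua_for_band <- function(m, band) {
  stopifnot(inherits(m, "recording"), inherits(band, "band_definition"))
  w <- round(m$rate / band$high_edge)
  if (w < 2)
    stop(sprintf("smoothing window 1/%g s spans < 2 samples at %g Hz",
                 band$high_edge, m$rate))
  y <- apply(m$samples, 2, moving_average, w = w)
  recording(y, rate = m$rate, labels = m$labels, start_offset = m$start_offset)
}

# centered moving average with shrinking edge windows
moving_average <- function(x, w) {
  n <- length(x)
  half_l <- (w - 1) %/% 2
  half_r <- w %/% 2
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Resample a recording to a target rate
#'
#' Polyphase resampling (via [signal::resample()]) of every channel.
#'
#' @param x a [recording()].
#' @param target_rate new sampling rate in Hz.
#' @return A [recording()] at `target_rate`.
#' @export
resample_recording <- function(x, target_rate) {
  stopifnot(inherits(x, "recording"))
  if (target_rate == x$rate) return(x)
  fr <- as.integer(round(target_rate * 1000))
  to <- as.integer(round(x$rate * 1000))
  g <- gcd_int(fr, to)
  p <- fr %/% g; q <- to %/% g
  y <- apply(x$samples, 2, function(v) signal::resample(v, p = p, q = q))
  recording(y, rate = target_rate, labels = x$labels,
            start_offset = x$start_offset)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)
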