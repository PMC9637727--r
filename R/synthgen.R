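#' Seeded 1/f^a ("pink") noise
#'
#' Generates Gaussian noise with a power spectrum proportional to
#' `1/f^exponent`, by frequency-domain shaping of seeded white Gaussian
#' noise (each rFFT coefficient scaled by `f^(-exponent/2)`, DC removed),
#' normalized to unit standard deviation before scaling by `amplitude`.
#'
#' @param n number of samples.
#' @param rate sampling rate in Hz.
#' @param exponent spectral slope (1 = pink).
#' @param amplitude output standard deviation.
#' @param seed integer seed; same seed gives bit-identical output.
#' @return Numeric vector of `n` samples.
#' @export
pink_noise <- function(n, rate, exponent = 1, amplitude = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- seq(0, n - 1) * rate / n
  f[f > rate / 2] <- rate - f[f > rate / 2]   # fold to physical frequency
  g <- numeric(n)
  g[f > 0] <- f[f > 0]^(-exponent / 2)
  x <- Re(stats::fft(W * g, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(x)
  amplitude * (x - mean(x)) / s
}

#' Specification for an amplitude-modulated test signal
#'
#' Describes a sum of amplitude-modulated sinusoids embedded in pink
#' noise. Each component is a sinusoid at `component_frequency` whose
#' amplitude is modulated at `carrier_frequency` (the slow rhythm that
#' envelope spectral analysis should recover) with the non-negative law
#' `1 - depth + depth * (1 + sin(2*pi*carrier*t)) / 2`.
#'
#' @param duration duration in seconds (> 0).
#' @param rate sampling rate in Hz; must exceed twice the fastest
#'   component frequency.
#' @param components list of components, each a list/vector with elements
#'   `component_frequency` (Hz), `carrier_frequency` (Hz),
#'   `modulation_depth` (0-1) and `amplitude`. The default is the
#'   two-component demonstration: a 2 Hz sinusoid modulated at 0.2 Hz and
#'   a 12 Hz sinusoid modulated at 1 Hz, both with depth 1 and unit
#'   amplitude.
#' @param noise_exponent spectral slope of the additive noise (1 = pink).
#' @param noise_amplitude standard deviation of the additive noise.
#'   The default 0.5 (half the component amplitude) leaves the carrier
#'   peaks clearly recoverable from the envelope spectra while keeping a
#'   visible noise floor.
#' @param seed integer seed.
#' @return Object of class `"sim_spec"`.
#' @export
sim_spec <- function(duration = 300, rate = 250,
                     components = list(
                       list(component_frequency = 2, carrier_frequency = 0.2,
                            modulation_depth = 1, amplitude = 1),
                       list(component_frequency = 12, carrier_frequency = 1,
                            modulation_depth = 1, amplitude = 1)),
                     noise_exponent = 1, noise_amplitude = 0.5, seed = 1L) {
  if (duration <= 0) stop("`duration` must be positive")
  for (cmp in components) {
    cmp <- as.list(cmp)
    if (rate <= 2 * cmp$component_frequency)
      stop(sprintf(paste0("rate %g Hz violates the Nyquist criterion for a ",
                          "%g Hz component (need rate > %g Hz)"),
                   rate, cmp$component_frequency, 2 * cmp$component_frequency))
    if (cmp$modulation_depth < 0 || cmp$modulation_depth > 1)
      stop("`modulation_depth` must lie in [0, 1]")
  }
  structure(list(duration = duration, rate = rate, components = components,
                 noise_exponent = noise_exponent,
                 noise_amplitude = noise_amplitude, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate the amplitude-modulated demonstration signal
#'
#' Builds the test signal used throughout to illustrate envelope spectral
#' analysis: the sum of the amplitude-modulated sinusoids in `spec` plus
#' seeded pink noise. With the default spec, the delta-band envelope
#' spectrum peaks at 0.2 Hz and the sigma-band envelope spectrum at 1 Hz,
#' while the ordinary signal spectrum peaks at 2 Hz and 12 Hz.
#'
#' @param spec a [sim_spec()].
#' @return A single-channel [recording()].
#' @examples
#' rec <- make_fig_signal(sim_spec(duration = 60, seed = 7))
#' @export
make_fig_signal <- function(spec = sim_spec()) {
  stopifnot(inherits(spec, "sim_spec"))
  n <- round(spec$duration * spec$rate)
  t <- (seq_len(n) - 1) / spec$rate
  x <- numeric(n)
  for (cmp in spec$components) {
    cmp <- as.list(cmp)
    m <- 1 - cmp$modulation_depth +
      cmp$modulation_depth * (1 + sin(2 * pi * cmp$carrier_frequency * t)) / 2
    x <- x + cmp$amplitude * m * sin(2 * pi * cmp$component_frequency * t)
  }
  if (spec$noise_amplitude > 0)
    x <- x + pink_noise(n, spec$rate, spec$noise_exponent,
                        spec$noise_amplitude, seed = spec$seed)
  recording(x, rate = spec$rate, labels = "sim")
}

#' Specification for an envelope-coupled cortical signal / firing pair
#'
#' @param band a [band_definition()] for the coupled band.
#' @param preferred_phase preferred firing phase in degrees, `[0, 360)`:
#'   the envelope phase (of its dominant oscillation) at which the firing
#'   proxy is maximal.
#' @param coupling_strength fraction 0-1; 0 gives independent signals.
#' @param lag delay of the firing proxy relative to the envelope in
#'   seconds, `|lag| <= 1`.
#' @param seed integer seed.
#' @return Object of class `"coupled_pair_spec"`.
#' @export
coupled_pair_spec <- function(band, preferred_phase = 0,
                              coupling_strength = 0.5, lag = 0, seed = 1L) {
  stopifnot(inherits(band, "band_definition"))
  if (preferred_phase < 0 || preferred_phase >= 360)
    stop("`preferred_phase` must lie in [0, 360)")
  if (coupling_strength < 0 || coupling_strength > 1)
    stop("`coupling_strength` must lie in [0, 1]")
  if (abs(lag) > 1) stop("`lag` must satisfy |lag| <= 1 s")
  structure(list(band = band, preferred_phase = preferred_phase,
                 coupling_strength = coupling_strength, lag = lag,
                 seed = as.integer(seed)),
            class = "coupled_pair_spec")
}

#' Generate an envelope-coupled cortical signal and firing-proxy pair
#'
#' The cortical-like signal is band-limited noise (in `spec$band`) whose
#' envelope fluctuates slowly. The firing proxy is a rectified-Gaussian
#' process whose gain is locked to the phase of the slow envelope
#' oscillation: gain is maximal when the envelope phase equals
#' `preferred_phase`, with overall modulation depth `coupling_strength`,
#' and the proxy is delayed by `lag` seconds. Strength 0 yields
#' independent signals.
#'
#' @param spec a [coupled_pair_spec()].
#' @param duration duration in seconds.
#' @param rate sampling rate in Hz (both outputs).
#' @return List with elements `ecog` and `mua`, both single-channel
#'   [recording()]s.
#' @export
make_coupled_pair <- function(spec, duration = 600, rate = 200) {
  stopifnot(inherits(spec, "coupled_pair_spec"))
  set.seed(spec$seed)
  n <- round(duration * rate)
  # band-limited cortical signal: filtered white noise
  white <- stats::rnorm(n)
  sig <- recording(white, rate = rate, labels = "ecog")
  sig <- band_filter(sig, spec$band)
  env <- hilbert_envelope(sig)$samples[, 1]
  # phase of the envelope's slow fluctuation
  phi <- instantaneous_phase(env - mean(env))
  # firing gain locked to envelope phase: max at preferred_phase
  pref <- spec$preferred_phase * pi / 180
  gain <- 1 + spec$coupling_strength * cos(phi - pref)
  lag_samp <- round(spec$lag * rate)
  if (lag_samp != 0) {
    if (lag_samp > 0) gain <- c(rep(gain[1], lag_samp), gain[1:(n - lag_samp)])
    else gain <- c(gain[(1 - lag_samp):n], rep(gain[n], -lag_samp))
  }
  mua <- gain * abs(stats::rnorm(n))
  mua <- moving_average(mua, max(2L, round(rate / 20)))
  list(ecog = recording(sig$samples[, 1], rate = rate, labels = "ecog"),
       mua = recording(mua, rate = rate, labels = "mua"))
}

#' Specification for a synthetic cohort of envelope spectra
#'
#' The effect map is the recovery ground truth: each entry injects a
#' feature at one (band, envelope-frequency range) locus whose expected
#' across-subject correlation with the named phenotype equals `effect`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range numeric length-2, age range in years.
#' @param effects list of effect entries, each a list with `band` (name),
#'   `freq_lo`, `freq_hi` (Hz, on the 0.01 Hz grid), `phenotype`
#'   (`"age"`, `"sex"` or `"iq"`) and `effect` (standardized correlation,
#'   `|effect| < 1`).
#' @param noise_sd standard deviation of the i.i.d. feature noise.
#' @param bands band names (default the canonical eight).
#' @param n_freq number of 0.01 Hz envelope-frequency bins (default 200,
#'   i.e. 0.01-2 Hz).
#' @param seed integer seed.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 176, age_range = c(17, 69),
                        effects = list(), noise_sd = 1,
                        bands = names(canonical_bands()),
                        n_freq = 200, seed = 1L) {
  if (n_subjects < 2) stop("`n_subjects` must be >= 2")
  for (e in effects) {
    if (!e$phenotype %in% c("age", "sex", "iq"))
      stop("effect phenotype must be one of 'age', 'sex', 'iq'")
    if (abs(e$effect) >= 1) stop("|effect| must be < 1")
    if (!e$band %in% bands) stop("effect band '", e$band, "' not in band set")
  }
  structure(list(n_subjects = as.integer(n_subjects), age_range = age_range,
                 effects = effects, noise_sd = noise_sd, bands = bands,
                 n_freq = as.integer(n_freq), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of envelope spectra with phenotype effects
#'
#' Draws per-subject phenotypes (age uniform over `age_range`, sex
#' Bernoulli(0.5) coded 0/1, IQ normal with mean 100 and SD 15) and
#' per-subject envelope spectra on the standard 0.01 Hz grid. Each
#' feature is `noise_sd`-scaled standard normal noise; at every declared
#' effect locus the feature is constructed as
#' `effect * z(phenotype) + sqrt(1 - effect^2) * noise`, so its expected
#' correlation with the phenotype equals the declared effect.
#'
#' @param spec a [cohort_spec()].
#' @return List with `spectra` (array subjects x bands x frequencies,
#'   dimnames set; frequencies `0.01 * (1:n_freq)` Hz) and `phenotypes`
#'   (data.frame with `id`, `age`, `sex`, `iq`).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_subjects
  phen <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    age = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    sex = stats::rbinom(n, 1, 0.5),
    iq = stats::rnorm(n, 100, 15))
  nb <- length(spec$bands)
  nf <- spec$n_freq
  freqs <- 0.01 * seq_len(nf)
  arr <- array(stats::rnorm(n * nb * nf), dim = c(n, nb, nf),
               dimnames = list(phen$id, spec$bands,
                               sprintf("%.2f", freqs)))
  for (e in spec$effects) {
    z <- scale(phen[[e$phenotype]])[, 1]
    if (all(!is.finite(z))) stop("constant phenotype in effect injection")
    bi <- match(e$band, spec$bands)
    fi <- which(freqs >= e$freq_lo & freqs <= e$freq_hi)
    for (k in fi)
      arr[, bi, k] <- e$effect * z + sqrt(1 - e$effect^2) * arr[, bi, k]
  }
  arr <- arr * spec$noise_sd
  list(spectra = arr, phenotypes = phen)
}

#' Build an artifact mask and stage annotation for a synthetic recording
#'
#' Converts artifact intervals (seconds, half-open) to the 4-s cell mask
#' (a cell is artifactual if it overlaps any interval) and stage blocks
#' to the 20-s epoch annotation.
#'
#' @param duration recording duration in seconds (multiple of 20
#'   recommended).
#' @param artifact_intervals list of numeric length-2 vectors
#'   `c(start, end)` in seconds, half-open, within `[0, duration)`.
#' @param stage_blocks list of lists with `stage`, `start`, `end`
#'   (seconds; multiples of 20, non-overlapping). Uncovered epochs are
#'   labelled `"U"`.
#' @return List with `mask` (an [artifact_mask()]) and `stages`
#'   (a [stage_annotation()]).
#' @export
make_mask_and_stages <- function(duration, artifact_intervals = list(),
                                 stage_blocks = list()) {
  n_cells <- ceiling(duration / 4)
  n_epochs <- ceiling(duration / 20)
  cells <- rep(FALSE, n_cells)
  for (iv in artifact_intervals) {
    if (iv[1] < 0 || iv[1] >= duration || iv[2] <= iv[1])
      stop("artifact interval must satisfy 0 <= start < end, start < duration")
    first <- floor(iv[1] / 4) + 1
    last <- ceiling(iv[2] / 4)
    cells[first:min(last, n_cells)] <- TRUE
  }
  stages <- rep("U", n_epochs)
  covered <- rep(FALSE, n_epochs)
  for (bl in stage_blocks) {
    if (bl$start %% 20 != 0 || bl$end %% 20 != 0)
      stop("stage blocks must start and end on multiples of 20 s")
    idx <- (bl$start / 20 + 1):(bl$end / 20)
    if (any(covered[idx])) stop("overlapping stage blocks")
    covered[idx] <- TRUE
    stages[idx] <- bl$stage
  }
  list(mask = artifact_mask(cells), stages = stage_annotation(stages))
}
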