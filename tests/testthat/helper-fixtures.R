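# shared fixtures: small, generated in code

# clean single-state annotations for a given duration
clean_nrem <- function(duration) {
  make_mask_and_stages(duration, list(),
                       list(list(stage = "N2", start = 0, end = duration)))
}

# a pure tone recording
tone_recording <- function(freq, duration = 60, rate = 250, amp = 1) {
  t <- (seq_len(duration * rate) - 1) / rate
  recording(amp * sin(2 * pi * freq * t), rate = rate)
}

# brute-force Benjamini-Hochberg step-up adjusted p-values (independent
# oracle for fdr_bh)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# brute-force weighted-mean aggregation oracle over explicit loops
aggregate_oracle <- function(wpsds) {
  nf <- length(wpsds[[1]]$freq)
  out <- rep(NA_real_, nf)
  for (k in seq_len(nf)) {
    num <- 0; den <- 0
    for (p in wpsds) {
      if (p$valid[k]) {
        num <- num + p$weight * p$density[k]
        den <- den + p$weight
      }
    }
    if (den > 0) out[k] <- num / den
  }
  out
}

# synthetic per-window PSD structure for aggregation tests
fake_window_psd <- function(density, L) {
  k <- 1:400
  list(freq = k / 100, density = density, valid = k >= ceiling(100 / L - 1e-9),
       L = L, weight = L / 100)
}
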