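#' Intraclass correlation for two measurements (pooled-SD form)
#'
#' Pearson-type coefficient with both covariance and variance taken
#' about the common (grand) mean of the two measurement vectors and the
#' variances pooled:
#' `ICC = mean((a-m)*(b-m)) / ((mean((a-m)^2) + mean((b-m)^2)) / 2)`
#' with `m = mean(c(a, b))` and population (1/n) moments. Unlike the
#' ordinary Pearson correlation this is sensitive to a mean difference
#' between the two measurements, and it equals the one-way
#' sums-of-squares form `(SSB - SSW) / (SSB + SSW)`.
#'
#' @param a,b numeric vectors of paired measurements (e.g. spectral
#'   density at one frequency from the two halves, across subjects).
#' @return ICC in `[-1, 1]`.
#' @export
icc_pooled <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2) return(NA_real_)
  m <- mean(c(a, b))
  num <- mean((a - m) * (b - m))
  den <- (mean((a - m)^2) + mean((b - m)^2)) / 2
  if (den == 0) return(NA_real_)
  num / den
}

# thin windows to every `thin`-th (starting at the first), then split the
# thinned sequence by parity of its order
thin_and_split <- function(n_windows, thin = 5) {
  idx <- seq(1, n_windows, by = thin)
  list(a = idx[seq_along(idx) %% 2 == 1],
       b = idx[seq_along(idx) %% 2 == 0])
}

#' Per-subject half spectra from per-window envelope spectra
#'
#' Builds the two half-measurements underlying reliability estimation
#' from one subject's per-window spectra. For the even-odd scheme the
#' windows (ordered in time) are first thinned to every fifth -- with
#' 100-s windows on a 20-s grid this leaves windows whose samples never
#' overlap -- and the thinned sequence is split by parity. For the
#' split-half scheme the windows are split into their first and last
#' 50%. Each half is aggregated with the usual length weighting and
#' post-processed (smoothing, log10, z), so the halves live on the same
#' normalized scale as full spectra.
#'
#' @param wpsd matrix of per-window densities (windows x 400 bins), as
#'   stored by [envelope_spectrum()] with `keep_windows = TRUE`.
#' @param windows the window plan (rows matching `wpsd`); typically
#'   restricted to one pass direction so that window order is a time
#'   order.
#' @param scheme `"even_odd"` or `"split_half"`.
#' @param thin thinning step for the even-odd scheme (default 5).
#' @return List with `a` and `b`, each the z-scored analysis-grid
#'   spectrum of one half (or `NULL` if a half has no windows).
#' @export
half_spectra <- function(wpsd, windows, scheme = c("even_odd", "split_half"),
                         thin = 5) {
  scheme <- match.arg(scheme)
  ord <- order(windows$start)
  wpsd <- wpsd[ord, , drop = FALSE]
  windows <- windows[ord, , drop = FALSE]
  n <- nrow(windows)
  if (scheme == "even_odd") {
    sp <- thin_and_split(n, thin)
  } else {
    half <- floor(n / 2)
    sp <- list(a = seq_len(half), b = seq(n - half + 1, n))
  }
  mk <- function(idx) {
    if (length(idx) == 0) return(NULL)
    wp <- lapply(idx, function(i) {
      L <- windows$length[i]
      k <- 1:400
      list(freq = k / 100, density = wpsd[i, ],
           valid = k >= ceiling(100 / L - 1e-9), L = L, weight = L / 100)
    })
    postprocess_psd(aggregate_psd(wp))$z
  }
  list(a = mk(sp$a), b = mk(sp$b))
}

#' Across-subject reliability of spectral features
#'
#' Given the two half-measurements for every subject (rows) and feature
#' (columns; e.g. envelope frequencies for one band and channel),
#' computes the per-feature reliability coefficient: the pooled-SD
#' intraclass correlation ([icc_pooled()]) for the even-odd scheme, or
#' the ordinary Pearson correlation (unsquared, the conservative choice)
#' for the split-half scheme.
#'
#' @param A,B numeric matrices subjects x features (half 1 and half 2).
#' @param type `"even_odd"` (ICC) or `"split_half"` (Pearson).
#' @return Object of class `"reliability_result"`: `coefficients` (per
#'   feature), `type`, `mean`, `sd`.
#' @export
reliability_coefficients <- function(A, B, type = c("even_odd", "split_half")) {
  type <- match.arg(type)
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)))
  if (type == "split_half" && nrow(A) < 3)
    coefs <- rep(NA_real_, ncol(A))
  else
    coefs <- vapply(seq_len(ncol(A)), function(j) {
      if (type == "even_odd") icc_pooled(A[, j], B[, j])
      else {
        ok <- is.finite(A[, j]) & is.finite(B[, j])
        if (sum(ok) < 3 || stats::sd(A[ok, j]) == 0 || stats::sd(B[ok, j]) == 0)
          NA_real_
        else stats::cor(A[ok, j], B[ok, j])
      }
    }, 0)
  structure(list(coefficients = coefs, type = type,
                 mean = mean(coefs, na.rm = TRUE),
                 sd = stats::sd(coefs[is.finite(coefs)])),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability_result> %s: mean %.3f (SD %.3f) over %d feature(s)\n",
              x$type, x$mean, x$sd, length(x$coefficients)))
  invisible(x)
}

#' Even-odd reliability across subjects
#'
#' Convenience wrapper: [reliability_coefficients()] with the intraclass
#' (pooled-SD) coefficient.
#' @inheritParams reliability_coefficients
#' @return A `"reliability_result"`.
#' @export
even_odd_reliability <- function(A, B)
  reliability_coefficients(A, B, "even_odd")

#' Split-half reliability across subjects
#'
#' Convenience wrapper: [reliability_coefficients()] with the ordinary
#' Pearson correlation (requires >= 3 subjects).
#' @inheritParams reliability_coefficients
#' @return A `"reliability_result"`.
#' @export
split_half_reliability <- function(A, B)
  reliability_coefficients(A, B, "split_half")

#' Across-subject correlation between envelope and signal spectra
#'
#' Pearson correlation, across subjects, of every (envelope frequency,
#' signal frequency) feature pair: rows are envelope-spectrum features
#' (typically 0.01-1 Hz, 100 bins), columns signal-spectrum features
#' (typically 0-48 Hz, 193 bins).
#'
#' @param env_features matrix subjects x envelope features.
#' @param sig_features matrix subjects x signal features.
#' @return Correlation matrix (envelope features x signal features;
#'   `NA` where a feature has zero variance).
#' @export
cross_measure_correlation <- function(env_features, sig_features) {
  env_features <- as.matrix(env_features)
  sig_features <- as.matrix(sig_features)
  stopifnot(nrow(env_features) == nrow(sig_features))
  if (nrow(env_features) < 3) stop("need at least 3 subjects")
  sde <- apply(env_features, 2, stats::sd)
  sds <- apply(sig_features, 2, stats::sd)
  out <- suppressWarnings(stats::cor(env_features, sig_features))
  out[sde == 0, ] <- NA_real_
  out[, sds == 0] <- NA_real_
  out
}

#' Univariate phenotype correlations with FDR control
#'
#' Pearson correlation of every spectral feature with one phenotype,
#' with pairwise deletion of missing phenotype values and
#' Benjamini-Hochberg adjustment within the supplied family (callers
#' group features by channel).
#'
#' @param features matrix subjects x features.
#' @param phenotype numeric vector (may contain `NA`).
#' @param q FDR level (default 0.05).
#' @return Data frame with `feature`, `r`, `p`, `p_adj`, `reject`.
#' @export
phenotype_correlations <- function(features, phenotype, q = 0.05) {
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(phenotype))
  if (sum(is.finite(phenotype)) < 4) stop("need >= 4 subjects with phenotype")
  if (stats::sd(phenotype, na.rm = TRUE) == 0) stop("constant phenotype")
  res <- lapply(seq_len(ncol(features)), function(j) {
    ok <- is.finite(features[, j]) & is.finite(phenotype)
    if (sum(ok) < 4 || stats::sd(features[ok, j]) == 0)
      return(c(NA_real_, NA_real_))
    ct <- stats::cor.test(features[ok, j], phenotype[ok])
    c(unname(ct$estimate), ct$p.value)
  })
  res <- do.call(rbind, res)
  fdr <- fdr_bh(res[, 2], q)
  nm <- colnames(features)
  if (is.null(nm)) nm <- paste0("f", seq_len(ncol(features)))
  data.frame(feature = nm, r = res[, 1], p = res[, 2],
             p_adj = fdr$adjusted, reject = fdr$reject)
}
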