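#' Maximal-variance validation split
#'
#' Orders subjects by the phenotype (ascending, stable tie-break by
#' subject id) and retains every 8th, starting from the first, as the
#' validation sample; the remainder trains. For 176 subjects this yields
#' 22 validation and 154 training subjects, and the validation sample
#' spans the phenotype's range ("maximal variance").
#'
#' @param phenotype numeric vector.
#' @param ids optional subject identifiers for the tie-break (default
#'   positional order).
#' @param every take every `every`-th ordered subject (default 8).
#' @return List with `train` and `validation`, integer indices into the
#'   input order.
#' @export
split_validation <- function(phenotype, ids = NULL, every = 8) {
  n <- length(phenotype)
  if (n < every) stop("need at least ", every, " subjects")
  if (is.null(ids)) ids <- seq_len(n)
  if (stats::sd(phenotype) == 0)
    warning("constant phenotype: split determined by the id tie-break")
  ord <- order(phenotype, ids)
  val <- ord[seq(1, n, by = every)]
  list(train = sort(setdiff(seq_len(n), val)), validation = sort(val))
}

# seeded fold assignment stratified by phenotype quantile
stratified_folds <- function(y, k = 5, seed = 1L) {
  set.seed(seed)
  ord <- order(y, stats::runif(length(y)))
  fold <- integer(length(y))
  # random assignment within consecutive quantile blocks of size k
  blocks <- split(ord, ceiling(seq_along(ord) / k))
  for (b in blocks) fold[b] <- sample.int(k, length(b))
  fold
}

#' Elastic-net phenotype model from envelope spectral features
#'
#' Fits an elastic net (L1-L2 mixture `mixing`, default 0.5) predicting
#' a phenotype from envelope spectral features, with the penalty chosen
#' by minimum mean squared error under seeded k-fold cross-validation
#' (folds stratified by phenotype quantile) over a descending
#' 100-value penalty path, then refit on the full training set. Columns
#' are standardized with training-set statistics only; constant columns
#' receive zero weight. A fit that errors or yields non-finite
#' coefficients, or a constant response, is returned as non-converged
#' rather than raising.
#'
#' @param X numeric matrix, training rows x features.
#' @param y numeric response, no missing values.
#' @param folds number of cross-validation folds (default 5).
#' @param mixing elastic-net mixing parameter alpha in `[0, 1]`
#'   (default 0.5; 1 = lasso).
#' @param seed seed for fold assignment.
#' @param nlambda,lambda_min_ratio penalty path controls.
#' @return Object of class `"envelope_enet"`: `coefficients` (on the
#'   original feature scale), `intercept`, `lambda`, `converged`,
#'   `center`, `scale`, `mixing`.
#' @export
fit_elastic_net <- function(X, y, folds = 5, mixing = 0.5, seed = 1L,
                            nlambda = 100, lambda_min_ratio = 1e-4) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  bad <- list(coefficients = rep(0, ncol(X)), intercept = NA_real_,
              lambda = NA_real_, converged = FALSE,
              center = rep(0, ncol(X)), scale = rep(1, ncol(X)),
              mixing = mixing)
  class(bad) <- "envelope_enet"
  if (any(!is.finite(y)) || stats::sd(y) == 0) return(bad)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- tryCatch({
    foldid <- stratified_folds(y, folds, seed)
    cv <- glmnet::cv.glmnet(Xs, y, alpha = mixing, foldid = foldid,
                            nlambda = nlambda,
                            lambda.min.ratio = lambda_min_ratio,
                            standardize = FALSE)
    co <- as.numeric(stats::coef(cv, s = "lambda.min"))
    if (any(!is.finite(co))) stop("non-finite coefficients")
    list(co = co, lambda = cv$lambda.min)
  }, error = function(e) NULL)
  if (is.null(fit)) return(bad)
  beta_std <- fit$co[-1]
  beta <- beta_std / scl
  structure(list(coefficients = beta,
                 intercept = fit$co[1] - sum(beta * ctr),
                 lambda = fit$lambda, converged = TRUE,
                 center = ctr, scale = scl, mixing = mixing),
            class = "envelope_enet")
}

#' @export
predict.envelope_enet <- function(object, newx, ...) {
  if (!object$converged) stop("model did not converge; no predictions")
  as.numeric(as.matrix(newx) %*% object$coefficients + object$intercept)
}

#' @export
coef.envelope_enet <- function(object, ...) {
  c(`(Intercept)` = object$intercept, object$coefficients)
}

#' @export
print.envelope_enet <- function(x, ...) {
  if (!x$converged) {
    cat("<envelope_enet> non-converged fit\n")
  } else {
    cat(sprintf("<envelope_enet> alpha %.2f, lambda %.4g, %d/%d nonzero\n",
                x$mixing, x$lambda, sum(x$coefficients != 0),
                length(x$coefficients)))
  }
  invisible(x)
}

#' Predictive accuracy on held-out subjects
#'
#' Pearson correlation between model predictions and actual phenotype
#' values in the validation sample. For a non-converged model the
#' accuracy is recorded as 0 and marked for exclusion from cross-channel
#' averages; zero-variance predictions yield `NA`.
#'
#' @param model an `"envelope_enet"` fit.
#' @param X_val validation feature matrix.
#' @param y_val validation phenotype values.
#' @return List with `r` and `converged`.
#' @export
evaluate_prediction <- function(model, X_val, y_val) {
  if (!model$converged) return(list(r = 0, converged = FALSE))
  pred <- predict(model, X_val)
  if (stats::sd(pred) == 0 || stats::sd(y_val) == 0)
    return(list(r = NA_real_, converged = TRUE))
  list(r = stats::cor(pred, y_val), converged = TRUE)
}

#' Assemble the 800-column feature matrix from cohort spectra
#'
#' Concatenates the envelope spectral values between 0.01 and
#' `freq_max_hz` Hz (the first 100 bins by default) of every band into
#' one row per subject: 100 bins x 8 bands = 800 predictors.
#'
#' @param spectra array subjects x bands x frequencies (0.01 Hz grid),
#'   e.g. from [make_cohort()].
#' @param freq_max_hz upper envelope frequency (default 1).
#' @return Numeric matrix subjects x (bands * bins) with band/frequency
#'   metadata in `attr(, "meta")` and column names `band_freq`.
#' @export
feature_matrix <- function(spectra, freq_max_hz = 1) {
  stopifnot(length(dim(spectra)) == 3)
  nb <- dim(spectra)[2]
  freqs <- 0.01 * seq_len(dim(spectra)[3])
  fi <- which(freqs <= freq_max_hz + 1e-9)
  bands <- dimnames(spectra)[[2]]
  if (is.null(bands)) bands <- paste0("band", seq_len(nb))
  cols <- do.call(cbind, lapply(seq_len(nb), function(b) spectra[, b, fi]))
  meta <- data.frame(band = rep(bands, each = length(fi)),
                     freq = rep(freqs[fi], nb))
  colnames(cols) <- paste0(meta$band, "_", sprintf("%.2f", meta$freq))
  attr(cols, "meta") <- meta
  cols
}

#' End-to-end phenotype prediction for one channel
#'
#' The complete multivariate pipeline: build the 800-column feature
#' matrix, hold out every 8th subject by ordered phenotype, fit the
#' elastic net on the training subjects and report the validation
#' accuracy.
#'
#' @param spectra array subjects x bands x frequencies.
#' @param phenotype numeric vector, one value per subject.
#' @param ... passed to [fit_elastic_net()].
#' @return List with `fit`, `r`, `converged`, `split`.
#' @export
phenotype_prediction <- function(spectra, phenotype, ...) {
  X <- feature_matrix(spectra)
  sp <- split_validation(phenotype)
  fit <- fit_elastic_net(X[sp$train, , drop = FALSE], phenotype[sp$train], ...)
  ev <- evaluate_prediction(fit, X[sp$validation, , drop = FALSE],
                            phenotype[sp$validation])
  list(fit = fit, r = ev$r, converged = ev$converged, split = sp)
}
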