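#' Read a recording from a CSV signal matrix with JSON side-car
#'
#' The CSV holds one column per channel (header = channel labels); the
#' side-car JSON (same path with extension `.json`, or given explicitly)
#' carries at least `rate` and optionally `labels`, `start_offset` and
#' generator metadata. EDF input is not supported by this build; an
#' explicit error points to the CSV route.
#'
#' @param path path to the `.csv` file.
#' @param sidecar optional path to the JSON side-car.
#' @param target_rate optionally resample to this rate after reading.
#' @return A [recording()].
#' @export
read_recording <- function(path, sidecar = NULL, target_rate = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE))
    stop("EDF input is not supported by this build; export the signal as ",
         "CSV with a JSON side-car (see write_recording())")
  if (is.null(sidecar)) sidecar <- sub("\\.csv$", ".json", path)
  if (!file.exists(sidecar))
    stop("missing side-car JSON with the sampling rate: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$rate)) stop("side-car JSON lacks a `rate` field")
  if (length(meta$rate) != 1)
    stop("non-uniform rate declaration: `rate` must be a single number")
  dat <- utils::read.csv(path, check.names = FALSE)
  labels <- if (!is.null(meta$labels)) meta$labels else colnames(dat)
  if (length(labels) != ncol(dat))
    stop("channel count mismatch between CSV and side-car labels")
  rec <- recording(as.matrix(dat), rate = meta$rate, labels = labels,
                   start_offset = if (!is.null(meta$start_offset))
                     meta$start_offset else 0)
  if (!is.null(target_rate)) rec <- resample_recording(rec, target_rate)
  rec
}

#' Write a recording as CSV + JSON side-car
#'
#' @param rec a [recording()].
#' @param path output `.csv` path; the side-car is written next to it.
#' @param extra named list merged into the side-car JSON (e.g. seed,
#'   generator spec).
#' @return Invisibly, the two paths written.
#' @export
write_recording <- function(rec, path, extra = list()) {
  stopifnot(inherits(rec, "recording"))
  df <- as.data.frame(rec$samples)
  colnames(df) <- rec$labels
  utils::write.csv(df, path, row.names = FALSE)
  meta <- c(list(rate = rec$rate, labels = rec$labels,
                 start_offset = rec$start_offset), extra)
  sidecar <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}

#' Read stage and artifact annotations
#'
#' Stage CSV: columns `epoch_index` (0-based) and `stage` (20-s epochs).
#' Artifact CSV: columns `cell_index` (0-based) and `is_artifact`
#' (4-s cells). Both must tile `[0, duration)`; a stage grid that
#' mismatches the duration by an epoch or more, or an artifact cell
#' beyond the duration, is an error.
#'
#' @param stage_path path to the stage CSV.
#' @param artifact_path path to the artifact CSV.
#' @param duration recording duration in seconds.
#' @return List with `stages` (a [stage_annotation()]) and `mask` (an
#'   [artifact_mask()]).
#' @export
read_annotations <- function(stage_path, artifact_path, duration) {
  st <- utils::read.csv(stage_path)
  if (!all(c("epoch_index", "stage") %in% colnames(st)))
    stop("stage CSV must have columns epoch_index,stage")
  st <- st[order(st$epoch_index), ]
  n_epochs <- round(duration / 20)
  if (abs(nrow(st) * 20 - duration) >= 20)
    stop(sprintf("stage grid mismatch: %d epochs x 20 s != %g s duration",
                 nrow(st), duration))
  if (!identical(as.integer(st$epoch_index), seq_len(nrow(st)) - 1L))
    stop("stage epoch_index must be 0..n-1 without gaps")
  ar <- utils::read.csv(artifact_path)
  if (!all(c("cell_index", "is_artifact") %in% colnames(ar)))
    stop("artifact CSV must have columns cell_index,is_artifact")
  n_cells <- ceiling(duration / 4)
  if (any(ar$cell_index < 0 | ar$cell_index >= n_cells))
    stop("artifact cell index beyond recording duration")
  cells <- rep(FALSE, n_cells)
  cells[ar$cell_index + 1] <- as.logical(ar$is_artifact)
  list(stages = stage_annotation(st$stage), mask = artifact_mask(cells))
}

#' Write stage and artifact annotations as CSV
#'
#' @param stages a [stage_annotation()].
#' @param mask an [artifact_mask()].
#' @param stage_path,artifact_path output paths.
#' @return Invisibly, the paths written.
#' @export
write_annotations <- function(stages, mask, stage_path, artifact_path) {
  utils::write.csv(data.frame(epoch_index = seq_along(stages$stages) - 1L,
                              stage = stages$stages),
                   stage_path, row.names = FALSE)
  utils::write.csv(data.frame(cell_index = seq_along(mask$cells) - 1L,
                              is_artifact = mask$cells),
                   artifact_path, row.names = FALSE)
  invisible(c(stage_path, artifact_path))
}

#' Run configuration with the standard analysis defaults
#'
#' @param ... overrides of the defaults (window_seconds 100,
#'   step_seconds 20, min_seconds 20, state "NREM", n_surrogates 1000,
#'   seed 1).
#' @return Named list of class `"run_config"`.
#' @export
run_config <- function(...) {
  cfg <- list(window_seconds = 100, step_seconds = 20, min_seconds = 20,
              state = "NREM", n_surrogates = 1000, seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  num <- c("window_seconds", "step_seconds", "min_seconds", "n_surrogates",
           "seed")
  for (nm in num) if (cfg[[nm]] <= 0) stop("`", nm, "` must be positive")
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as JSON (lossless round-trip)
#' @param cfg a [run_config()].
#' @param path JSON path.
#' @return `write_config` the path, `read_config` a [run_config()].
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(run_config, jsonlite::fromJSON(path))
}

#' Write analysis results to tab-separated files
#'
#' `envelope_psd` objects become one TSV per processing stage (rows =
#' frequencies, columns = band x channel, deterministic order) plus a
#' JSON with window counts and state; `coupling_result` objects become
#' three TSVs (lags, coherence frequencies, phase bins) plus a JSON with
#' p-values. Numbers are written with 17 significant digits so that
#' read/write round-trips are exact to double precision.
#'
#' @param x an `"envelope_psd"` or `"coupling_result"`.
#' @param outdir output directory (created if needed).
#' @param prefix filename prefix (default from the class).
#' @return Invisibly, the files written.
#' @export
write_results <- function(x, outdir, prefix = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(v) formatC(v, digits = 17, format = "g")
  files <- character(0)
  if (inherits(x, "envelope_psd")) {
    if (is.null(prefix)) prefix <- "envelope_psd"
    combos <- expand.grid(channel = x$channels, band = x$bands,
                          stringsAsFactors = FALSE)[, 2:1]
    for (stage in c("raw", "z")) {
      arr <- if (stage == "raw") x$raw else x$z
      freqs <- if (stage == "raw") x$freq else x$analysis_freq
      df <- data.frame(frequency = fmt(freqs))
      for (i in seq_len(nrow(combos))) {
        bi <- match(combos$band[i], x$bands)
        ci <- match(combos$channel[i], x$channels)
        df[[paste(combos$band[i], combos$channel[i], sep = ".")]] <-
          fmt(arr[bi, ci, ])
      }
      f <- file.path(outdir, sprintf("%s_%s.tsv", prefix, stage))
      utils::write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    meta <- list(state = x$state, n_windows = nrow(x$windows),
                 bands = x$bands, channels = x$channels, stage = "raw+z")
    f <- file.path(outdir, sprintf("%s_meta.json", prefix))
    jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  } else if (inherits(x, "coupling_result")) {
    if (is.null(prefix)) prefix <- "coupling"
    tabs <- list(
      lags = data.frame(lag = fmt(x$lag), crosscorr = fmt(x$crosscorr)),
      coherence = data.frame(frequency = fmt(x$coh_freq),
                             coherence = fmt(x$coherence)),
      phase = data.frame(bin_deg = x$phase_bins,
                         mean_z_amplitude = fmt(x$phase_profile)))
    for (nm in names(tabs)) {
      f <- file.path(outdir, sprintf("%s_%s.tsv", prefix, nm))
      utils::write.table(tabs[[nm]], f, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      files <- c(files, f)
    }
    meta <- list(band = x$band, n_segments = x$n_segments,
                 p_crosscorr = x$p_crosscorr, p_coherence = x$p_coherence,
                 p_phase = x$p_phase)
    f <- file.path(outdir, sprintf("%s_meta.json", prefix))
    jsonlite::write_json(meta, f, auto_unbox = TRUE, digits = NA)
    files <- c(files, f)
  } else stop("no writer for class ", paste(class(x), collapse = "/"))
  invisible(files)
}
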