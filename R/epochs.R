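# Epoched EEG container and the plain-text fixture format (matrix + JSON
# sidecar), plus the averaged-ERP (evoked) container.

#' Epoched EEG for one subject and condition
#'
#' @param data numeric array trials x channels x samples, in microvolts.
#' @param sfreq sampling rate in Hz.
#' @param t0_index 1-based sample index of stimulus onset.
#' @param subject_id subject identifier.
#' @param group group factor level (e.g. "Nonmusician").
#' @param condition condition factor level (e.g. "R", "Tsub", "Tapp").
#' @param labels channel labels (length = dim(data)[2]).
#' @param kept_mask logical per-trial vector (after artifact rejection);
#'   defaults to all `TRUE`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, sfreq, t0_index, subject_id, group, condition,
                      labels, kept_mask = NULL) {
  data <- unclass(data)
  stopifnot(length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop_fmt("epoch data contains non-finite values")
  if (t0_index < 1L || t0_index > dim(data)[3])
    stop_fmt("t0_index %d outside 1..%d", t0_index, dim(data)[3])
  if (length(labels) != dim(data)[2])
    stop_fmt("%d labels for %d channels", length(labels), dim(data)[2])
  if (is.null(kept_mask)) kept_mask <- rep(TRUE, dim(data)[1])
  stopifnot(length(kept_mask) == dim(data)[1])
  structure(list(data = data, sfreq = sfreq, t0_index = as.integer(t0_index),
                 subject_id = subject_id, group = group, condition = condition,
                 labels = as.character(labels), kept_mask = kept_mask),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoch_set> %s/%s/%s: %d trials (%d kept) x %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$condition, d[1], sum(x$kept_mask),
              d[2], d[3], x$sfreq))
  invisible(x)
}

#' Sample times (ms) of an epoch_set or evoked
#' @param x an `epoch_set` or `evoked`.
#' @return numeric vector of times in ms relative to stimulus onset.
#' @export
times_of <- function(x) {
  n <- if (inherits(x, "epoch_set")) dim(x$data)[3] else ncol(x$data)
  epoch_times(n, x$sfreq, x$t0_index)
}

#' Averaged ERP (evoked response)
#'
#' @param data channels x samples mean waveform (microvolts).
#' @param sfreq sampling rate (Hz).
#' @param t0_index 1-based onset sample index.
#' @param n_epochs number of epochs averaged.
#' @param labels channel labels.
#' @param subject_id,group,condition metadata carried along.
#' @param baseline_window baseline window (ms) applied, or `NULL`.
#' @param average_referenced,baseline_corrected logical flags.
#' @return object of class `evoked`.
#' @export
evoked <- function(data, sfreq, t0_index, n_epochs, labels,
                   subject_id = NA, group = NA, condition = NA,
                   baseline_window = NULL,
                   average_referenced = FALSE, baseline_corrected = FALSE) {
  data <- as.matrix(data)
  rownames(data) <- labels
  structure(list(data = data, sfreq = sfreq, t0_index = as.integer(t0_index),
                 n_epochs = n_epochs, labels = as.character(labels),
                 subject_id = subject_id, group = group, condition = condition,
                 baseline_window = baseline_window,
                 average_referenced = average_referenced,
                 baseline_corrected = baseline_corrected),
            class = "evoked")
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %s/%s/%s: %d ch x %d samples @ %g Hz, n = %s\n",
              x$subject_id, x$group, x$condition, nrow(x$data), ncol(x$data),
              x$sfreq, x$n_epochs))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Fixture format: a whitespace-separated text matrix plus a JSON sidecar.
# Continuous form: matrix channels x samples, sidecar lists event samples.
# Epoched form:    matrix (trials*channels) x samples, sidecar has n_trials.

sidecar_path <- function(path) paste0(path, ".json")

#' Write an epoch_set in the fixture format
#'
#' The data matrix is written as plain text ((trials*channels) rows, trial
#' blocks stacked) at full double precision; metadata go to `<path>.json`.
#'
#' @param epochs an `epoch_set`.
#' @param path data-file path (sidecar is written at `<path>.json`).
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
  con <- file(path, "w")
  on.exit(close(con))
  write.table(format(flat, digits = 17, scientific = TRUE, trim = TRUE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  meta <- list(kind = "epoched", n_trials = d[1], n_channels = d[2],
               n_samples = d[3], sfreq = epochs$sfreq, t0_index = epochs$t0_index,
               subject_id = epochs$subject_id, group = epochs$group,
               condition = epochs$condition, labels = epochs$labels,
               kept_mask = epochs$kept_mask)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read epoched EEG from the fixture format
#'
#' Two sidecar kinds are accepted. `"epoched"` restores an [epoch_set()]
#' written by [write_epochs()]. `"continuous"` holds a channels x samples
#' recording plus event sample indices; epochs are cut in the window
#' `epoch_window` (ms, inclusive at both ends) around each event, and events
#' whose window extends past either end of the recording are dropped with a
#' warning.
#'
#' @param path data-file path (sidecar expected at `<path>.json`).
#' @param epoch_window epoch extent in ms around each event, used for
#'   continuous input.
#' @return an `epoch_set`.
#' @export
read_epochs <- function(path, epoch_window = c(-200, 750)) {
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  mat <- as.matrix(read.table(path, header = FALSE))
  dimnames(mat) <- NULL
  if (identical(meta$kind, "epoched")) {
    d <- c(meta$n_trials, meta$n_channels, meta$n_samples)
    if (nrow(mat) != d[1] * d[2] || ncol(mat) != d[3])
      stop_fmt("data matrix %dx%d does not match sidecar dims", nrow(mat), ncol(mat))
    data <- aperm(array(mat, dim = c(d[2], d[1], d[3])), c(2L, 1L, 3L))
    return(epoch_set(data, meta$sfreq, meta$t0_index, meta$subject_id,
                     meta$group, meta$condition, meta$labels,
                     kept_mask = as.logical(meta$kept_mask)))
  }
  if (!identical(meta$kind, "continuous"))
    stop_fmt("unknown fixture kind '%s'", meta$kind)
  if (nrow(mat) != meta$n_channels)
    stop_fmt("sfreq/shape mismatch: %d rows, sidecar says %d channels",
             nrow(mat), meta$n_channels)
  sfreq <- meta$sfreq
  pre <- round(epoch_window[1] * sfreq / 1000)   # samples, e.g. -200
  post <- round(epoch_window[2] * sfreq / 1000)  # e.g. +750, inclusive
  ev <- as.integer(meta$events)
  ok <- (ev + pre >= 1L) & (ev + post <= ncol(mat))
  if (any(!ok))
    warn_fmt("%d event(s) too close to the record edge; epochs dropped", sum(!ok))
  ev <- ev[ok]
  if (!length(ev)) stop_fmt("no events left after boundary check")
  n_s <- post - pre + 1L
  data <- array(NA_real_, dim = c(length(ev), nrow(mat), n_s))
  for (i in seq_along(ev))
    data[i, , ] <- mat[, (ev[i] + pre):(ev[i] + post)]
  epoch_set(data, sfreq, t0_index = 1L - pre,
            subject_id = meta$subject_id %||% NA,
            group = meta$group %||% NA, condition = meta$condition %||% NA,
            labels = meta$labels)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
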