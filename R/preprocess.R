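# ERP preprocessing chain: average reference -> band-pass -> downsample ->
# spherical-spline channel interpolation -> threshold artifact rejection ->
# averaging with pre-stimulus baseline correction.

#' Re-reference data to the common average
#'
#' @param data channels x samples matrix (microvolts).
#' @return matrix of the same shape with zero channel mean at every sample.
#' @export
average_reference <- function(data) {
  data <- as.matrix(data)
  if (nrow(data) < 2L) stop_fmt("average reference needs >= 2 channels")
  sweep(data, 2L, colMeans(data), "-")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a 2nd-order Butterworth band-pass (two poles per band edge, i.e.
#' an asymptotic roll-off of -12 dB/octave per pass direction) and applies it
#' forward and backward, so the net filter has zero phase and the squared
#' magnitude response of the single pass.
#'
#' @param data channels x samples matrix, or a numeric vector.
#' @param sfreq sampling rate (Hz).
#' @param low,high band edges (Hz); defaults 0.25 and 30.
#' @param order filter order per band edge (default 2).
#' @return filtered data, same shape.
#' @export
bandpass <- function(data, sfreq, low = 0.25, high = 30, order = 2) {
  if (!(low > 0 && low < high && high < sfreq / 2))
    stop_fmt("band (%g, %g) Hz outside (0, Nyquist = %g)", low, high, sfreq / 2)
  flt <- signal::butter(order, c(low, high) / (sfreq / 2), type = "pass")
  vec <- is.null(dim(data))
  x <- if (vec) matrix(data, nrow = 1) else as.matrix(data)
  out <- t(apply(x, 1L, function(ch) signal::filtfilt(flt, ch)))
  if (vec) drop(out) else out
}

#' Magnitude response of the single-pass band-pass design
#'
#' Utility for verifying the asymptotic roll-off of the designed filter:
#' returns |H(f)| of one (forward) pass at the requested frequencies.
#'
#' @inheritParams bandpass
#' @param freqs frequencies (Hz) at which to evaluate.
#' @return numeric vector of magnitudes.
#' @export
bandpass_response <- function(freqs, sfreq, low = 0.25, high = 30, order = 2) {
  flt <- signal::butter(order, c(low, high) / (sfreq / 2), type = "pass")
  w <- 2 * pi * freqs / sfreq
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(flt$b * zz^-(seq_along(flt$b) - 1)), complex(1))
  den <- vapply(z, function(zz) sum(flt$a * zz^-(seq_along(flt$a) - 1)), complex(1))
  Mod(num / den)
}

#' Downsample by integer decimation
#'
#' Keeps every (`sfreq_in / sfreq_out`)-th sample starting at the first
#' sample. Assumes the data were already low-passed below the new Nyquist
#' (the 30 Hz band-pass precedes decimation in the pipeline).
#'
#' @param data channels x samples matrix.
#' @param sfreq_in,sfreq_out input and output rates; the ratio must be an
#'   integer.
#' @param t0_index 1-based onset index at the input rate (optional).
#' @return list with `data` and, when `t0_index` given, the rescaled
#'   `t0_index`. The onset sample must lie on the decimation grid.
#' @export
downsample <- function(data, sfreq_in = 1000, sfreq_out = 250, t0_index = NULL) {
  fac <- sfreq_in / sfreq_out
  if (abs(fac - round(fac)) > 1e-9)
    stop_fmt("sfreq_in/sfreq_out = %g is not an integer", fac)
  fac <- as.integer(round(fac))
  data <- as.matrix(data)
  idx <- seq(1L, ncol(data), by = fac)
  out <- data[, idx, drop = FALSE]
  if (is.null(t0_index)) return(list(data = out, t0_index = NULL))
  if ((t0_index - 1L) %% fac != 0L)
    stop_fmt("t0_index %d not on the decimation grid (factor %d)", t0_index, fac)
  list(data = out, t0_index = as.integer((t0_index - 1L) / fac + 1L))
}

# ---------------------------------------------------------------------------
# Perrin spherical-spline interpolation.

# g(x) kernel: (1/4pi) * sum_{n=1}^{n_terms} (2n+1) / (n^m (n+1)^m) P_n(x),
# evaluated for a matrix of cosines by the Legendre recurrence.
spline_g <- function(cosang, m = 4, n_terms = 50) {
  x <- as.matrix(cosang)
  Pnm1 <- matrix(1, nrow(x), ncol(x))  # P_0
  Pn <- x                              # P_1
  out <- (3 / (1 * 2)^m) * Pn
  if (n_terms >= 2) for (n in 2:n_terms) {
    Pnp <- ((2 * n - 1) * x * Pn - (n - 1) * Pnm1) / n
    Pnm1 <- Pn; Pn <- Pnp
    out <- out + ((2 * n + 1) / (n * (n + 1))^m) * Pn
  }
  out / (4 * pi)
}

#' Interpolate bad channels with a 3D spherical spline
#'
#' Replaces the listed channels by the Perrin spherical-spline prediction
#' computed from the remaining channels on the montage's fitted sphere.
#'
#' @param data channels x samples matrix.
#' @param montage an `electrode_montage`, sphere-fitted (see [fit_sphere()]).
#' @param bad_labels character vector of channels to replace (may be empty).
#' @param m spline order (default 4).
#' @param n_terms Legendre series truncation (default 50).
#' @param ridge ridge added to the spline system diagonal (default 1e-5).
#' @return data with the bad channels replaced.
#' @export
interpolate_bad_channels <- function(data, montage, bad_labels,
                                     m = 4, n_terms = 50, ridge = 1e-5) {
  data <- as.matrix(data)
  if (!length(bad_labels)) return(data)
  stopifnot(inherits(montage, "electrode_montage"))
  if (is.null(montage$fitted_sphere)) stop_fmt("montage must be sphere-fitted first")
  lab <- montage$labels
  if (!all(bad_labels %in% lab))
    stop_fmt("unknown bad channel(s): %s",
             paste(setdiff(bad_labels, lab), collapse = ", "))
  bad <- lab %in% bad_labels
  if (sum(bad) > length(lab) / 2)
    stop_fmt("refusing to interpolate more than half of the channels (%d of %d)",
             sum(bad), length(lab))
  ctr <- montage$fitted_sphere$center
  U <- sweep(montage$positions, 2L, ctr, "-")
  U <- U / sqrt(rowSums(U^2))
  Ug <- U[!bad, , drop = FALSE]
  Ub <- U[bad, , drop = FALSE]
  G <- spline_g(tcrossprod(Ug), m = m, n_terms = n_terms)
  Gb <- spline_g(tcrossprod(Ub, Ug), m = m, n_terms = n_terms)
  ng <- nrow(Ug)
  # spline system with the constant term and sum-to-zero constraint
  A <- rbind(cbind(G + diag(ridge, ng), 1), c(rep(1, ng), 0))
  rhs <- rbind(data[!bad, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  pred <- cbind(Gb, 1) %*% sol
  out <- data
  out[bad, ] <- pred
  out
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' An epoch is rejected iff any channel sample exceeds the threshold in
#' absolute value (strict inequality: a sample exactly at the threshold is
#' kept).
#'
#' @param epochs an `epoch_set`.
#' @param threshold amplitude criterion in microvolts (default 100).
#' @return the `epoch_set` with its `kept_mask` updated.
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  mx <- apply(abs(epochs$data), 1L, max)
  epochs$kept_mask <- mx <= threshold
  epochs
}

#' Average kept epochs into an ERP with pre-stimulus baseline correction
#'
#' @param epochs an `epoch_set` (kept_mask honoured).
#' @param baseline baseline window in ms, half-open `[start, end)`; default
#'   `c(-200, 0)`, i.e. the pre-stimulus period.
#' @return an [evoked()] object.
#' @export
make_evoked <- function(epochs, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  keep <- which(epochs$kept_mask)
  if (!length(keep)) stop_fmt("no kept epochs to average")
  avg <- apply(epochs$data[keep, , , drop = FALSE], c(2L, 3L), mean)
  tms <- times_of(epochs)
  bidx <- window_index(tms, baseline)
  if (!length(bidx)) stop_fmt("baseline window contains no samples")
  avg <- avg - rowMeans(avg[, bidx, drop = FALSE])
  evoked(avg, epochs$sfreq, epochs$t0_index, n_epochs = length(keep),
         labels = epochs$labels, subject_id = epochs$subject_id,
         group = epochs$group, condition = epochs$condition,
         baseline_window = baseline, baseline_corrected = TRUE,
         average_referenced = FALSE)
}

#' Run the full preprocessing chain on one epoch_set
#'
#' Fixed stage order: average reference, band-pass, downsample, bad-channel
#' interpolation, artifact rejection, averaging with baseline correction.
#'
#' @param epochs an `epoch_set` (at the acquisition rate).
#' @param montage sphere-fitted montage (needed only when `bad_labels` given).
#' @param bad_labels channels to interpolate (default none).
#' @param band band edges in Hz.
#' @param order Butterworth order per edge.
#' @param sfreq_out analysis rate after decimation (Hz).
#' @param threshold artifact threshold (microvolts).
#' @param baseline baseline window (ms).
#' @return an [evoked()] object at `sfreq_out`.
#' @export
preprocess_epochs <- function(epochs, montage = NULL, bad_labels = character(),
                              band = c(0.25, 30), order = 2, sfreq_out = 250,
                              threshold = 100, baseline = c(-200, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  fac <- epochs$sfreq / sfreq_out
  new_ns <- length(seq(1L, d[3], by = as.integer(round(fac))))
  out <- array(NA_real_, c(d[1], d[2], new_ns))
  t0_new <- NA_integer_
  for (i in seq_len(d[1])) {
    x <- average_reference(epochs$data[i, , ])
    x <- bandpass(x, epochs$sfreq, band[1], band[2], order)
    ds <- downsample(x, epochs$sfreq, sfreq_out, t0_index = epochs$t0_index)
    x <- ds$data
    t0_new <- ds$t0_index
    if (length(bad_labels))
      x <- interpolate_bad_channels(x, montage, bad_labels)
    out[i, , ] <- x
  }
  ep <- epoch_set(out, sfreq_out, t0_new, epochs$subject_id, epochs$group,
                  epochs$condition, epochs$labels)
  ep <- reject_artifacts(ep, threshold)
  make_evoked(ep, baseline)
}
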