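# Small shared helpers: time-axis arithmetic and validation.

#' Convert a duration in milliseconds to a whole number of sampling frames
#'
#' The minimum-duration rule for waveform runs and microstate segments is
#' stated in milliseconds (28 ms) but enforced on the sampling grid; at
#' 250 Hz it corresponds to 7 frames.
#'
#' @param ms duration in milliseconds.
#' @param sfreq sampling rate in Hz.
#' @return integer number of frames, `round(ms * sfreq / 1000)`.
#' @examples
#' ms_to_frames(28, 250)  # 7
#' @export
ms_to_frames <- function(ms, sfreq) {
  stopifnot(is.finite(ms), ms >= 0, sfreq > 0)
  as.integer(round(ms * sfreq / 1000))
}

#' Sample times of an epoch
#'
#' @param n_samples number of samples.
#' @param sfreq sampling rate (Hz).
#' @param t0_index 1-based index of the sample at stimulus onset (t = 0).
#' @return numeric vector of times in ms.
#' @export
epoch_times <- function(n_samples, sfreq, t0_index) {
  (seq_len(n_samples) - t0_index) * 1000 / sfreq
}

# Indices of samples whose time falls in the half-open window [start, end) ms.
window_index <- function(times, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  which(times >= window[1] & times < window[2])
}

# Per-column (frame-wise) centering: subtract the channel mean of each column.
center_columns <- function(x) {
  sweep(x, 2L, colMeans(x), "-")
}

#' @rdname gfp
#' @param x channels x frames matrix.
#' @export
gfp_frames <- function(x) {
  x <- as.matrix(x)
  xc <- center_columns(x)
  sqrt(colMeans(xc^2))
}

# Spatial Pearson correlation between columns of a (channels x k) template
# matrix and columns of a (channels x T) data matrix; returns k x T.
spatial_correlation <- function(maps, data) {
  m <- center_columns(as.matrix(maps))
  d <- center_columns(as.matrix(data))
  m <- sweep(m, 2L, sqrt(colSums(m^2)), "/")
  nd <- sqrt(colSums(d^2))
  nd[nd == 0] <- Inf # zero-GFP frames correlate 0 with everything
  d <- sweep(d, 2L, nd, "/")
  crossprod(m, d)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)
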