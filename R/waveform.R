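# Pointwise between-group waveform statistics at selected electrodes:
# independent t-tests at every sample with Bonferroni correction and a
# minimum-run-length criterion.

#' Pointwise between-group t-test runs at one electrode
#'
#' Two-sided pooled-variance independent t-tests on amplitude at every
#' sample; a sample is significant iff `p < alpha / n_family`; maximal runs
#' of at least `min_frames` consecutive significant samples are reported.
#' Samples with zero pooled variance are marked non-significant with a
#' warning.
#'
#' @param evokeds_a,evokeds_b lists of per-subject [evoked()] objects for
#'   the two groups (same channels, rate and epoch).
#' @param electrode channel label to test.
#' @param alpha nominal level (default 0.05).
#' @param n_family Bonferroni family size (default 3, the pairwise group
#'   contrasts per electrode and condition).
#' @param min_ms minimum run duration in ms (default 28).
#' @param contrast,condition labels stored with each run.
#' @return data.frame of runs: electrode, contrast, condition, start_ms,
#'   end_ms (half-open on the sample grid), n_frames, mean_t.
#' @export
pointwise_runs <- function(evokeds_a, evokeds_b, electrode, alpha = 0.05,
                           n_family = 3, min_ms = 28,
                           contrast = "A vs B", condition = NA) {
  stopifnot(length(evokeds_a) >= 2L, length(evokeds_b) >= 2L)
  e1 <- evokeds_a[[1]]
  ch <- match(electrode, e1$labels)
  if (is.na(ch)) stop_fmt("electrode '%s' not in the montage", electrode)
  xa <- t(vapply(evokeds_a, function(e) e$data[ch, ], numeric(ncol(e1$data))))
  xb <- t(vapply(evokeds_b, function(e) e$data[ch, ], numeric(ncol(e1$data))))
  na <- nrow(xa); nb <- nrow(xb)
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- apply(xa, 2L, var); vb <- apply(xb, 2L, var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- ifelse(se > 0, (ma - mb) / se, 0)
  if (any(se == 0))
    warn_fmt("%d sample(s) with degenerate variance marked non-significant",
             sum(se == 0))
  df <- na + nb - 2
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  sig <- se > 0 & p < alpha / n_family
  sfreq <- e1$sfreq
  min_frames <- ms_to_frames(min_ms, sfreq)
  tms <- times_of(e1)
  rl <- rle(sig)
  ends <- cumsum(rl$lengths); starts <- ends - rl$lengths + 1L
  keep <- which(rl$values & rl$lengths >= min_frames)
  if (!length(keep))
    return(data.frame(electrode = character(), contrast = character(),
                      condition = character(), start_ms = numeric(),
                      end_ms = numeric(), n_frames = integer(),
                      mean_t = numeric()))
  do.call(rbind, lapply(keep, function(i) {
    idx <- starts[i]:ends[i]
    data.frame(electrode = electrode, contrast = contrast,
               condition = condition, start_ms = tms[starts[i]],
               end_ms = tms[ends[i]] + 1000 / sfreq,
               n_frames = length(idx), mean_t = mean(tstat[idx]),
               stringsAsFactors = FALSE)
  }))
}
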