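# Topographic microstate analysis: global field power, global map
# dissimilarity, modified k-means segmentation of grand-mean ERPs,
# cross-validation / Krzanowski-Lai model selection, back-fitting to
# individual ERPs and nonparametric duration statistics.

#' Global field power
#'
#' The reference-free spatial standard deviation of a scalp map: the root
#' mean square of the deviations from the instantaneous channel mean.
#'
#' @param map numeric channel vector (one scalp map, microvolts).
#' @return non-negative scalar (microvolts).
#' @export
gfp <- function(map) {
  map <- as.numeric(map)
  if (length(map) < 2L) stop_fmt("gfp needs >= 2 channels")
  sqrt(mean((map - mean(map))^2))
}

#' Global map dissimilarity
#'
#' Distance between two scalp maps after average-referencing and GFP
#' normalisation; satisfies `gmd^2 = 2 (1 - r)` with `r` the spatial Pearson
#' correlation, so `gmd` ranges from 0 (identical topographies) to 2
#' (polarity-reversed).
#'
#' @param u,v channel vectors with non-zero GFP.
#' @return scalar in `[0, 2]`.
#' @export
gmd <- function(u, v) {
  gu <- gfp(u); gv <- gfp(v)
  if (gu == 0 || gv == 0) stop_fmt("gmd undefined for a zero-GFP map")
  un <- (u - mean(u)) / gu
  vn <- (v - mean(v)) / gv
  sqrt(mean((un - vn)^2))
}

# Normalise a map to zero channel mean and unit GFP.
normalize_map <- function(map) {
  m <- map - mean(map)
  g <- sqrt(mean(m^2))
  if (g == 0) stop_fmt("cannot normalise a flat map")
  m / g
}

# ---------------------------------------------------------------------------
# Modified k-means over frames, on topographic (dis)similarity.

# One k-means restart on precomputed centered frames.
# Fc: centered frames (channels x T); Fn: unit-norm centered frames;
# gfp2: per-frame GFP^2. Frames are seeded k-means++-style: the first map is
# a GFP^2-weighted draw, subsequent maps are drawn with probability
# proportional to gfp2 * (1 - max r^2) against the maps picked so far.
kmeans_once <- function(Fc, Fn, gfp2, k, polarity, max_iter = 200) {
  C <- nrow(Fc); Tn <- ncol(Fc)
  picks <- integer(k)
  picks[1] <- sample.int(Tn, 1L, prob = gfp2)
  if (k > 1L) for (j in 2:k) {
    r2 <- crossprod(Fn[, picks[seq_len(j - 1L)], drop = FALSE], Fn)^2
    w <- gfp2 * pmax(1 - apply(r2, 2L, max), 0)
    if (sum(w) <= 0) w <- gfp2
    picks[j] <- sample.int(Tn, 1L, prob = w)
  }
  maps <- Fn[, picks, drop = FALSE]
  labels <- rep(0L, Tn)
  for (it in seq_len(max_iter)) {
    r <- crossprod(maps, Fn)                      # k x T correlations
    score <- if (polarity == "sensitive") r else abs(r)
    new_labels <- max.col(t(score), ties.method = "first")
    for (j in which(tabulate(new_labels, k) == 0L)) {
      # re-seed an empty cluster from the worst-fit frame
      fit <- score[cbind(new_labels, seq_len(Tn))]
      worst <- which.min(fit)
      new_labels[worst] <- j
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    if (polarity == "sensitive") {
      Z <- matrix(0, Tn, k)
      Z[cbind(seq_len(Tn), labels)] <- 1
      M <- Fc %*% Z                               # cluster sums of frames
      maps <- sweep(M, 2L, pmax(sqrt(colSums(M^2)), 1e-300), "/")
    } else {
      for (j in seq_len(k)) {
        fj <- Fc[, labels == j, drop = FALSE]
        sv <- svd(fj, nu = 1, nv = 0)
        maps[, j] <- sv$u[, 1]
      }
    }
  }
  r <- crossprod(maps, Fn)
  score <- if (polarity == "sensitive") r else abs(r)
  labels <- max.col(t(score), ties.method = "first")
  r_ass <- r[cbind(labels, seq_len(Tn))]
  gev <- sum(gfp2 * r_ass^2) / sum(gfp2)
  rss <- sum(C * gfp2 * (1 - r_ass^2))
  # rescale maps to unit GFP (channel mean is 0 already)
  maps <- sweep(maps, 2L, sqrt(colMeans(maps^2)), "/")
  list(maps = maps, labels = labels, gev = gev, rss = rss)
}

# Reject labelled segments shorter than min_frames within one sequence:
# each frame of a short segment is reassigned to whichever neighbouring
# segment's map correlates better with it; repeat until stable.
smooth_labels <- function(labels, frames, maps, min_frames, polarity) {
  if (min_frames <= 1L) return(labels)
  r <- spatial_correlation(maps, frames)
  if (polarity != "sensitive") r <- abs(r)
  for (pass in seq_len(50L)) {
    rl <- rle(labels)
    short <- which(rl$lengths < min_frames)
    if (!length(short)) break
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    # handle the shortest segment first
    s <- short[which.min(rl$lengths[short])]
    left <- if (s > 1L) rl$values[s - 1L] else NA_integer_
    right <- if (s < length(rl$values)) rl$values[s + 1L] else NA_integer_
    for (t in starts[s]:ends[s]) {
      cand <- stats::na.omit(c(left, right))
      if (!length(cand)) break
      labels[t] <- cand[which.max(r[cbind(cand, t)])]
    }
  }
  labels
}

#' Segment grand-mean ERPs into k microstate maps (modified k-means)
#'
#' Fits `k` template topographies to the concatenated grand-mean ERPs of all
#' design cells by a modified k-means: frames are assigned to the template
#' with the highest spatial correlation (signed when polarity-sensitive,
#' absolute otherwise) and templates are re-estimated as the normalised mean
#' (sensitive) or first principal direction (invariant) of their frames.
#' The best of `n_restarts` random starts by global explained variance is
#' kept, and labelled segments shorter than `min_frames` are rejected by
#' reassigning their frames to the better-correlated neighbouring template.
#'
#' @param grand_means named list of [evoked()] objects (one per design cell)
#'   sharing channels and sampling rate.
#' @param k number of template maps (>= 2).
#' @param n_restarts random restarts (default 100).
#' @param polarity `"sensitive"` (default, appropriate for ERP data whose
#'   components have fixed polarity) or `"invariant"`.
#' @param window analysis window in ms, half-open; default `c(0, 750)`.
#' @param min_frames minimum segment length in frames (default 7, i.e. 28 ms
#'   at 250 Hz).
#' @param seed integer seed for the restarts.
#' @return an object of class `microstate_model` with elements `maps`
#'   (channels x k, each average-referenced with unit GFP), `labels` (named
#'   list of per-cell integer frame label vectors), `gev`, `polarity`,
#'   `window`, `sfreq`, and `selection` (filled by [choose_k()]).
#' @export
microstate_segment <- function(grand_means, k, n_restarts = 100,
                               polarity = c("sensitive", "invariant"),
                               window = c(0, 750), min_frames = 7, seed = 1) {
  polarity <- match.arg(polarity)
  if (k < 2L) stop_fmt("k must be >= 2")
  stopifnot(is.list(grand_means), length(grand_means) >= 1L)
  sfreq <- grand_means[[1]]$sfreq
  labels_ch <- grand_means[[1]]$labels
  cell_frames <- lapply(grand_means, function(ev) {
    stopifnot(inherits(ev, "evoked"))
    if (ev$sfreq != sfreq || !identical(ev$labels, labels_ch))
      stop_fmt("all cells must share channels and sampling rate")
    idx <- window_index(times_of(ev), window)
    average_reference(ev$data[, idx, drop = FALSE])
  })
  nf <- vapply(cell_frames, ncol, integer(1))
  frames <- do.call(cbind, cell_frames)
  Fc <- center_columns(frames)
  nrm <- sqrt(colSums(Fc^2))
  Fn <- sweep(Fc, 2L, pmax(nrm, 1e-300), "/")
  gfp2 <- colMeans(Fc^2)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- kmeans_once(Fc, Fn, gfp2, k, polarity)
    if (is.null(best) || fit$gev > best$gev) best <- fit
  }
  # smooth within each cell's sequence separately
  off <- c(0L, cumsum(nf))
  labs <- best$labels
  for (i in seq_along(nf)) {
    idx <- (off[i] + 1L):off[i + 1L]
    labs[idx] <- smooth_labels(best$labels[idx], frames[, idx, drop = FALSE],
                               best$maps, min_frames, polarity)
  }
  labs[gfp2 == 0] <- 0L                      # zero-GFP frames stay unlabeled
  per_cell <- lapply(seq_along(nf), function(i) labs[(off[i] + 1L):off[i + 1L]])
  names(per_cell) <- names(grand_means)
  gev <- explained_variance_frames(best$maps, frames, labs, polarity)
  structure(list(maps = best$maps, k = k, labels = per_cell, gev = gev,
                 rss = best$rss, polarity = polarity, window = window,
                 sfreq = sfreq, channel_labels = labels_ch,
                 n_frames_total = sum(nf), selection = NULL),
            class = "microstate_model")
}

# GFP^2-weighted mean squared spatial correlation between each frame and its
# assigned map; unlabeled (0) frames contribute zero.
explained_variance_frames <- function(maps, frames, labels, polarity) {
  gfp2 <- colMeans(center_columns(frames)^2)
  lab <- labels > 0L
  if (!any(lab)) return(0)
  r <- spatial_correlation(maps, frames[, lab, drop = FALSE])
  r_ass <- r[cbind(labels[lab], seq_len(sum(lab)))]
  sum(gfp2[lab] * r_ass^2) / sum(gfp2)
}

#' Global explained variance of a label assignment
#'
#' @param model a `microstate_model`.
#' @param data channels x frames matrix.
#' @param labels integer frame labels (0 = unlabeled).
#' @return fraction in `[0, 1]`.
#' @export
explained_variance <- function(model, data, labels) {
  explained_variance_frames(model$maps, as.matrix(data), labels, model$polarity)
}

#' Select the number of microstate maps
#'
#' Fits segmentations over a consecutive range of `k` and scores each by
#' (i) the cross-validation criterion, the residual variance inflated by
#' `((C - 1) / (C - 1 - k))^2` with `C` the channel count, and (ii) a
#' modified Krzanowski-Lai criterion computed from the dispersion curve
#' `W(k)`: with `DIFF(k) = W(k-1)^(2/C) - W(k)^(2/C)`, `KL(k) =
#' DIFF(k)/DIFF(k+1)`, set to 0 at the endpoints of the range. The chosen
#' `k` maximises KL among candidates whose CV exceeds the CV minimum by at
#' most 5%.
#'
#' @inheritParams microstate_segment
#' @param k_range integer vector of consecutive k values (>= 4 values).
#' @param kl_exponent exponent applied to W in the KL statistic
#'   (default `2/C`).
#' @return list with `k_opt`, `criteria` (data.frame k/cv/kl/gev) and
#'   `models` (one `microstate_model` per k).
#' @export
choose_k <- function(grand_means, k_range = 2:12, n_restarts = 50,
                     polarity = "sensitive", window = c(0, 750),
                     min_frames = 7, seed = 1, kl_exponent = NULL) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 4L || !all(diff(k_range) == 1L))
    stop_fmt("k_range must contain >= 4 consecutive values")
  models <- lapply(k_range, function(k)
    microstate_segment(grand_means, k, n_restarts = n_restarts,
                       polarity = polarity, window = window,
                       min_frames = min_frames, seed = seed + k))
  C <- length(models[[1]]$channel_labels)
  Tn <- models[[1]]$n_frames_total
  W <- vapply(models, function(m) m$rss, numeric(1))
  sigma2 <- W / (Tn * (C - 1))
  cv <- sigma2 * ((C - 1) / (C - 1 - k_range))^2
  e <- if (is.null(kl_exponent)) 2 / C else kl_exponent
  We <- W^e
  nk <- length(k_range)
  diffk <- c(NA, We[-nk] - We[-1])          # DIFF(k) = W(k-1)^e - W(k)^e
  kl <- rep(0, nk)
  if (nk >= 3) for (i in 2:(nk - 1)) kl[i] <- diffk[i] / diffk[i + 1]
  kl[!is.finite(kl) | kl < 0] <- 0          # endpoint / non-monotone convention
  # CV must not exceed its minimum by more than 5% (with a numerical floor
  # for the saturated, perfect-fit regime where CV is ~0 for every k)
  ok <- cv <= 1.05 * min(cv) + 1e-9 * max(cv)
  cand <- which(ok & kl == max(kl[ok]))
  k_opt <- k_range[cand[1]]
  criteria <- data.frame(k = k_range, cv = cv, kl = kl,
                         gev = vapply(models, function(m) m$gev, numeric(1)))
  best <- models[[cand[1]]]
  best$selection <- criteria
  list(k_opt = k_opt, criteria = criteria, model = best, models = models)
}

# ---------------------------------------------------------------------------
# Model methods

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d (%s polarity), %d channels, GEV = %.2f%%\n",
              x$k, x$polarity, nrow(x$maps), 100 * x$gev))
  invisible(x)
}

#' @export
summary.microstate_model <- function(object, ...) {
  cat(sprintf("Microstate model: k = %d templates, %s polarity\n",
              object$k, object$polarity))
  cat(sprintf("Channels: %d   analysis window: [%g, %g) ms @ %g Hz\n",
              nrow(object$maps), object$window[1], object$window[2], object$sfreq))
  cat(sprintf("Global explained variance: %.2f%%\n", 100 * object$gev))
  if (!is.null(object$selection)) {
    cat("Model selection criteria:\n")
    print(object$selection, row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.microstate_model <- function(object, ...) object$maps

#' Back-fit template maps to an ERP (predict method)
#'
#' @param object a `microstate_model`.
#' @param newdata an [evoked()] object.
#' @param window fitting window in ms, half-open (default `c(295, 480)`).
#' @param ... unused.
#' @return integer vector of frame labels in the window (0 = unlabeled),
#'   with the frame times as names.
#' @export
predict.microstate_model <- function(object, newdata, window = c(295, 480), ...) {
  microstate_backfit(object, newdata, window)
}

#' @export
plot.microstate_model <- function(x, ...) {
  matplot(t(x$maps), type = "l", lty = 1, xlab = "channel",
          ylab = "normalised amplitude",
          main = sprintf("%d microstate templates", x$k), ...)
  legend("topright", legend = paste("map", seq_len(x$k)), lty = 1,
         col = seq_len(x$k), cex = 0.7)
  invisible(x)
}

#' Back-fit microstate templates to an individual ERP
#'
#' Each frame in the window is assigned to the template with the highest
#' spatial correlation (signed or absolute per the model's polarity mode);
#' zero-GFP frames stay unlabeled. No smoothing is applied at back-fit.
#'
#' @inheritParams predict.microstate_model
#' @param evoked an [evoked()] object with the model's channels.
#' @return integer labels per frame in the window (0 = unlabeled).
#' @export
microstate_backfit <- function(object, evoked, window = c(295, 480)) {
  stopifnot(inherits(object, "microstate_model"), inherits(evoked, "evoked"))
  if (!identical(evoked$labels, object$channel_labels))
    stop_fmt("evoked channels do not match the model")
  tms <- times_of(evoked)
  idx <- window_index(tms, window)
  if (!length(idx)) stop_fmt("window [%g, %g) outside the epoch", window[1], window[2])
  frames <- average_reference(evoked$data[, idx, drop = FALSE])
  g <- gfp_frames(frames)
  labels <- rep(0L, length(idx))
  nz <- g > 0
  if (any(nz)) {
    r <- spatial_correlation(object$maps, frames[, nz, drop = FALSE])
    if (object$polarity != "sensitive") r <- abs(r)
    labels[nz] <- max.col(t(r), ties.method = "first")
  }
  names(labels) <- tms[idx]
  labels
}

#' Microstate durations within a window
#'
#' @param labels integer frame labels (0 = unlabeled) as returned by
#'   [microstate_backfit()].
#' @param k number of template maps.
#' @param sfreq sampling rate (Hz).
#' @return named numeric vector of durations in ms: one entry per map plus
#'   `"unlabeled"`; entries sum to `length(labels) * 1000 / sfreq`.
#' @export
state_durations <- function(labels, k, sfreq) {
  frame_ms <- 1000 / sfreq
  counts <- tabulate(labels[labels > 0L], nbins = k)
  out <- c(counts, sum(labels == 0L)) * frame_ms
  names(out) <- c(paste0("map", seq_len(k)), "unlabeled")
  out
}

#' Build a duration table for a set of subjects
#'
#' @param model a `microstate_model`.
#' @param evokeds list of per-subject [evoked()] objects (each carrying
#'   `subject_id`, `group`, `condition`).
#' @param window fitting window in ms (half-open).
#' @return data.frame: subject, group, condition, map, duration_ms.
#' @export
duration_table <- function(model, evokeds, window = c(295, 480)) {
  rows <- lapply(evokeds, function(ev) {
    lab <- microstate_backfit(model, ev, window)
    dur <- state_durations(lab, model$k, model$sfreq)
    data.frame(subject = ev$subject_id, group = ev$group,
               condition = ev$condition, map = names(dur),
               duration_ms = as.numeric(dur), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Nonparametric tests on microstate durations
#'
#' Per map and condition: a Kruskal-Wallis one-way ANOVA on ranks across
#' groups; when its p-value is below `alpha`, the three pairwise
#' Mann-Whitney U tests with a Bonferroni factor equal to the number of
#' pairs. The gatekeeping is recorded in the correction label.
#'
#' @param durations data.frame from [duration_table()].
#' @param alpha gate for the post-hoc tests (default 0.05).
#' @return a [stat_table()].
#' @export
duration_tests <- function(durations, alpha = 0.05) {
  maps <- setdiff(unique(durations$map), "unlabeled")
  conds <- unique(durations$condition)
  out <- list()
  for (mp in maps) for (cn in conds) {
    d <- durations[durations$map == mp & durations$condition == cn, ]
    groups <- unique(d$group)
    if (length(groups) < 2L) next
    if (all(d$duration_ms == d$duration_ms[1])) {
      kwH <- 0; kwp <- 1; kwdf <- length(groups) - 1
    } else {
      kw <- kruskal.test(duration_ms ~ factor(group), data = d)
      kwH <- unname(kw$statistic); kwp <- kw$p.value
      kwdf <- unname(kw$parameter)
    }
    out[[length(out) + 1L]] <- stat_table(
      label = sprintf("%s/%s KW", mp, cn), statistic = "H", value = kwH,
      df1 = kwdf, df2 = NA, p = kwp, effect_size = NA, correction = "none")
    if (is.finite(kwp) && kwp < alpha) {
      prs <- utils::combn(sort(groups), 2, simplify = FALSE)
      for (pr in prs) {
        xa <- d$duration_ms[d$group == pr[1]]
        xb <- d$duration_ms[d$group == pr[2]]
        wt <- suppressWarnings(wilcox.test(xa, xb))
        out[[length(out) + 1L]] <- stat_table(
          label = sprintf("%s/%s %s vs %s", mp, cn, pr[1], pr[2]),
          statistic = "U", value = unname(wt$statistic), df1 = length(xa),
          df2 = length(xb), p = min(1, wt$p.value * length(prs)),
          effect_size = NA,
          correction = sprintf("bonferroni x%d (gated on KW p<%g)",
                               length(prs), alpha))
      }
    }
  }
  if (!length(out)) return(stat_table())
  do.call(rbind_stat, out)
}
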