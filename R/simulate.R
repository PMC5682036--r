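# Synthetic study generator: multi-group, multi-condition epoched EEG with
# known microstate structure and known dipolar sources, plus YES/NO
# behavioural responses with known sensitivity.

#' Study design
#'
#' @param groups named integer vector: subjects per group (between factor).
#' @param conditions character vector of within-subject condition levels.
#' @return object of class `study_design`.
#' @export
study_design <- function(groups = c(Nonmusician = 19, Amateur = 20, Expert = 20),
                         conditions = c("R", "Tsub", "Tapp")) {
  if (length(groups) < 2L || length(conditions) < 2L)
    stop_fmt("need >= 2 levels per factor")
  structure(list(groups = groups, conditions = conditions),
            class = "study_design")
}

#' Default microstate timeline per design cell
#'
#' An ordered list of (template, onset ms, offset ms) segments for every
#' group x condition cell. Early templates (1-3) are shared by all cells;
#' inside the 295-480 ms analysis window the durations of templates 4-7
#' depend on the cell, emulating a design where a "naive" map dominates the
#' untrained group and two late centro-parietal maps dominate the experts,
#' with the contrast growing with transgression salience.
#'
#' @param design a [study_design()] (3 x 3 reference design).
#' @return named list (one per cell `group.condition`) of data.frames with
#'   columns template/onset/offset (ms).
#' @export
default_timeline <- function(design = study_design()) {
  stopifnot(length(design$groups) == 3L, length(design$conditions) == 3L)
  # durations of maps 4..7 inside [295, 480) per group, modulated by condition
  base <- list(
    c(104, 20, 40, 20),   # group 1: map4 dominates
    c(60, 44, 40, 40),    # group 2: intermediate
    c(20, 64, 40, 60))    # group 3: maps 5 and 7 dominate
  cond_shift <- c(R = 0, Tsub = 8, Tapp = 16)  # transgression sharpens the pattern
  cells <- list()
  for (g in seq_along(design$groups)) for (cn in design$conditions) {
    d <- base[[g]]
    sh <- cond_shift[[cn]]
    if (g == 1L) d <- d + c(sh, 0, 0, -sh)          # naive map grows
    if (g == 3L) d <- d + c(-sh, sh / 2, 0, sh / 2) # expert maps grow
    d <- round(d / 4) * 4                            # keep on the 250 Hz grid
    d[4] <- 184 - sum(d[1:3])                        # exact window budget
    on4 <- 295 + cumsum(c(0, d[-4]))
    seg <- rbind(
      data.frame(template = 1L, onset = 0, offset = 100),
      data.frame(template = 2L, onset = 100, offset = 200),
      data.frame(template = 3L, onset = 200, offset = 295),
      data.frame(template = 4:7, onset = on4, offset = on4 + d),
      data.frame(template = 2L, onset = 479, offset = 620),
      data.frame(template = 3L, onset = 620, offset = 750))
    seg <- seg[seg$offset > seg$onset, ]
    cells[[paste(names(design$groups)[g], cn, sep = ".")]] <- seg
  }
  cells
}

#' Simulation specification
#'
#' @param design a [study_design()].
#' @param k_templates number of template maps.
#' @param timeline per-cell segment list, see [default_timeline()].
#' @param cell_amplitudes named numeric vector (microvolts) per cell, or a
#'   single value.
#' @param noise_sd single-trial Gaussian channel noise SD (microvolts).
#' @param n_trials trials per cell.
#' @param sfreq analysis sampling rate (Hz).
#' @param subject_jitter_sd SD of the log-normal per-subject amplitude
#'   jitter (on the log scale; default 0.2).
#' @param seed integer seed.
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(design = study_design(), k_templates = 7,
                            timeline = default_timeline(design),
                            cell_amplitudes = 4, noise_sd = 8,
                            n_trials = 90, sfreq = 250,
                            subject_jitter_sd = 0.2, seed = 1) {
  stopifnot(noise_sd >= 0, n_trials >= 1)
  for (cell in names(timeline)) {
    seg <- timeline[[cell]]
    if (any(seg$onset < -200) || any(seg$offset > 750))
      stop_fmt("timeline of %s outside the epoch", cell)
    o <- order(seg$onset)
    if (any(seg$offset[o][-nrow(seg)] > seg$onset[o][-1] + 1e-9))
      stop_fmt("overlapping segments in %s", cell)
  }
  if (length(cell_amplitudes) == 1L)
    cell_amplitudes <- setNames(rep(cell_amplitudes, length(timeline)),
                                names(timeline))
  structure(list(design = design, k_templates = k_templates,
                 timeline = timeline, cell_amplitudes = cell_amplitudes,
                 noise_sd = noise_sd, n_trials = n_trials, sfreq = sfreq,
                 subject_jitter_sd = subject_jitter_sd, seed = seed),
            class = "simulation_spec")
}

#' Generate template scalp maps from random superficial dipole pairs
#'
#' Each template is the forward projection of a pair of random dipoles
#' placed at superficial grid nodes, average-referenced and scaled to unit
#' GFP. Pairs are redrawn until all pairwise absolute spatial correlations
#' are below 0.9.
#'
#' @param k number of templates (>= 2).
#' @param leadfield a [compute_leadfield()] result.
#' @param grid the matching [build_grid()] result.
#' @param seed integer seed.
#' @param max_tries redraw budget (default 1000).
#' @return channels x k matrix; also attaches the generating node indices
#'   and moments as attributes `nodes` and `moments`.
#' @export
generate_templates <- function(k, leadfield, grid, seed = 1, max_tries = 1000) {
  stopifnot(k >= 2, inherits(leadfield, "lead_field"), inherits(grid, "source_grid"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  r <- sqrt(rowSums(sweep(grid$positions, 2L, grid$center, "-")^2))
  superficial <- which(r >= stats::quantile(r, 0.7))
  maps <- matrix(NA_real_, nrow(leadfield$gain), k)
  nodes <- matrix(NA_integer_, 2, k)
  moments <- array(NA_real_, c(3, 2, k))
  j <- 1L
  for (tr in seq_len(max_tries)) {
    nd <- sample(superficial, 2L)
    mom <- matrix(rnorm(6), 3, 2)
    mom <- sweep(mom, 2L, sqrt(colSums(mom^2)), "/")
    v <- leadfield$gain[, (3 * nd[1] - 2):(3 * nd[1])] %*% mom[, 1] +
      leadfield$gain[, (3 * nd[2] - 2):(3 * nd[2])] %*% mom[, 2]
    v <- normalize_map(as.vector(v))
    ok <- j == 1L ||
      all(abs(crossprod(maps[, seq_len(j - 1L), drop = FALSE], v)) /
            nrow(maps) < 0.9)
    if (ok) {
      maps[, j] <- v; nodes[, j] <- nd; moments[, , j] <- mom
      if (j == k) {
        attr(maps, "nodes") <- nodes
        attr(maps, "moments") <- moments
        return(maps)
      }
      j <- j + 1L
    }
  }
  stop_fmt("could not draw %d sufficiently dissimilar templates in %d tries",
           k, max_tries)
}

# Cell ERP (channels x samples) for one cell: piecewise templates scaled by
# a smooth raised-cosine envelope within each segment.
cell_erp <- function(seg, templates, times, amplitude) {
  C <- nrow(templates)
  erp <- matrix(0, C, length(times))
  for (i in seq_len(nrow(seg))) {
    idx <- which(times >= seg$onset[i] & times < seg$offset[i])
    if (!length(idx)) next
    u <- (times[idx] - seg$onset[i]) / (seg$offset[i] - seg$onset[i])
    env <- 0.6 + 0.4 * sin(pi * u)    # smooth, strictly positive envelope
    erp[, idx] <- templates[, seg$template[i]] %o% (amplitude * env)
  }
  erp
}

# Ground-truth label sequence on the sampling grid for one cell.
cell_labels <- function(seg, times) {
  lab <- rep(0L, length(times))
  for (i in seq_len(nrow(seg))) {
    idx <- which(times >= seg$onset[i] & times < seg$offset[i])
    lab[idx] <- seg$template[i]
  }
  lab
}

#' Simulate an epoched EEG study with known microstate structure
#'
#' Every trial is the cell ERP (piecewise-constant template topographies
#' under a smooth amplitude envelope) scaled by a per-subject log-normal
#' amplitude factor, plus independent Gaussian channel noise. With
#' `trials = FALSE` the per-subject evoked responses are returned directly,
#' with noise SD `noise_sd / sqrt(n_trials)` (the distribution of the mean
#' of `n_trials` i.i.d.-noise trials), which is far cheaper at study scale.
#'
#' @param spec a [simulation_spec()].
#' @param templates channels x k template matrix ([generate_templates()]).
#' @param montage the `electrode_montage` the templates live on.
#' @param trials if `TRUE` return `epoch_set`s (trial level), else
#'   subject-level [evoked()] objects.
#' @return list with `data` (list of `epoch_set` or `evoked`, one per
#'   subject x condition), and `ground_truth` (templates, per-cell label
#'   sequences, per-cell durations in the 295-480 ms window, cell
#'   amplitudes).
#' @export
simulate_study <- function(spec, templates, montage, trials = FALSE) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(montage, "electrode_montage"),
            nrow(templates) == length(montage$labels))
  set.seed(as.integer(spec$seed) %% .Machine$integer.max)
  sfreq <- spec$sfreq
  # epoch -200..750 ms: samples on the grid, onset included, end <= 750 ms
  n_s <- floor(950 * sfreq / 1000) + 1L
  t0 <- floor(200 * sfreq / 1000) + 1L
  times <- epoch_times(n_s, sfreq, t0)
  design <- spec$design
  k <- spec$k_templates
  data <- list()
  gt_labels <- list(); gt_durations <- list()
  erps <- list()
  for (cell in names(spec$timeline)) {
    seg <- spec$timeline[[cell]]
    erps[[cell]] <- cell_erp(seg, templates, times, spec$cell_amplitudes[[cell]])
    lab <- cell_labels(seg, times)
    gt_labels[[cell]] <- lab
    win <- times >= 295 & times < 480
    gt_durations[[cell]] <- state_durations(lab[win], k, sfreq)
  }
  sid <- 0L
  for (g in names(design$groups)) {
    for (s in seq_len(design$groups[[g]])) {
      sid <- sid + 1L
      subj <- sprintf("S%02d", sid)
      jit <- exp(rnorm(1, 0, spec$subject_jitter_sd))
      for (cn in design$conditions) {
        cell <- paste(g, cn, sep = ".")
        erp <- jit * erps[[cell]]
        if (trials) {
          arr <- array(NA_real_, c(spec$n_trials, nrow(erp), n_s))
          for (tr in seq_len(spec$n_trials))
            arr[tr, , ] <- erp + matrix(rnorm(length(erp), 0, spec$noise_sd),
                                        nrow(erp))
          data[[paste(subj, cn, sep = ".")]] <-
            epoch_set(arr, sfreq, t0, subj, g, cn, montage$labels)
        } else {
          noise <- matrix(rnorm(length(erp), 0, spec$noise_sd / sqrt(spec$n_trials)),
                          nrow(erp))
          data[[paste(subj, cn, sep = ".")]] <-
            evoked(erp + noise, sfreq, t0, n_epochs = spec$n_trials,
                   labels = montage$labels, subject_id = subj, group = g,
                   condition = cn)
        }
      }
    }
  }
  list(data = data,
       ground_truth = list(templates = templates, labels = gt_labels,
                           durations = gt_durations,
                           cell_amplitudes = spec$cell_amplitudes,
                           times = times))
}

#' Grand means per design cell from a list of evoked objects
#'
#' @param evokeds list of [evoked()] objects with group/condition metadata.
#' @return named list of [evoked()] grand means, one per `group.condition`.
#' @export
grand_mean_cells <- function(evokeds) {
  keys <- vapply(evokeds, function(e) paste(e$group, e$condition, sep = "."),
                 character(1))
  out <- list()
  for (kk in unique(keys)) {
    sub <- evokeds[keys == kk]
    avg <- Reduce(`+`, lapply(sub, function(e) e$data)) / length(sub)
    e1 <- sub[[1]]
    out[[kk]] <- evoked(avg, e1$sfreq, e1$t0_index, n_epochs = length(sub),
                        labels = e1$labels, group = e1$group,
                        condition = e1$condition)
  }
  out
}

#' Simulate YES/NO appraisal responses with known sensitivity
#'
#' Equal-variance signal-detection model. For each group the subject's
#' decision criterion sits at `criterion_c` plus half the group's mean
#' transgression d-prime, so that the hit rate for transgression `t` is
#' `pnorm(dprime_t - dbar/2 - c)` and the false-alarm rate (NO responses to
#' regular endings, the shared noise class) is `pnorm(-dbar/2 - c)`; the
#' recovered `z(H) - z(FA)` then equals the per-cell target. When the two
#' transgression targets coincide this is the symmetric unbiased placement
#' `H = pnorm(d'/2 - c)`, `FA = pnorm(-d'/2 - c)`.
#'
#' @param design a [study_design()] whose conditions are
#'   `c("R", <transgressions...>)`.
#' @param dprime_by_cell named list per group of named d-prime targets per
#'   transgression condition, e.g.
#'   `list(Nonmusician = c(Tsub = 0.49, Tapp = 1.60), ...)`.
#' @param criterion_c response bias (0 = unbiased; positive = conservative,
#'   fewer NO responses).
#' @param n_trials trials per condition (default 90).
#' @param seed integer seed.
#' @return data.frame: subject, group, condition, trial, response
#'   ("YES"/"NO").
#' @export
simulate_behavior <- function(design = study_design(),
                              dprime_by_cell = default_dprime(),
                              criterion_c = 0, n_trials = 90, seed = 1) {
  stopifnot(n_trials >= 1)
  if (!all(vapply(dprime_by_cell, function(x) all(is.finite(x)), logical(1))))
    stop_fmt("d-prime targets must be finite")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  trans <- setdiff(design$conditions, "R")
  rows <- list()
  sid <- 0L
  for (g in names(design$groups)) {
    dbar <- mean(dprime_by_cell[[g]][trans])
    p_no <- c(R = pnorm(-dbar / 2 - criterion_c),
              setNames(pnorm(dprime_by_cell[[g]][trans] - dbar / 2 - criterion_c),
                       trans))
    for (s in seq_len(design$groups[[g]])) {
      sid <- sid + 1L
      for (cn in design$conditions) {
        no <- rbinom(n_trials, 1L, p_no[[cn]]) == 1L
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sprintf("S%02d", sid), group = g, condition = cn,
          trial = seq_len(n_trials),
          response = ifelse(no, "NO", "YES"), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Default per-cell d-prime targets
#'
#' Group means reported for the reference study: untrained listeners show
#' weak sensitivity to the subtle transgression and moderate sensitivity to
#' the apparent one; amateurs are intermediate; experts are near ceiling for
#' both.
#'
#' @return named list per group of per-transgression d-prime targets.
#' @export
default_dprime <- function() {
  list(Nonmusician = c(Tsub = 0.49, Tapp = 1.60),
       Amateur = c(Tsub = 1.54, Tapp = 3.68),
       Expert = c(Tsub = 4.40, Tapp = 4.50))
}
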