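# Behavioural arm: scoring of YES/NO appraisal responses, signal-detection
# d-prime, mixed ANOVA and Bonferroni-corrected contrasts.

#' Score trial-level YES/NO responses
#'
#' Regular endings (`"R"`) are the noise class: a NO response to R is a
#' false alarm. Transgressed endings are signal trials: a NO response is a
#' hit (correct detection of the transgression).
#'
#' @param trials data.frame with columns subject, group, condition,
#'   response ("YES"/"NO"), e.g. from [simulate_behavior()].
#' @param noise_condition name of the regular-ending condition
#'   (default "R").
#' @return data.frame, one row per subject x condition: n_trials, n_yes,
#'   n_no, percent_correct, and per transgression condition the d-prime
#'   computed against the subject's shared false-alarm count.
#' @export
score_responses <- function(trials, noise_condition = "R") {
  need <- c("subject", "group", "condition", "response")
  if (!all(need %in% names(trials)))
    stop_fmt("trials must have columns %s", paste(need, collapse = ", "))
  if (!all(trials$response %in% c("YES", "NO")))
    stop_fmt("responses must be YES or NO")
  conds <- unique(trials$condition)
  if (!noise_condition %in% conds)
    stop_fmt("unknown noise condition '%s'", noise_condition)
  agg <- aggregate(cbind(n_trials = response == response,
                         n_no = response == "NO") ~ subject + group + condition,
                   data = trials, FUN = sum)
  agg$n_yes <- agg$n_trials - agg$n_no
  agg$percent_correct <- ifelse(agg$condition == noise_condition,
                                100 * agg$n_yes / agg$n_trials,
                                100 * agg$n_no / agg$n_trials)
  agg$dprime <- NA_real_
  for (s in unique(agg$subject)) {
    noise <- agg[agg$subject == s & agg$condition == noise_condition, ]
    for (cn in setdiff(conds, noise_condition)) {
      i <- which(agg$subject == s & agg$condition == cn)
      agg$dprime[i] <- dprime(hits = agg$n_no[i], n_signal = agg$n_trials[i],
                              fas = noise$n_no, n_noise = noise$n_trials)
    }
  }
  agg[order(agg$subject, agg$condition), ]
}

#' Signal-detection sensitivity (d-prime) from counts
#'
#' Rates of exactly 0 or 1 are corrected by the 1/(2N) rule (0 becomes
#' `1/(2N)`, 1 becomes `1 - 1/(2N)`); interior rates are used exactly.
#' `d' = z(H) - z(FA)`. Negative values indicate responding below chance
#' sensitivity (more false alarms than hits).
#'
#' @param hits number of hits (NO responses to signal trials).
#' @param n_signal number of signal trials (> 0).
#' @param fas number of false alarms (NO responses to noise trials).
#' @param n_noise number of noise trials (> 0).
#' @return d-prime (finite).
#' @export
dprime <- function(hits, n_signal, fas, n_noise) {
  if (n_signal <= 0 || n_noise <= 0) stop_fmt("trial counts must be positive")
  stopifnot(hits >= 0, hits <= n_signal, fas >= 0, fas <= n_noise)
  fix <- function(x, n) {
    r <- x / n
    if (r == 0) r <- 1 / (2 * n)
    if (r == 1) r <- 1 - 1 / (2 * n)
    r
  }
  qnorm(fix(hits, n_signal)) - qnorm(fix(fas, n_noise))
}

#' Mixed ANOVA on d-prime
#'
#' Group (between) x transgression condition (within) split-plot ANOVA on
#' the per-subject d-prime values, reporting F, degrees of freedom, p and
#' partial eta squared per effect.
#'
#' @param scores data.frame from [score_responses()] (rows with non-missing
#'   `dprime` are used).
#' @return a [stat_table()].
#' @export
dprime_anova <- function(scores) {
  d <- scores[!is.na(scores$dprime), ]
  subs <- unique(d$subject)
  conds <- sort(unique(d$condition))
  y <- matrix(NA_real_, length(subs), length(conds),
              dimnames = list(subs, conds))
  for (i in seq_len(nrow(d))) y[d$subject[i], d$condition[i]] <- d$dprime[i]
  if (anyNA(y)) stop_fmt("missing d-prime cells")
  grp <- d$group[match(subs, d$subject)]
  mixed_anova(y, grp, effect_names = c("Expertise", "Transgression"))
}

#' Bonferroni-corrected group and simple-effect contrasts on d-prime
#'
#' Per transgression condition: the three pairwise independent t-tests
#' between groups, Bonferroni factor 3. Per group: a paired t-test between
#' the two transgression conditions, Bonferroni factor 3 (one per group).
#' Degenerate variance yields p = 1 with a warning.
#'
#' @param scores data.frame from [score_responses()].
#' @return a [stat_table()].
#' @export
group_contrasts <- function(scores) {
  d <- scores[!is.na(scores$dprime), ]
  conds <- sort(unique(d$condition))
  groups <- sort(unique(d$group))
  out <- list()
  t_ind <- function(x, y) {
    nx <- length(x); ny <- length(y)
    sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
    if (sp2 == 0) {
      warn_fmt("degenerate variance in an independent contrast")
      return(list(t = 0, df = nx + ny - 2, p = 1))
    }
    tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    list(t = tt, df = nx + ny - 2, p = 2 * pt(abs(tt), nx + ny - 2, lower.tail = FALSE))
  }
  for (cn in conds) {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    for (pr in prs) {
      x <- d$dprime[d$condition == cn & d$group == pr[1]]
      y <- d$dprime[d$condition == cn & d$group == pr[2]]
      r <- t_ind(x, y)
      out[[length(out) + 1L]] <- stat_table(
        label = sprintf("%s: %s vs %s", cn, pr[1], pr[2]), statistic = "t",
        value = r$t, df1 = r$df, df2 = NA, p = min(1, r$p * length(prs)),
        effect_size = NA, correction = sprintf("bonferroni x%d", length(prs)))
    }
  }
  if (length(conds) == 2L) {
    for (g in groups) {
      x <- d$dprime[d$group == g & d$condition == conds[1]]
      y <- d$dprime[d$group == g & d$condition == conds[2]]
      subx <- d$subject[d$group == g & d$condition == conds[1]]
      suby <- d$subject[d$group == g & d$condition == conds[2]]
      diffs <- x[order(subx)] - y[order(suby)]
      if (var(diffs) == 0) {
        warn_fmt("degenerate variance in the paired contrast for %s", g)
        tt <- 0; p <- 1; dfp <- length(diffs) - 1
      } else {
        tt <- mean(diffs) / (sd(diffs) / sqrt(length(diffs)))
        dfp <- length(diffs) - 1
        p <- 2 * pt(abs(tt), dfp, lower.tail = FALSE)
      }
      out[[length(out) + 1L]] <- stat_table(
        label = sprintf("%s: %s vs %s (paired)", g, conds[1], conds[2]),
        statistic = "t", value = tt, df1 = dfp, df2 = NA,
        p = min(1, p * length(groups)), effect_size = NA,
        correction = sprintf("bonferroni x%d", length(groups)))
    }
  }
  do.call(rbind_stat, out)
}
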