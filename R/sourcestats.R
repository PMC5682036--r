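# Node-wise mixed-design (split-plot) ANOVA on current density, cluster-
# extent thresholding, Monte-Carlo cluster calibration (AlphaSim approach),
# and gatekept Fisher-LSD post-hocs.

#' Mixed-design ANOVA, vectorised over nodes
#'
#' Classical split-plot ANOVA with one between-subject factor (group) and
#' one within-subject factor (condition), computed independently at every
#' node. Unequal group sizes are handled by unweighted-means sums of squares
#' for the between-factor terms. The between effect is tested against
#' subjects-within-groups; the within effect and the interaction against the
#' subject x condition residual. A node with zero residual variance reports
#' `F = 0, p = 1`.
#'
#' @param y numeric array subjects x conditions x nodes (a matrix is treated
#'   as a single node).
#' @param group factor/character vector of length `subjects`.
#' @return list with per-effect (`between`, `within`, `interaction`)
#'   elements `F` and `p` (vectors over nodes), plus `df` (named list of
#'   `c(df1, df2)`).
#' @export
mixed_anova_map <- function(y, group) {
  if (length(dim(y)) == 2L) dim(y) <- c(dim(y), 1L)
  stopifnot(length(dim(y)) == 3L)
  N <- dim(y)[1]; b <- dim(y)[2]; V <- dim(y)[3]
  group <- factor(group)
  a <- nlevels(group)
  if (a < 2L) stop_fmt("need >= 2 groups")
  ng <- as.vector(table(group))
  if (any(ng < 2L)) stop_fmt("every group needs >= 2 subjects")
  n_h <- a / sum(1 / ng)
  if (b == 1L) {
    # pure between-subject reduction (one-way on the single condition)
    S <- matrix(y[, 1, ], N, V)
    G <- model_matrix_groups(group)
    R <- G %*% S
    grand <- colMeans(R)
    ss_A <- n_h * colSums(sweep(R, 2L, grand, "-")^2)
    ss_S <- colSums((S - R[as.integer(group), , drop = FALSE])^2)
    df <- list(between = c(a - 1, N - a))
    ms_err <- ss_S / df$between[2]
    f <- ifelse(ms_err > 0, (ss_A / df$between[1]) / ms_err, 0)
    p <- ifelse(ms_err > 0, pf(f, df$between[1], df$between[2], lower.tail = FALSE), 1)
    return(list(between = list(F = f, p = p), df = df,
                ss = list(between = ss_A, subjects = ss_S)))
  }
  Y <- matrix(y, nrow = N)                     # N x (b*V), conditions fastest? no:
  # y[i, c, v] maps to column (v-1)*b + c of matrix(y, N): R unrolls dim 2 first.
  G <- model_matrix_groups(group)              # a x N averaging matrix
  M <- G %*% Y                                 # a x (b*V) cell means
  S <- subject_means(y)                        # N x V subject means
  Gs <- G %*% S                                # a x V group means of subject means
  dim(M) <- c(a, b, V)
  R <- apply(M, c(1, 3), mean)                 # a x V row means (= Gs)
  Cm <- apply(M, c(2, 3), mean)                # b x V unweighted condition means
  grand <- colMeans(R)                         # V
  ss_A <- n_h * b * colSums(sweep(R, 2L, grand, "-")^2)
  ss_B <- n_h * a * colSums(sweep(Cm, 2L, grand, "-")^2)
  inter <- sweep(M, c(1, 3), R) |> sweep(c(2, 3), Cm) |> sweep(3, -grand)
  ss_AB <- n_h * apply(inter^2, 3, sum)
  ss_S <- b * colSums((S - Gs[group, , drop = FALSE])^2)
  fit <- array(NA_real_, dim(y))
  Mfull <- array(M, c(a, b, V))
  gi <- as.integer(group)
  for (cnd in seq_len(b))
    fit[, cnd, ] <- S + matrix(Mfull[gi, cnd, ], N, V) -
      matrix(Gs[gi, ], N, V)
  ss_res <- apply((y - fit)^2, 3, sum)
  df <- list(between = c(a - 1, N - a),
             within = c(b - 1, (N - a) * (b - 1)),
             interaction = c((a - 1) * (b - 1), (N - a) * (b - 1)))
  f_of <- function(ss_eff, df1, ss_err, df2) {
    ms_err <- ss_err / df2
    f <- ifelse(ms_err > 0, (ss_eff / df1) / ms_err, 0)
    p <- ifelse(ms_err > 0, pf(f, df1, df2, lower.tail = FALSE), 1)
    list(F = f, p = p)
  }
  out <- list(
    between = f_of(ss_A, df$between[1], ss_S, df$between[2]),
    within = f_of(ss_B, df$within[1], ss_res, df$within[2]),
    interaction = f_of(ss_AB, df$interaction[1], ss_res, df$interaction[2]))
  out$df <- df
  out$ss <- list(between = ss_A, within = ss_B, interaction = ss_AB,
                 subjects = ss_S, residual = ss_res)
  out
}

model_matrix_groups <- function(group) {
  a <- nlevels(group)
  G <- matrix(0, a, length(group))
  for (g in seq_len(a)) G[g, group == levels(group)[g]] <- 1 / sum(group == levels(group)[g])
  G
}

subject_means <- function(y) {
  # N x V means over the condition dimension
  colMeans(aperm(y, c(2L, 1L, 3L)))
}

#' Mixed ANOVA on a single variable, reported as a stat table
#'
#' Same engine as [mixed_anova_map()], with partial eta squared
#' (`SS_effect / (SS_effect + SS_error)`) per effect.
#'
#' @param y subjects x conditions matrix.
#' @param group group factor of length `subjects`.
#' @param effect_names labels for the two factors (between, within).
#' @return a [stat_table()] with one row per effect.
#' @export
mixed_anova <- function(y, group, effect_names = c("between", "within")) {
  y <- as.matrix(y)
  if (anyNA(y)) stop_fmt("missing cells in the design")
  res <- mixed_anova_map(y, group)
  eta <- c(res$ss$between / (res$ss$between + res$ss$subjects),
           res$ss$within / (res$ss$within + res$ss$residual),
           res$ss$interaction / (res$ss$interaction + res$ss$residual))
  stat_table(
    label = c(effect_names[1], effect_names[2],
              paste(effect_names, collapse = " x ")),
    statistic = "F",
    value = c(res$between$F, res$within$F, res$interaction$F),
    df1 = c(res$df$between[1], res$df$within[1], res$df$interaction[1]),
    df2 = c(res$df$between[2], res$df$within[2], res$df$interaction[2]),
    p = c(res$between$p, res$within$p, res$interaction$p),
    effect_size = eta, correction = "none")
}

# ---------------------------------------------------------------------------
# Cluster-extent machinery

# Connected components of `nodes` (integer indices) under the grid adjacency.
connected_components <- function(nodes, adjacency) {
  if (!length(nodes)) return(list())
  in_set <- logical(length(adjacency))
  in_set[nodes] <- TRUE
  seen <- logical(length(adjacency))
  comps <- list()
  for (s in nodes) {
    if (seen[s]) next
    comp <- integer(0)
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      comp <- c(comp, v)
      nb <- adjacency[[v]]
      nb <- nb[in_set[nb] & !seen[nb]]
      if (length(nb)) { seen[nb] <- TRUE; stack <- c(stack, nb) }
    }
    comps[[length(comps) + 1L]] <- comp
  }
  comps
}

#' Cluster-extent thresholding of a statistical map
#'
#' Supra-threshold nodes (`p < node_alpha`) are grouped into connected
#' components under the grid's adjacency (nodes within the connection
#' radius); only components of at least `min_nodes` nodes are reported.
#'
#' @param p_map per-node p-values.
#' @param f_map per-node F (or other statistic) values, used for peaks.
#' @param grid a [build_grid()] result.
#' @param node_alpha node-level threshold (default 0.005).
#' @param min_nodes minimum cluster extent (default 10).
#' @param effect label stored with each cluster.
#' @return data.frame: effect, cluster id, size, peak statistic, peak node
#'   index and coordinates (mm), and the member node ids (list column).
#' @export
threshold_clusters <- function(p_map, f_map, grid, node_alpha = 0.005,
                               min_nodes = 10, effect = "effect") {
  stopifnot(inherits(grid, "source_grid"),
            length(p_map) == nrow(grid$positions))
  supra <- which(p_map < node_alpha)
  comps <- connected_components(supra, grid$adjacency)
  comps <- comps[vapply(comps, length, integer(1)) >= min_nodes]
  if (!length(comps))
    return(data.frame(effect = character(), cluster = integer(),
                      size = integer(), peak_F = numeric(),
                      peak_node = integer(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric(),
                      members = I(list())))
  rows <- lapply(seq_along(comps), function(i) {
    mem <- comps[[i]]
    pk <- mem[which.max(f_map[mem])]
    data.frame(effect = effect, cluster = i, size = length(mem),
               peak_F = f_map[pk], peak_node = pk,
               peak_x = grid$positions[pk, 1], peak_y = grid$positions[pk, 2],
               peak_z = grid$positions[pk, 3], members = I(list(mem)))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo calibration of the cluster-extent criterion
#'
#' AlphaSim-style estimate of the per-map probability that smooth Gaussian
#' noise produces at least one supra-threshold cluster of the minimum
#' extent. Per iteration: i.i.d. standard Gaussian node values are smoothed
#' with a Gaussian kernel of the given FWHM over node distances (kernel rows
#' renormalised), re-standardised to unit variance, thresholded two-sided at
#' `node_alpha`, and searched for connected clusters of `min_nodes` or more.
#'
#' @param grid a [build_grid()] result (its adjacency defines contiguity).
#' @param fwhm smoothing kernel full width at half maximum, mm (default 7).
#' @param node_alpha two-sided node threshold (default 0.005).
#' @param min_nodes minimum cluster extent (default 10).
#' @param n_iter Monte-Carlo iterations (default 10000).
#' @param seed integer seed.
#' @return list of class `mc_calibration`: `prob` (estimated per-map
#'   probability), `n_hits`, `n_iter`, parameters and `seed`.
#' @export
montecarlo_cluster_p <- function(grid, fwhm = 7, node_alpha = 0.005,
                                 min_nodes = 10, n_iter = 10000, seed = 1) {
  stopifnot(inherits(grid, "source_grid"), n_iter >= 1)
  n <- nrow(grid$positions)
  K <- smoothing_kernel(grid, fwhm)
  sd_vec <- sqrt(Matrix::rowSums(K^2))
  thr <- qnorm(1 - node_alpha / 2)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  hits <- 0L
  for (it in seq_len(n_iter)) {
    z <- rnorm(n)
    s <- as.vector(K %*% z) / sd_vec
    supra <- which(abs(s) > thr)
    if (length(supra) >= min_nodes) {
      comps <- connected_components(supra, grid$adjacency)
      if (any(vapply(comps, length, integer(1)) >= min_nodes)) hits <- hits + 1L
    }
  }
  structure(list(prob = hits / n_iter, n_hits = hits, n_iter = n_iter,
                 fwhm = fwhm, node_alpha = node_alpha, min_nodes = min_nodes,
                 connection_radius = grid$connection_radius, seed = seed),
            class = "mc_calibration")
}

#' @export
print.mc_calibration <- function(x, ...) {
  cat(sprintf(paste0("<mc_calibration> P(>=1 cluster of >=%d nodes) = %.5f ",
                     "(%d/%d iterations; fwhm %g mm, node alpha %g)\n"),
              x$min_nodes, x$prob, x$n_hits, x$n_iter, x$fwhm, x$node_alpha))
  invisible(x)
}

# Sparse row-normalised Gaussian smoothing kernel over node distances,
# truncated at 3 sigma. fwhm = 0 gives the identity.
smoothing_kernel <- function(grid, fwhm) {
  n <- nrow(grid$positions)
  if (fwhm <= 0) return(Matrix::Diagonal(n))
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  cutoff <- 3 * sigma
  s <- grid$spacing
  maxoff <- floor(cutoff / s)
  ii <- seq_len(n); jj <- seq_len(n); ww <- rep(1, n)  # self weights
  if (maxoff >= 1) {
    g <- seq(-maxoff, maxoff)
    offs <- as.matrix(expand.grid(g, g, g))
    d <- sqrt(rowSums(offs^2)) * s
    offs <- offs[d > 0 & d <= cutoff, , drop = FALSE]
    d <- sqrt(rowSums(offs^2)) * s
    keys <- grid$ijk[, 1] * 4e6 + grid$ijk[, 2] * 2e3 + grid$ijk[, 3] + 4.002e9
    ord <- order(keys); sorted <- keys[ord]
    for (r in seq_len(nrow(offs))) {
      nb <- (grid$ijk[, 1] + offs[r, 1]) * 4e6 +
        (grid$ijk[, 2] + offs[r, 2]) * 2e3 + (grid$ijk[, 3] + offs[r, 3]) + 4.002e9
      pos <- findInterval(nb, sorted)
      hit <- pos >= 1L & sorted[pmax(pos, 1L)] == nb
      from <- which(hit); to <- ord[pos[hit]]
      w <- exp(-d[r]^2 / (2 * sigma^2))
      ii <- c(ii, from); jj <- c(jj, to); ww <- c(ww, rep(w, length(from)))
    }
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(n, n))
  rs <- Matrix::rowSums(K)
  Matrix::Diagonal(x = 1 / rs) %*% K
}

#' Gatekept Fisher-LSD post-hoc contrasts
#'
#' Pairwise comparisons using the omnibus error term and its degrees of
#' freedom, with no further correction (Fisher's least significant
#' difference, which holds the family-wise error rate at alpha for exactly
#' three groups). Contrasts are reported only when the omnibus test is
#' significant; otherwise an empty table with a gatekeeping note results.
#'
#' @param values for `effect = "between"`: a numeric vector (one value per
#'   subject, e.g. a peak-node CD averaged over conditions); for
#'   `"within"`: a subjects x conditions matrix.
#' @param group group factor (between effect only).
#' @param effect `"between"` or `"within"`.
#' @param alpha omnibus gate (default 0.05).
#' @return a [stat_table()] (possibly empty).
#' @export
lsd_posthoc <- function(values, group = NULL, effect = c("between", "within"),
                        alpha = 0.05) {
  effect <- match.arg(effect)
  if (effect == "between") {
    group <- factor(group)
    a <- nlevels(group)
    ng <- as.vector(table(group))
    means <- tapply(values, group, mean)
    grand <- mean(values)
    ss_b <- sum(ng * (means - grand)^2)
    ss_w <- sum((values - means[group])^2)
    df1 <- a - 1; df2 <- length(values) - a
    mse <- ss_w / df2
    f <- if (mse > 0) (ss_b / df1) / mse else 0
    p_omni <- if (mse > 0) pf(f, df1, df2, lower.tail = FALSE) else 1
    if (!(p_omni < alpha)) {
      out <- stat_table()
      attr(out, "gatekeeping") <- sprintf("omnibus F(%d,%d) = %.3f, p = %.4f >= %g: no contrasts",
                                          df1, df2, f, p_omni, alpha)
      return(out)
    }
    prs <- utils::combn(levels(group), 2, simplify = FALSE)
    rows <- lapply(prs, function(pr) {
      n1 <- ng[match(pr[1], levels(group))]; n2 <- ng[match(pr[2], levels(group))]
      tt <- (means[pr[1]] - means[pr[2]]) / sqrt(mse * (1 / n1 + 1 / n2))
      stat_table(label = sprintf("%s vs %s", pr[1], pr[2]), statistic = "t",
                 value = unname(tt), df1 = df2, df2 = NA,
                 p = 2 * pt(abs(tt), df2, lower.tail = FALSE),
                 effect_size = NA, correction = "LSD (gated)")
    })
    return(do.call(rbind_stat, rows))
  }
  # within: repeated measures one-way on a subjects x conditions matrix
  y <- as.matrix(values)
  ns <- nrow(y); b <- ncol(y)
  smean <- rowMeans(y); cmean <- colMeans(y); grand <- mean(y)
  ss_b <- ns * sum((cmean - grand)^2)
  resid <- y - outer(smean, rep(1, b)) - outer(rep(1, ns), cmean) + grand
  ss_e <- sum(resid^2)
  df1 <- b - 1; df2 <- (ns - 1) * (b - 1)
  mse <- ss_e / df2
  f <- if (mse > 0) (ss_b / df1) / mse else 0
  p_omni <- if (mse > 0) pf(f, df1, df2, lower.tail = FALSE) else 1
  if (!(p_omni < alpha)) {
    out <- stat_table()
    attr(out, "gatekeeping") <- sprintf("omnibus F(%d,%d) = %.3f, p = %.4f >= %g: no contrasts",
                                        df1, df2, f, p_omni, alpha)
    return(out)
  }
  cn <- colnames(y) %||% paste0("c", seq_len(b))
  prs <- utils::combn(seq_len(b), 2, simplify = FALSE)
  rows <- lapply(prs, function(pr) {
    tt <- (cmean[pr[1]] - cmean[pr[2]]) / sqrt(mse * 2 / ns)
    stat_table(label = sprintf("%s vs %s", cn[pr[1]], cn[pr[2]]), statistic = "t",
               value = unname(tt), df1 = df2, df2 = NA,
               p = 2 * pt(abs(tt), df2, lower.tail = FALSE),
               effect_size = NA, correction = "LSD (gated)")
  })
  do.call(rbind_stat, rows)
}
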