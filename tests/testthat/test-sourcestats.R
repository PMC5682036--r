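# Split-plot ANOVA maps, cluster-extent thresholding, Monte-Carlo cluster
# calibration, gatekept LSD post-hocs.

test_that("the mixed ANOVA matches aov on balanced toy data", {
  set.seed(1)
  for (rep in 1:3) {
    y <- matrix(rnorm(18), 6, 3)
    grp <- rep(c("a", "b", "c"), each = 2)
    got <- mixed_anova(y, grp)
    df <- data.frame(y = as.vector(y), s = factor(rep(1:6, 3)),
                     g = factor(rep(grp, 3)), c = factor(rep(1:3, each = 6)))
    fit <- summary(aov(y ~ g * c + Error(s / c), data = df))
    bet <- fit[["Error: s"]][[1]]
    wit <- fit[["Error: s:c"]][[1]]
    expect_equal(got$value, c(bet["g", "F value"], wit["c", "F value"],
                              wit["g:c", "F value"]), tolerance = 1e-8)
    expect_equal(got$p, c(bet["g", "Pr(>F)"], wit["c", "Pr(>F)"],
                          wit["g:c", "Pr(>F)"]), tolerance = 1e-8)
    # partial eta^2 from aov sums of squares
    eta <- c(bet["g", "Sum Sq"] / (bet["g", "Sum Sq"] + bet["Residuals", "Sum Sq"]),
             wit["c", "Sum Sq"] / (wit["c", "Sum Sq"] + wit["Residuals", "Sum Sq"]),
             wit["g:c", "Sum Sq"] / (wit["g:c", "Sum Sq"] + wit["Residuals", "Sum Sq"]))
    expect_equal(got$effect_size, eta, tolerance = 1e-8)
  }
})

test_that("identical data give F = 0, p = 1", {
  y <- matrix(5, 6, 3)
  got <- mixed_anova(y, rep(c("a", "b", "c"), each = 2))
  expect_equal(got$value, c(0, 0, 0))
  expect_equal(got$p, c(1, 1, 1))
})

test_that("the 2-group single-condition reduction equals the squared pooled t", {
  set.seed(2)
  x <- rnorm(8); y <- rnorm(9, 0.5)
  res <- mixed_anova_map(array(c(x, y), c(17, 1, 1)),
                         rep(c("a", "b"), c(8, 9)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(res$between$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$between$p, tt$p.value, tolerance = 1e-10)
})

test_that("the map version equals per-node scalar ANOVAs", {
  set.seed(3)
  y <- array(rnorm(10 * 3 * 7), c(10, 3, 7))
  grp <- rep(c("a", "b", "c"), c(3, 3, 4))   # unequal n
  res <- mixed_anova_map(y, grp)
  for (v in c(1, 4, 7)) {
    one <- mixed_anova(y[, , v], grp)
    expect_equal(c(res$between$F[v], res$within$F[v], res$interaction$F[v]),
                 one$value, tolerance = 1e-10)
  }
  expect_error(mixed_anova_map(y, rep(c("a", "b"), c(1, 9))), ">= 2 subjects")
})

toy_grid <- function(n_side = 6, spacing = 6) {
  h <- head_model()
  g <- seq_len(n_side) - 1L
  ijk <- as.matrix(expand.grid(i = g, j = g, k = g))
  pos <- ijk * spacing
  structure(list(positions = pos, ijk = ijk, spacing = spacing,
                 gm_radius = NA, shell = c(0, 1), connection_radius = 10,
                 adjacency = erpstates:::lattice_adjacency(ijk, spacing, 10),
                 center = c(0, 0, 0)),
            class = "source_grid")
}

test_that("cluster extraction respects size and connectivity rules", {
  g <- toy_grid()
  n <- nrow(g$positions)
  p <- rep(1, n); f <- rep(0, n)
  # a 12-node blob: contiguous lattice rows
  blob <- which(g$ijk[, 1] <= 3 & g$ijk[, 2] == 0 & g$ijk[, 3] <= 2)[1:12]
  p[blob] <- 1e-4; f[blob] <- 5
  tab <- threshold_clusters(p, f, g, effect = "test")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 12)
  expect_true(tab$peak_node %in% blob)

  # 9 nodes: below the minimum extent
  p2 <- rep(1, n); p2[blob[1:9]] <- 1e-4
  expect_equal(nrow(threshold_clusters(p2, f, g)), 0)

  # two supra nodes 12 mm apart are separate components (each rejected)
  p3 <- rep(1, n)
  a <- which(g$ijk[, 1] == 0 & g$ijk[, 2] == 0 & g$ijk[, 3] == 0)
  b <- which(g$ijk[, 1] == 2 & g$ijk[, 2] == 0 & g$ijk[, 3] == 0)
  p3[c(a, b)] <- 1e-4
  expect_equal(nrow(threshold_clusters(p3, f, g, min_nodes = 2)), 0)
  expect_equal(nrow(threshold_clusters(p3, f, g, min_nodes = 1)), 2)
})

test_that("cluster membership is invariant to node relabelling", {
  g <- toy_grid(5)
  n <- nrow(g$positions)
  set.seed(4)
  p <- runif(n); p[p < 0.4] <- 1e-4
  tab <- threshold_clusters(p, rep(1, n), g, min_nodes = 3)
  perm <- sample(n)
  g2 <- g
  g2$positions <- g$positions[perm, ]
  g2$ijk <- g$ijk[perm, ]
  g2$adjacency <- erpstates:::lattice_adjacency(g2$ijk, g$spacing, 10)
  tab2 <- threshold_clusters(p[perm], rep(1, n), g2, min_nodes = 3)
  sizes1 <- sort(tab$size)
  sizes2 <- sort(tab2$size)
  expect_equal(sizes1, sizes2)
  mem1 <- lapply(tab$members, sort)
  mem2 <- lapply(tab2$members, function(m) sort(perm[m]))
  expect_setequal(vapply(mem1, paste, "", collapse = ","),
                  vapply(mem2, paste, "", collapse = ","))
})

test_that("the unsmoothed single-node Monte-Carlo matches the closed form", {
  g <- toy_grid(8)         # 512 nodes
  n <- nrow(g$positions)
  alpha <- 0.005
  mc <- montecarlo_cluster_p(g, fwhm = 0, node_alpha = alpha, min_nodes = 1,
                             n_iter = 2000, seed = 5)
  p_true <- 1 - (1 - alpha)^n
  se <- sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(mc$prob - p_true), 3 * se)
})

test_that("the Monte-Carlo estimate is monotone in its strictness knobs", {
  g <- toy_grid(7)
  p1 <- montecarlo_cluster_p(g, fwhm = 7, node_alpha = 0.05, min_nodes = 1,
                             n_iter = 400, seed = 6)$prob
  p2 <- montecarlo_cluster_p(g, fwhm = 7, node_alpha = 0.05, min_nodes = 3,
                             n_iter = 400, seed = 6)$prob
  p3 <- montecarlo_cluster_p(g, fwhm = 7, node_alpha = 0.05, min_nodes = 6,
                             n_iter = 400, seed = 6)$prob
  expect_true(p1 >= p2 && p2 >= p3)
  q1 <- montecarlo_cluster_p(g, fwhm = 7, node_alpha = 0.05, min_nodes = 2,
                             n_iter = 400, seed = 7)$prob
  q2 <- montecarlo_cluster_p(g, fwhm = 7, node_alpha = 0.01, min_nodes = 2,
                             n_iter = 400, seed = 7)$prob
  q3 <- montecarlo_cluster_p(g, fwhm = 7, node_alpha = 0.002, min_nodes = 2,
                             n_iter = 400, seed = 7)$prob
  expect_true(q1 >= q2 && q2 >= q3)
  # determinism
  expect_identical(montecarlo_cluster_p(g, n_iter = 100, seed = 8)$prob,
                   montecarlo_cluster_p(g, n_iter = 100, seed = 8)$prob)
})

test_that("LSD post-hocs are gatekept and use the omnibus error term", {
  # equal group means: omnibus non-significant, empty table
  set.seed(9)
  v <- rnorm(30, 0, 1e-3) + rep(5, 30)
  tab <- lsd_posthoc(v, rep(c("a", "b", "c"), each = 10))
  expect_equal(nrow(tab), 0)
  expect_match(attr(tab, "gatekeeping"), "omnibus")

  # toy data with a real effect: brute-force pooled-error t
  v2 <- c(rnorm(10, 0), rnorm(10, 2), rnorm(10, 4))
  grp <- rep(c("a", "b", "c"), each = 10)
  tab2 <- lsd_posthoc(v2, grp)
  expect_equal(nrow(tab2), 3)
  mse <- sum(tapply(v2, grp, function(x) sum((x - mean(x))^2))) / 27
  t_ab <- (mean(v2[1:10]) - mean(v2[11:20])) / sqrt(mse * (2 / 10))
  row <- tab2[tab2$label == "a vs b", ]
  expect_equal(row$value, t_ab, tolerance = 1e-8)
  expect_equal(row$p, 2 * pt(abs(t_ab), 27, lower.tail = FALSE),
               tolerance = 1e-8)

  # within-subject variant gate
  y <- matrix(rnorm(40), 20, 2)
  res <- lsd_posthoc(y, effect = "within")
  expect_s3_class(res, "stat_table")
})
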