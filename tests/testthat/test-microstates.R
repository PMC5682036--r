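# Microstate machinery: GFP/GMD, segmentation, model selection, back-fit,
# durations and their nonparametric statistics.

test_that("gfp matches its closed form", {
  expect_equal(gfp(c(1, -1)), 1)
  expect_equal(gfp(rep(3.7, 10)), 0)
  set.seed(1)
  m <- rnorm(204)
  expect_equal(gfp(m), sqrt(mean((m - mean(m))^2)), tolerance = 1e-12)
})

test_that("gmd obeys the dissimilarity/correlation identity", {
  set.seed(2)
  u <- rnorm(50)
  expect_equal(gmd(u, u), 0)
  expect_equal(gmd(u, -u), 2)
  expect_error(gmd(u, rep(1, 50)), "zero-GFP")
  for (i in 1:1000) {
    a <- rnorm(30); b <- rnorm(30)
    r <- cor(a, b)
    expect_lt(abs(gmd(a, b)^2 - 2 * (1 - r)), 1e-10)
  }
})

orthogonal_templates <- function(C, k) {
  q <- qr.Q(qr(matrix(rnorm(C * (k + 1)), C, k + 1)))[, 1:k]
  q <- apply(q, 2, function(v) normalize_map(v))
  q
}

toy_cells <- function(tpl, reps = 30, seq_len_frames = 10, amp = 3) {
  # one "cell": templates in blocks of seq_len_frames frames each, repeated;
  # the first data frame sits at t = 0 (50 zero baseline columns, onset 51)
  C <- nrow(tpl); k <- ncol(tpl)
  lab <- rep(rep(seq_len(k), each = seq_len_frames), length.out = reps * k)
  data <- tpl[, lab] * amp
  ev <- evoked(cbind(matrix(0, C, 50), data), 250, 51, 1, paste0("E", 1:C))
  list(cells = list(cell = ev), labels = lab)
}

test_that("noiseless orthogonal-template data is segmented exactly", {
  set.seed(3)
  tpl <- orthogonal_templates(32, 4)
  tc <- toy_cells(tpl)
  mod <- microstate_segment(tc$cells, k = 4, n_restarts = 20, seed = 4)
  expect_equal(mod$gev, 1, tolerance = 1e-9)
  r <- abs(crossprod(mod$maps, tpl)) / nrow(tpl)
  expect_equal(sort(apply(r, 2, max)), rep(1, 4), tolerance = 1e-9)
  # recovered label sequence equals the construction up to map relabelling
  got <- mod$labels$cell
  perm <- apply(r, 2, which.max)
  expect_identical(unname(perm[tc$labels]), got)
})

test_that("segments shorter than the minimum duration are smoothed away", {
  set.seed(5)
  tpl <- orthogonal_templates(32, 3)
  # blocks of 12 frames with 3-frame blips that must be rejected
  lab <- c(rep(1, 12), rep(2, 3), rep(1, 12), rep(3, 12), rep(2, 12))
  ev <- evoked(cbind(matrix(0, 32, 50), tpl[, lab] * 2), 250, 51, 1,
               paste0("E", 1:32))
  mod <- microstate_segment(list(cell = ev), k = 3, n_restarts = 20,
                            min_frames = 7, seed = 6)
  runs <- rle(mod$labels$cell)
  expect_true(all(runs$lengths >= 7))
})

test_that("explained variance matches a brute-force frame sum", {
  set.seed(7)
  tpl <- orthogonal_templates(24, 3)
  tc <- toy_cells(tpl, reps = 5)
  mod <- microstate_segment(tc$cells, k = 3, n_restarts = 10, seed = 8)
  frames <- average_reference(tc$cells$cell$data[, -(1:50)])
  labels <- mod$labels$cell
  # brute force: GFP^2-weighted mean squared correlation
  num <- 0; den <- 0
  for (t in seq_len(ncol(frames))) {
    f <- frames[, t]
    den <- den + gfp(f)^2
    if (labels[t] > 0) {
      rr <- cor(f, mod$maps[, labels[t]])
      num <- num + gfp(f)^2 * rr^2
    }
  }
  expect_equal(explained_variance(mod, frames, labels), num / den,
               tolerance = 1e-12)
  expect_equal(explained_variance(mod, frames, rep(0L, ncol(frames))), 0)
})

test_that("model selection recovers the true k on noiseless data", {
  set.seed(9)
  tpl <- orthogonal_templates(32, 5)
  tc <- toy_cells(tpl, reps = 12)
  sel <- choose_k(tc$cells, k_range = 2:9, n_restarts = 10, seed = 10)
  expect_equal(sel$k_opt, 5)
  expect_equal(sel$criteria$kl[1], 0)                      # endpoint rule
  expect_equal(sel$criteria$kl[nrow(sel$criteria)], 0)
  expect_error(choose_k(tc$cells, k_range = 2:4), "consecutive")
})

test_that("cross-validation decreases with k on pure-noise data", {
  # overfitting guard: on structureless data CV's parsimony penalty must not
  # mask the monotone residual decrease
  # at the 204-channel reference configuration the parsimony penalty grows
  # slowly enough that the residual decrease dominates
  ok <- 0
  for (s in 1:10) {
    set.seed(400 + s)
    ev <- evoked(matrix(rnorm(204 * 150), 204), 250, 51, 1, paste0("E", 1:204))
    sel <- choose_k(list(cell = ev), k_range = 2:6, n_restarts = 10,
                    seed = 500 + s)
    if (all(diff(sel$criteria$cv) < 0)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("explained variance is non-decreasing in k on structured data", {
  set.seed(11)
  tpl <- orthogonal_templates(32, 6)
  tc <- toy_cells(tpl, reps = 8)
  sel <- choose_k(tc$cells, k_range = 2:8, n_restarts = 15, seed = 12)
  expect_true(all(diff(sel$criteria$gev) > -1e-6))
})

test_that("back-fitting labels frames by spatial correlation", {
  set.seed(13)
  tpl <- orthogonal_templates(40, 5)
  mod <- structure(list(maps = tpl, k = 5, polarity = "sensitive",
                        channel_labels = paste0("E", 1:40), sfreq = 250),
                   class = "microstate_model")
  # evoked equal to template 3 across the window
  ev <- toy_evoked(matrix(tpl[, 3] * 2, 40, 238))
  lab <- microstate_backfit(mod, ev, window = c(295, 480))
  expect_equal(length(lab), 46)
  expect_true(all(lab == 3))
  dur <- state_durations(lab, 5, 250)
  expect_equal(unname(dur["map3"]), 184)
  expect_equal(sum(dur), 184)

  # zero evoked: all frames unlabeled
  lab0 <- microstate_backfit(mod, toy_evoked(matrix(0, 40, 238)))
  expect_true(all(lab0 == 0))
  expect_equal(unname(state_durations(lab0, 5, 250)["unlabeled"]), 184)
})

test_that("durations conserve the analysis window exactly", {
  lab <- rep(c(1L, 2L), 23)
  dur <- state_durations(lab, 3, 250)
  expect_equal(unname(dur[c("map1", "map2")]), c(92, 92))
  expect_equal(sum(dur), 184)
  set.seed(14)
  for (i in 1:20) {
    lab <- sample(0:4, 46, replace = TRUE)
    expect_equal(sum(state_durations(lab, 4, 250)), 46 * 4)
  }
})

test_that("predict/coef/print methods expose the fitted model", {
  set.seed(15)
  tpl <- orthogonal_templates(32, 3)
  tc <- toy_cells(tpl)
  mod <- microstate_segment(tc$cells, k = 3, n_restarts = 5, seed = 16)
  expect_identical(coef(mod), mod$maps)
  expect_output(print(mod), "microstate_model")
  expect_output(summary(mod), "Global explained variance")
  ev <- toy_evoked(tpl[, c(rep(1, 100), rep(2, 138))] * 2)
  lab <- predict(mod, ev, window = c(0, 400))
  expect_equal(length(lab), 100)
})

test_that("duration statistics: Kruskal-Wallis with gatekept Mann-Whitney", {
  durs <- data.frame(
    subject = rep(sprintf("S%02d", 1:9), times = 2),
    group = rep(rep(c("N", "A", "E"), each = 3), times = 2),
    condition = "R",
    map = rep(c("map1", "map2"), each = 9),
    duration_ms = c(1, 2, 3, 4, 5, 6, 7, 8, 9,    # map1: separated groups
                    rep(10, 9)))                   # map2: all tied
  tab <- duration_tests(durs)
  kw1 <- tab[tab$label == "map1/R KW", ]
  expect_equal(kw1$value, 7.2, tolerance = 1e-10)  # brute-force rank H
  kw2 <- tab[tab$label == "map2/R KW", ]
  expect_equal(kw2$value, 0)
  expect_equal(kw2$p, 1)
  # gatekeeping: no post-hocs for map2
  expect_false(any(grepl("map2/R .* vs", tab$label)))
  # Mann-Whitney on {1,2,3} vs {4,5,6}: U = 0; exact one-sided p = 1/20
  mw <- tab[grepl("map1/R A vs E", tab$label), ]
  expect_equal(mw$value, 0)
  expect_equal(suppressWarnings(
    wilcox.test(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p.value),
    1 / choose(6, 3), tolerance = 1e-12)
})
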