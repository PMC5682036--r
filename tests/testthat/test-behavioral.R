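# Behavioural scoring, d-prime and its ANOVA/contrasts.

fixed_trials <- function(per_cond) {
  # one subject; per_cond: named list condition -> vector of responses
  do.call(rbind, lapply(names(per_cond), function(cn)
    data.frame(subject = "S01", group = "G", condition = cn,
               response = per_cond[[cn]], stringsAsFactors = FALSE)))
}

test_that("scoring counts hits and false alarms with R as the noise class", {
  tr <- fixed_trials(list(R = rep("YES", 10),
                          Tsub = rep("YES", 10),
                          Tapp = rep("YES", 10)))
  sc <- score_responses(tr)
  expect_equal(sc$percent_correct[sc$condition == "R"], 100)
  expect_equal(sc$percent_correct[sc$condition == "Tsub"], 0)

  tr2 <- fixed_trials(list(R = rep("NO", 10), Tsub = rep("NO", 10),
                           Tapp = rep("NO", 10)))
  sc2 <- score_responses(tr2)
  expect_equal(sc2$percent_correct[sc2$condition == "R"], 0)
  expect_equal(sc2$percent_correct[sc2$condition == "Tapp"], 100)

  # coin-flip responses: percent correct near 50 (binomial oracle: +/-11
  # covers ~2 SD at 90 trials)
  set.seed(1)
  tr3 <- fixed_trials(list(R = sample(c("YES", "NO"), 90, TRUE),
                           Tsub = sample(c("YES", "NO"), 90, TRUE),
                           Tapp = sample(c("YES", "NO"), 90, TRUE)))
  sc3 <- score_responses(tr3)
  expect_true(all(abs(sc3$percent_correct - 50) < 11))

  expect_error(score_responses(data.frame(subject = 1, group = 1,
                                          condition = 1, response = "maybe")),
               "YES or NO")
})

test_that("d-prime follows the quantile formula with 1/(2N) edge correction", {
  expect_equal(dprime(50, 100, 50, 100), 0)
  expect_equal(dprime(90, 100, 10, 100), qnorm(0.9) - qnorm(0.1),
               tolerance = 1e-12)
  expect_equal(dprime(90, 100, 10, 100), 2.5631, tolerance = 1e-4)
  # H < FA gives a negative value
  expect_lt(dprime(20, 100, 40, 100), 0)
  # edge correction engages only at rates 0 and 1
  expect_equal(dprime(100, 100, 0, 100),
               qnorm(1 - 1 / 200) - qnorm(1 / 200))
  expect_equal(dprime(89, 90, 1, 90), qnorm(89 / 90) - qnorm(1 / 90))
  expect_error(dprime(1, 0, 1, 10), "positive")
})

test_that("d-prime is monotone in hits and antitone in false alarms", {
  n <- 40
  for (fa in c(0, 7, 20)) {
    d <- sapply(0:n, function(h) dprime(h, n, fa, n))
    expect_true(all(diff(d) > 0))
  }
  for (h in c(5, 25, 40)) {
    d <- sapply(0:n, function(fa) dprime(h, n, fa, n))
    expect_true(all(diff(d) < 0))
  }
})

test_that("the d-prime ANOVA matches aov and flags zero-effect data", {
  scores <- data.frame(
    subject = rep(sprintf("S%02d", 1:6), 2),
    group = rep(rep(c("a", "b", "c"), each = 2), 2),
    condition = rep(c("Tsub", "Tapp"), each = 6),
    dprime = c(1.2, 1.4, 2.0, 2.3, 3.1, 3.0, 2.2, 2.6, 3.4, 3.3, 4.4, 4.1))
  got <- dprime_anova(scores)
  df <- data.frame(y = scores$dprime, s = factor(scores$subject),
                   g = factor(scores$group), c = factor(scores$condition))
  fit <- summary(aov(y ~ g * c + Error(s / c), data = df))
  bet <- fit[["Error: s"]][[1]]; wit <- fit[["Error: s:c"]][[1]]
  expect_equal(got$value, c(bet["g", "F value"], wit["c", "F value"],
                            wit["g:c", "F value"]), tolerance = 1e-8)

  flat <- scores; flat$dprime <- 2
  gotf <- dprime_anova(flat)
  expect_equal(gotf$value, c(0, 0, 0))
})

test_that("study-scale simulated behaviour yields both main effects reliably", {
  hits <- 0
  for (s in 1:20) {
    tr <- simulate_behavior(seed = 1000 + s)
    sc <- score_responses(tr)
    an <- dprime_anova(sc)
    if (all(an$p[1:2] < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("behaviour round trip recovers the target ordering and levels", {
  tr <- simulate_behavior(seed = 42)
  sc <- score_responses(tr)
  agg <- aggregate(dprime ~ group + condition, sc, mean)
  tgt <- default_dprime()
  for (g in names(tgt)) for (cn in names(tgt[[g]])) {
    got <- agg$dprime[agg$group == g & agg$condition == cn]
    expect_lt(abs(got - tgt[[g]][[cn]]), 0.15)
  }
  # ordering: Experts > Amateurs > Non-musicians; Tapp > Tsub off-ceiling
  d <- function(g, cn) agg$dprime[agg$group == g & agg$condition == cn]
  expect_true(d("Expert", "Tsub") > d("Amateur", "Tsub"))
  expect_true(d("Amateur", "Tsub") > d("Nonmusician", "Tsub"))
  expect_true(d("Expert", "Tapp") > d("Amateur", "Tapp"))
  expect_true(d("Amateur", "Tapp") > d("Nonmusician", "Tapp"))
  expect_true(d("Nonmusician", "Tapp") > d("Nonmusician", "Tsub"))
  expect_true(d("Amateur", "Tapp") > d("Amateur", "Tsub"))
})

test_that("contrasts are Bonferroni-corrected and handle degenerate variance", {
  scores <- data.frame(
    subject = rep(sprintf("S%02d", 1:9), 2),
    group = rep(rep(c("a", "b", "c"), each = 3), 2),
    condition = rep(c("Tsub", "Tapp"), each = 9),
    dprime = rep(c(1, 1.5, 2), 6))
  # identical groups: all corrected p = 1
  tab <- suppressWarnings(group_contrasts(scores))
  expect_true(all(tab$p[grepl(" vs ", tab$label) & !grepl("paired", tab$label)] == 1))

  # paired contrast with constant difference exercises the degenerate branch
  sc2 <- scores
  sc2$dprime[sc2$condition == "Tapp"] <- sc2$dprime[sc2$condition == "Tapp"] + 1
  w <- capture_warnings(tab2 <- group_contrasts(sc2))
  expect_gt(length(w), 0)
  expect_true(all(grepl("paired", w)))
  paired_rows <- tab2[grepl("paired", tab2$label), ]
  expect_true(all(paired_rows$p == 1))

  # independent t against the brute-force formula
  sc3 <- data.frame(
    subject = rep(sprintf("S%02d", 1:6), 2),
    group = rep(rep(c("a", "b"), each = 3), 2),
    condition = rep(c("Tsub", "Tapp"), each = 6),
    dprime = c(1, 2, 3, 5, 6, 9, 2, 3, 4, 6, 7, 10))
  tab3 <- suppressWarnings(group_contrasts(sc3))
  x <- c(1, 2, 3); y <- c(5, 6, 9)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (2 / 3))
  row <- tab3[tab3$label == "Tsub: a vs b", ]
  expect_equal(row$value, tt, tolerance = 1e-10)
})
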