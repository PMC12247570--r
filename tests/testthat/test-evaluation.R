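test_that("classification uses a strict larger-than rule", {
  expect_equal(classify_regions(c(-1.5, -3.4), -2), c("EZ_PZ", "NIZ"))
  expect_equal(classify_regions(-2, -2), "NIZ")   # exactly at threshold
  expect_true(all(classify_regions(c(-4, -2, -1), -10) == "EZ_PZ"))
})

test_that("sweep reproduces the worked examples", {
  # perfectly separated medians
  rep1 <- sweep_threshold(c(-1.5, -1.8, -3.5, -3.6, -3.6), c(1, 2))
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$f1, 1)

  # single positive region separated from the rest
  rep2 <- sweep_threshold(c(-1.5, -1.8, -3.5, -3.6, -3.6), 1)
  expect_equal(rep2$precision, 1)
  expect_equal(rep2$recall, 1)
  expect_gt(rep2$threshold, -1.8)
  expect_lte(rep2$threshold, -1.5)

  # second true region sunk below every NIZ: precision maximization
  # sacrifices it
  rep3 <- sweep_threshold(c(-1.5, -3.8, -3.5, -3.6, -3.7), c(1, 2))
  expect_equal(rep3$precision, 1)
  expect_equal(rep3$recall, 0.5)
  expect_equal(rep3$f1, 2 / 3)
})

test_that("sweep equals the exhaustive-threshold oracle on random cases", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    medians <- runif(n, -4.8, -1.2)
    truth <- seq_len(n) %in% sample.int(n, sample(1:3, 1))
    a <- sweep_threshold(medians, truth)
    b <- brute_force_sweep(medians, truth)
    expect_equal(a$threshold, b$threshold)
    expect_equal(a$precision, b$precision)
    expect_equal(a$recall, b$recall)
  }
})

test_that("F1 is the harmonic mean and counts add up", {
  set.seed(4)
  medians <- runif(12, -4.5, -1.5)
  truth <- seq_len(12) %in% c(2, 5)
  rep <- sweep_threshold(medians, truth)
  expect_equal(rep$tp + rep$fp + rep$fn + rep$tn, 12)
  expect_equal(rep$f1,
               2 * rep$precision * rep$recall / (rep$precision + rep$recall),
               tolerance = 1e-12)
  expect_gte(rep$f1, min(rep$precision, rep$recall) - 1e-12)
  expect_lte(rep$f1, max(rep$precision, rep$recall) + 1e-12)
})

test_that("group statistics behave on degenerate and shifted samples", {
  # identical distributions across conditions: no group effect
  vals <- rep(c(0.2, 0.4, 0.6, 0.8, 1.0), 4)
  reports <- data.frame(
    config_id = rep(sprintf("c%02d", 1:5), 4),
    config_type = "ez_single",
    condition = rep(c("lc_none", "lc_0", "lc_2", "lc_4"), each = 5),
    gof = vals, precision = vals, recall = vals, f1 = vals)
  gs <- group_stats(reports)
  expect_gt(gs$ez_single$kruskal_p[["gof"]], 0.9)

  # constant positive shift of 0.3 with n = 20 pairs: strongly significant
  set.seed(8)
  base <- runif(20, 0.2, 0.6)
  reports2 <- data.frame(
    config_id = rep(sprintf("c%02d", 1:20), 2),
    config_type = "ez_single",
    condition = rep(c("lc_none", "lc_0"), each = 20),
    gof = c(base + 0.3, base), precision = c(base + 0.3, base),
    recall = c(base + 0.3, base), f1 = c(base + 0.3, base))
  gs2 <- group_stats(reports2)
  expect_lt(gs2$ez_single$wilcoxon_p["lc_0", "gof"], 0.01)

  # medians per cell match the middle order statistic
  expect_equal(gs2$ez_single$medians["lc_none", "gof"], median(base + 0.3))
})

test_that("gain-similarity analysis bins means and ranks the trend", {
  rec <- data.frame(r = c(0.05, 0.12, 0.18, 0.35, 0.55, 0.58),
                    gof = c(0.1, 0.2, 0.25, 0.4, 0.6, 0.62))
  rec$precision <- rec$gof; rec$recall <- rec$gof; rec$f1 <- rec$gof
  out <- correlation_analysis(rec)
  expect_equal(out$spearman[["f1"]], 1)
  b <- out$bins
  at <- function(m) b$gof[which.min(abs(b$mid - m))]
  expect_equal(at(0.15), mean(c(0.2, 0.25)))
  expect_equal(at(0.55), mean(c(0.6, 0.62)))
  expect_true(is.na(at(0.95)))   # empty bins carried as missing

  # constant metric: zero rank correlation by convention
  rec2 <- rec
  rec2$f1 <- 0.5
  expect_equal(correlation_analysis(rec2)$spearman[["f1"]], 0)
})
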