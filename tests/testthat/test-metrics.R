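test_that("agreement, Type I and power follow their definitions", {
  expect_equal(accuracy(c(1, 0, 1, 0), c(1, 1, 1, 1)), 0.5)
  expect_equal(accuracy(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_error(accuracy(c(1, 0), c(1, 0, 1)), "equal length")
  expect_error(accuracy(c(1, 2), c(1, 0)), "only 0 and 1")

  expect_equal(type1_rate(c(1, 0, 1, 0), c(0, 0, 0, 0)), 0.5)
  expect_equal(type1_rate(rep(0, 6), rep(0, 6)), 0)
  expect_equal(type1_rate(rep(1, 6), rep(0, 6)), 1)
  expect_error(type1_rate(c(1, 0), c(1, 1)), "undefined")

  expect_equal(power_rate(c(1, 1, 0, 0), c(1, 1, 1, 1)), 0.5)
  expect_equal(power_rate(c(1, 0), c(1, 0)), 1)
  expect_equal(power_rate(c(0, 1), c(1, 0)), 0)
  expect_error(power_rate(c(1, 0), c(0, 0)), "undefined")
})

test_that("accuracy decomposes into power and Type I exactly", {
  set.seed(61)
  for (i in 1:1000) {
    n <- sample(4:40, 1)
    truth <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))  # both classes
    pred <- sample(0:1, n, replace = TRUE)
    n_pos <- sum(truth == 1L)
    n_neg <- n - n_pos
    expect_equal(accuracy(pred, truth),
                 (power_rate(pred, truth) * n_pos +
                  (1 - type1_rate(pred, truth)) * n_neg) / n)
    # brute-force recount oracle
    expect_equal(accuracy(pred, truth), sum(pred == truth) / n)
    expect_equal(type1_rate(pred, truth),
                 sum(pred == 1 & truth == 0) / sum(truth == 0))
    expect_equal(power_rate(pred, truth),
                 sum(pred == 1 & truth == 1) / sum(truth == 1))
  }
})

test_that("agreement matrix is symmetric with unit diagonal", {
  a <- c(1, 0, 1, 0)
  b <- c(0, 1, 0, 1)
  m <- agreement_matrix(list(a = a, b = b), truth = a)
  expect_identical(dim(m), c(3L, 3L))
  expect_identical(rownames(m), c("True", "a", "b"))
  expect_equal(diag(m), c(True = 1, a = 1, b = 1))
  expect_equal(m["a", "b"], 0)  # complementary vectors
  expect_equal(m["True", "a"], 1)
  expect_equal(m, t(m))
})

test_that("Wald interval reproduces its closed form", {
  ci <- binomial_ci(0.8, 300)
  expect_equal(unname(diff(ci)) / 2, 0.045263, tolerance = 1e-5)
  expect_equal(round(unname(diff(ci)) / 2, 2), 0.05)
  ci2 <- binomial_ci(0.5, 100)
  expect_equal(unname(ci2), 0.5 + c(-1, 1) * 0.097998, tolerance = 1e-5)
  # degenerate proportions collapse to a point before clipping
  expect_equal(unname(binomial_ci(0, 50)), c(0, 0))
  expect_equal(unname(binomial_ci(1, 50)), c(1, 1))
  # clipping keeps the interval inside [0, 1]
  expect_equal(binomial_ci(0.02, 10)[["low"]], 0)
})

test_that("point-versus-interval significance rule", {
  expect_false(significance_flag(0.5, 512, 0.5, 512))
  expect_true(significance_flag(0.9, 512, 0.5, 512))   # 0.9 outside 0.5 +/- 0.043
  expect_false(significance_flag(0.52, 512, 0.5, 512))
  # the rule is asymmetric: orientation can matter
  expect_true(significance_flag(0.55, 100, 0.5, 10000))
  expect_false(significance_flag(0.5, 10000, 0.55, 100))
})

test_that("stratified metrics equal a brute-force filtered recount", {
  man <- ab_training_set(15, total = 640)
  truth <- manifest_truth(man)
  set.seed(62)
  pred <- as.integer(runif(640) < 0.3 + 0.4 * truth)
  for (ch in c("n_a", "n_b", "autocorr", "trend", "variability")) {
    col <- switch(ch, trend = "trend_deg", variability = "var_level", ch)
    tab <- stratify_metrics(pred, truth, man, ch, method = "m")
    for (lv in unique(man$spec[[col]])) {
      in_lv <- man$spec[[col]] == lv
      sub <- tab[tab$stratum_level == as.character(lv), ]
      expect_equal(sub$estimate[sub$metric == "accuracy"],
                   accuracy(pred[in_lv], truth[in_lv]))
      expect_equal(sub$estimate[sub$metric == "type1"],
                   type1_rate(pred[in_lv], truth[in_lv]))
      expect_equal(sub$estimate[sub$metric == "power"],
                   power_rate(pred[in_lv], truth[in_lv]))
    }
  }
  expect_error(stratify_metrics(pred, truth, man, "colour"), "characteristic")
})

test_that("SMD stratification gives Type I at 0 and power at 1..5", {
  man <- ab_training_set(16, total = 640)
  truth <- manifest_truth(man)
  set.seed(63)
  pred <- as.integer(runif(640) < 0.5)
  tab <- stratify_metrics(pred, truth, man, "smd", method = "m")
  expect_identical(tab$metric, c("type1", rep("power", 5)))
  expect_identical(tab$stratum_level, as.character(0:5))
  expect_identical(tab$n, c(320L, rep(64L, 5)))
  # per-level confusion counts add up to the overall counts
  hits <- sum(tab$estimate * tab$n)
  expect_equal(hits, sum(pred == 1))
})

test_that("metrics_report bundles overall and stratified sections", {
  man <- ab_training_set(17, total = 320)
  truth <- manifest_truth(man)
  pred <- cdc_batch(man)
  rep <- metrics_report(pred, truth, manifest = man, method = "cdc")
  expect_s3_class(rep, "metrics_report")
  ov <- rep$overall
  expect_equal(ov$estimate[ov$metric == "accuracy"], accuracy(pred, truth))
  expect_true(all(ov$ci_low <= ov$estimate & ov$estimate <= ov$ci_high))
  expect_identical(unique(rep$strata$stratum_variable),
                   c("n_a", "n_b", "autocorr", "trend", "variability", "smd"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, path)
  back <- read.csv(path)
  expect_identical(nrow(back), nrow(ov) + nrow(rep$strata))
})
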