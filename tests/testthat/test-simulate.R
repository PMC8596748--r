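test_that("AR(1) recurrence matches a hand evaluation", {
  # x1 = e1, x_t = 0.2 x_{t-1} + e_t with e = (1,1,1): raw series 1, 1.2, 1.24
  g <- fixed_graph(1, 2, errors = c(1, 1, 1), autocorr = 0.2)
  expect_equal(g$values, c(1, 1.2, 1.24) + 10)
})

test_that("zero-noise construction reduces to offset plus effect", {
  g <- zero_noise_graph(3, 5, smd = 0)
  expect_equal(g$values, rep(10, 8))
  expect_identical(g$label, 0L)

  g3 <- zero_noise_graph(3, 5, smd = 3)
  expect_equal(g3$values, c(rep(10, 3), rep(13, 5)))
  expect_identical(g3$label, 1L)

  gv <- zero_noise_graph(3, 5, var_level = "variable")
  expect_equal(gv$values, rep(4, 8))
})

test_that("trend shear matches tan(30 deg) about the midpoint", {
  out <- apply_trend(rep(0, 5), 30)
  expect_equal(out, tan(pi / 6) * (-2:2), tolerance = 1e-12)
  expect_equal(out, c(-1.1547005, -0.5773503, 0, 0.5773503, 1.1547005),
               tolerance = 1e-6)
  # per-session increment is 0.58 to 2 d.p., the pivot value is unchanged
  expect_equal(round(unique(round(diff(out), 10)), 2), 0.58)
  expect_equal(out[3], 0)
  # even length: interpolated midpoint, constant increment everywhere
  out6 <- apply_trend(rep(0, 6), 30)
  expect_equal(diff(out6), rep(tan(pi / 6), 5), tolerance = 1e-12)
  expect_equal(sum(out6), 0, tolerance = 1e-12)
  # identity at 0 degrees
  x <- rnorm(7)
  expect_identical(apply_trend(x, 0), x)
})

test_that("offset and effect operations follow their definitions", {
  expect_equal(apply_offset(rep(0, 4), "stable"), rep(10, 4))
  expect_equal(apply_offset(rep(0, 4), "variable"), rep(4, 4))
  expect_error(apply_offset(rep(0, 4), "wobbly"), "stable")

  expect_equal(apply_effect(rep(0, 8), 3, 2), c(0, 0, 0, rep(2, 5)))
  x <- rnorm(8)
  expect_identical(apply_effect(x, 3, 0), x)
  expect_error(apply_effect(rep(0, 8), 8, 1), "n_a")
  expect_error(graph_spec(0, 5), "positive")
  expect_error(graph_spec(3, -1), "positive")
})

test_that("test-set manifest has the exact counterbalanced composition", {
  man <- ab_test_set(7)
  s <- man$spec
  expect_identical(nrow(s), 1024L)
  expect_identical(sum(s$smd == 0), 384L)
  expect_true(all(table(s$smd[s$smd > 0]) == 128L))
  expect_true(all(table(s$n_a) == 512L))
  expect_true(all(table(s$n_b) == 512L))
  expect_true(all(table(s$autocorr) == 512L))
  expect_true(all(table(s$trend_deg) == 512L))
  expect_true(all(table(s$var_level) == 512L))
  expect_identical(manifest_truth(man), as.integer(s$smd > 0))
  expect_true(all(lengths(man$values) == s$n_a + s$n_b))
  # each combination holds 12 no-effect and 4-per-SMD effect graphs
  combo <- interaction(s$n_a, s$n_b, s$autocorr, s$trend_deg, s$var_level)
  expect_true(all(table(combo[s$smd == 0]) == 12L))
  expect_true(all(table(combo[s$smd == 3]) == 4L))
})

test_that("training manifest is counterbalanced at any valid size", {
  man <- ab_training_set(3, total = 320)
  s <- man$spec
  expect_identical(nrow(s), 320L)
  expect_identical(sum(s$smd == 0), 160L)
  expect_true(all(table(s$smd[s$smd > 0]) == 32L))
  cells <- manifest_cells(man)
  expect_true(all(table(droplevels(cells[s$smd == 0])) == 5L))
  expect_true(all(table(droplevels(cells[s$smd > 0])) == 1L))
  expect_error(ab_training_set(1, total = 500), "multiple of 320")
  expect_error(ab_training_set(1, total = 500), "640")
})

test_that("regeneration from the same seed is bit-identical", {
  a <- ab_test_set(11)
  b <- ab_test_set(11)
  expect_identical(a, b)
  c <- ab_test_set(12)
  expect_false(identical(a$spec$graph_id, c$spec$graph_id) &&
               identical(a$values, c$values))
})

test_that("plain noise coverage matches the normal 68/95 rule", {
  set.seed(5)
  man <- ab_training_set(5, total = 6720)  # 21 graphs/combination, >= 65k pts
  keep <- man$spec$autocorr == 0 & man$spec$trend_deg == 0 &
    man$spec$smd == 0 & man$spec$var_level == "stable"
  pts <- unlist(man$values[keep])
  # top up to >= 1e5 points with more no-effect stable graphs
  need <- ceiling((1e5 - length(pts)) / 15)
  more <- unlist(lapply(seq_len(max(need, 0)), function(i) {
    generate_series(graph_spec(5, 10))$values
  }))
  pts <- c(pts, more)
  expect_gte(length(pts), 1e5)
  dev <- pts - mean(pts)
  expect_equal(mean(abs(dev) <= 1), 0.6827, tolerance = 0.01)
  expect_equal(mean(abs(dev) <= 2), 0.9545, tolerance = 0.01)
})
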