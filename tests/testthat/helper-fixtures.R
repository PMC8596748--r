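# Shared fixture builders. Everything is generated in code; no stored data.

# a graph built from explicit innovations, for hand-checkable cases
fixed_graph <- function(n_a, n_b, errors, autocorr = 0, trend_deg = 0,
                        var_level = "stable", smd = 0) {
  generate_series(
    graph_spec(n_a, n_b, autocorr = autocorr, trend_deg = trend_deg,
               var_level = var_level, smd = smd),
    errors = errors)
}

# zero-noise graph: all innovations 0 (constant offset, optional step)
zero_noise_graph <- function(n_a = 3, n_b = 5, smd = 0, ...) {
  fixed_graph(n_a, n_b, errors = rep(0, n_a + n_b), smd = smd, ...)
}

# tiny alternating perturbation so a flat graph is still standardizable
ripple_graph <- function(n_a = 3, n_b = 5, smd = 0, eps = 0.01) {
  fixed_graph(n_a, n_b, errors = eps * rep_len(c(1, -1), n_a + n_b),
              smd = smd)
}

# random graph drawn from the study grid
random_grid_graph <- function() {
  spec <- graph_spec(sample(c(3, 5), 1), sample(c(5, 10), 1),
                     autocorr = sample(c(0, 0.2), 1),
                     trend_deg = sample(c(0, 30), 1),
                     var_level = sample(c("stable", "variable"), 1),
                     smd = sample(0:5, 1))
  generate_series(spec)
}

# independent naive CDC recount: refits the lines with lm() and counts by
# an explicit loop; used only as an oracle against cdc_classify()
naive_cdc_count <- function(values, n_a) {
  a <- values[seq_len(n_a)]
  b <- values[(n_a + 1):length(values)]
  idx_a <- seq_len(n_a) - 1
  raise <- 0.25 * sd(a)
  fit <- lm(a ~ idx_a)
  count <- 0L
  for (j in seq_along(b)) {
    i <- n_a + j - 1
    trend_val <- unname(coef(fit)[1] + coef(fit)[2] * i) + raise
    mean_val <- mean(a) + raise
    if (b[j] > trend_val && b[j] > mean_val) count <- count + 1L
  }
  count
}
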