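# Simulation of single-case AB graphs.
#
# A graph is built in four steps: an AR(1) series with standard-normal
# innovations, an optional 30-degree trend shear, an additive level constant
# controlling the variability coefficient, and a standardized mean difference
# added to every Phase B point.

#' Specification of one simulated AB graph
#'
#' Bundles the six manipulated characteristics of a single AB graph. The
#' constructor accepts any positive phase lengths and any non-negative effect
#' size; the canonical dataset builders ([ab_test_set()], [ab_training_set()])
#' restrict themselves to the study grid (3/5 Phase A points, 5/10 Phase B
#' points, autocorrelation 0/0.2, trend 0/30 degrees, SMD 0-5).
#'
#' @param n_a Number of Phase A (baseline) sessions.
#' @param n_b Number of Phase B (treatment) sessions.
#' @param autocorr First-order autocorrelation coefficient of the error
#'   series.
#' @param trend_deg Trend manipulation in degrees; 0 means no trend.
#' @param var_level `"stable"` (additive constant 10, variability coefficient
#'   0.1) or `"variable"` (additive constant 4, variability coefficient 0.25).
#' @param smd Standardized mean difference added to every Phase B point; 0
#'   means no true effect.
#' @return An object of class `graph_spec`.
#' @examples
#' graph_spec(3, 5, autocorr = 0.2, trend_deg = 30, var_level = "variable",
#'            smd = 2)
#' @export
graph_spec <- function(n_a, n_b, autocorr = 0, trend_deg = 0,
                       var_level = "stable", smd = 0) {
  if (length(n_a) != 1L || length(n_b) != 1L ||
      !is.finite(n_a) || !is.finite(n_b) ||
      n_a < 1 || n_b < 1 || n_a != round(n_a) || n_b != round(n_b)) {
    stop("phase lengths `n_a` and `n_b` must be positive integers",
         call. = FALSE)
  }
  if (!is.numeric(autocorr) || length(autocorr) != 1L || !is.finite(autocorr)) {
    stop("`autocorr` must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(trend_deg) || length(trend_deg) != 1L || trend_deg < 0) {
    stop("`trend_deg` must be a single non-negative number", call. = FALSE)
  }
  var_level <- match.arg(var_level, c("stable", "variable"))
  if (!is.numeric(smd) || length(smd) != 1L || smd < 0) {
    stop("`smd` must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(n_a = as.integer(n_a), n_b = as.integer(n_b), autocorr = autocorr,
         trend_deg = trend_deg, var_level = var_level, smd = smd),
    class = "graph_spec"
  )
}

#' @export
print.graph_spec <- function(x, ...) {
  cat(sprintf(
    "<graph_spec> A:%d B:%d a=%.1f trend=%gdeg %s SMD=%g\n",
    x$n_a, x$n_b, x$autocorr, x$trend_deg, x$var_level, x$smd))
  invisible(x)
}

#' Construct an AB graph object
#'
#' @param values Numeric vector of session measurements, Phase A first.
#' @param spec The [graph_spec()] that produced (or describes) the series.
#' @return An object of class `ab_graph` with fields `values`, `n_a`, `spec`
#'   and `label` (1 if `spec$smd > 0`, else 0).
#' @export
ab_graph <- function(values, spec) {
  stopifnot(inherits(spec, "graph_spec"))
  if (length(values) != spec$n_a + spec$n_b) {
    stop("length(values) must equal n_a + n_b", call. = FALSE)
  }
  structure(
    list(values = as.numeric(values), n_a = spec$n_a, spec = spec,
         label = as.integer(spec$smd > 0)),
    class = "ab_graph"
  )
}

#' @export
print.ab_graph <- function(x, ...) {
  cat(sprintf("<ab_graph> %d sessions (A:%d B:%d), label %d\n",
              length(x$values), x$n_a, x$spec$n_b, x$label))
  print(round(x$values, 3))
  invisible(x)
}

#' Apply a trend shear to a series
#'
#' Adds `tan(degrees) * (i - m)` to the i-th point (0-based index), where
#' `m = (length - 1) / 2` is the series midpoint. For a 30-degree trend this
#' adds or subtracts about 0.58 per session, pivoting on the middle of the
#' series; the midpoint value itself is unchanged (interpolated midpoint for
#' even lengths).
#'
#' @param values Numeric series (length at least 2).
#' @param degrees Trend angle in degrees; 0 returns the input unchanged.
#' @return The sheared series.
#' @export
apply_trend <- function(values, degrees) {
  if (!is.numeric(degrees) || length(degrees) != 1L || degrees < 0) {
    stop("`degrees` must be a single non-negative number", call. = FALSE)
  }
  if (degrees == 0) return(values)
  if (length(values) < 2L) stop("series must have at least 2 points",
                                call. = FALSE)
  idx <- seq_along(values) - 1
  m <- (length(values) - 1) / 2
  values + tan(degrees * pi / 180) * (idx - m)
}

#' Shift a series to its variability level
#'
#' Adds the level constant that fixes the variability coefficient of a
#' unit-SD series: +10 for `"stable"` graphs (coefficient 0.1) and +4 for
#' `"variable"` graphs (coefficient 0.25).
#'
#' @param values Numeric series.
#' @param var_level `"stable"` or `"variable"`.
#' @return The shifted series.
#' @export
apply_offset <- function(values, var_level) {
  offsets <- c(stable = 10, variable = 4)
  if (length(var_level) != 1L || !var_level %in% names(offsets)) {
    stop("`var_level` must be \"stable\" or \"variable\"", call. = FALSE)
  }
  values + offsets[[var_level]]
}

#' Add a treatment effect to Phase B
#'
#' Adds `smd` (a standardized mean difference, in baseline-SD units since the
#' innovation SD is 1) to every point at 0-based index `>= n_a`; Phase A is
#' untouched.
#'
#' @param values Numeric series.
#' @param n_a Number of Phase A sessions.
#' @param smd Effect size to add to Phase B.
#' @return The series with the effect applied.
#' @export
apply_effect <- function(values, n_a, smd) {
  if (length(n_a) != 1L || n_a < 1 || n_a >= length(values)) {
    stop("`n_a` must satisfy 0 < n_a < length(values)", call. = FALSE)
  }
  if (smd != 0) {
    b <- (n_a + 1):length(values)
    values[b] <- values[b] + smd
  }
  values
}

#' Simulate one AB graph
#'
#' Builds the series in the canonical order: (1) AR(1) recurrence
#' `x[t] = a * x[t-1] + e[t]` with `e[t] ~ N(0, 1)` and `x[1] = e[1]`;
#' (2) trend shear ([apply_trend()]); (3) level constant ([apply_offset()]);
#' (4) Phase B effect ([apply_effect()]).
#'
#' @param spec A [graph_spec()].
#' @param errors Optional numeric vector of innovations (length
#'   `n_a + n_b`); when `NULL` they are drawn from the current RNG stream.
#'   Supplying them makes the generator deterministic, which the test suite
#'   uses for hand-checked cases.
#' @return An [ab_graph()].
#' @examples
#' set.seed(1)
#' g <- generate_series(graph_spec(3, 5, smd = 3))
#' g$values
#' @export
generate_series <- function(spec, errors = NULL) {
  stopifnot(inherits(spec, "graph_spec"))
  len <- spec$n_a + spec$n_b
  if (is.null(errors)) {
    errors <- rnorm(len)
  } else if (length(errors) != len) {
    stop("`errors` must have length n_a + n_b", call. = FALSE)
  }
  x <- numeric(len)
  x[1] <- errors[1]
  if (len > 1L) {
    for (t in 2:len) x[t] <- spec$autocorr * x[t - 1] + errors[t]
  }
  if (spec$trend_deg > 0) x <- apply_trend(x, spec$trend_deg)
  x <- apply_offset(x, spec$var_level)
  x <- apply_effect(x, spec$n_a, spec$smd)
  ab_graph(x, spec)
}

# the 2^5 grid of binary characteristics, in a fixed canonical order
characteristic_grid <- function() {
  expand.grid(n_a = c(3L, 5L), n_b = c(5L, 10L), autocorr = c(0, 0.2),
              trend_deg = c(0, 30), var_level = c("stable", "variable"),
              stringsAsFactors = FALSE)
}

new_manifest <- function(spec_df, values, seed, scheme) {
  spec_df$graph_id <- seq_len(nrow(spec_df))
  spec_df$label <- as.integer(spec_df$smd > 0)
  cols <- c("graph_id", "n_a", "n_b", "autocorr", "trend_deg", "var_level",
            "smd", "label")
  rownames(spec_df) <- NULL
  structure(
    list(spec = spec_df[, cols], values = values, seed = as.integer(seed),
         scheme = scheme),
    class = "ab_manifest"
  )
}

#' @export
print.ab_manifest <- function(x, ...) {
  cat(sprintf("<ab_manifest> %d graphs, scheme \"%s\", seed %d\n",
              nrow(x$spec), x$scheme, x$seed))
  cat(sprintf("  no effect: %d; with effect: %d\n",
              sum(x$spec$smd == 0), sum(x$spec$smd > 0)))
  invisible(x)
}

#' @export
length.ab_manifest <- function(x) nrow(x$spec)

#' @export
as.data.frame.ab_manifest <- function(x, ...) x$spec

#' Extract one graph from a manifest
#'
#' @param manifest An `ab_manifest`.
#' @param i Graph position (manifest order).
#' @return The i-th [ab_graph()].
#' @export
manifest_graph <- function(manifest, i) {
  stopifnot(inherits(manifest, "ab_manifest"))
  s <- manifest$spec[i, ]
  ab_graph(manifest$values[[i]],
           graph_spec(s$n_a, s$n_b, s$autocorr, s$trend_deg, s$var_level,
                      s$smd))
}

#' True labels of a manifest
#'
#' @param manifest An `ab_manifest`.
#' @return Integer 0/1 vector in manifest order (1 = true effect present).
#' @export
manifest_truth <- function(manifest) {
  stopifnot(inherits(manifest, "ab_manifest"))
  manifest$spec$label
}

simulate_rows <- function(spec_df) {
  lapply(seq_len(nrow(spec_df)), function(i) {
    s <- spec_df[i, ]
    generate_series(graph_spec(s$n_a, s$n_b, s$autocorr, s$trend_deg,
                               s$var_level, s$smd))$values
  })
}

#' Generate the counterbalanced 1,024-graph test set
#'
#' For each of the 32 combinations of the five binary characteristics the set
#' holds 12 no-effect graphs (SMD 0) and 4 graphs at each SMD 1-5, giving
#' 1,024 graphs: 384 without effect, 128 per positive SMD, and 512 at each
#' level of every binary characteristic. Graphs are shuffled into a random
#' presentation order driven by `seed`, which also drives the series noise;
#' the same seed regenerates the manifest bit for bit.
#'
#' @param seed Integer RNG seed.
#' @return An `ab_manifest` with scheme `"test_1024"`.
#' @export
ab_test_set <- function(seed) {
  set.seed(seed)
  grid <- characteristic_grid()
  spec_df <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(grid[i, , drop = FALSE],
               smd = c(rep(0L, 12L), rep(1:5, each = 4L)),
               row.names = NULL)
  }))
  spec_df <- spec_df[sample.int(nrow(spec_df)), ]
  new_manifest(spec_df, simulate_rows(spec_df), seed, "test_1024")
}

#' Generate the counterbalanced training set
#'
#' Half the graphs carry no effect (SMD 0) and the other half are split
#' equally over SMD 1-5, with the five binary characteristics perfectly
#' counterbalanced within each class. At the default size of 96,000 every
#' cell defined by (characteristic combination x positive SMD level) holds
#' 300 graphs and every (combination x no-effect) cell holds 1,500.
#'
#' @param seed Integer RNG seed.
#' @param total Total number of graphs; must be divisible by 320
#'   (32 combinations x 2 classes x 5 SMD levels) so the counterbalancing is
#'   exact.
#' @return An `ab_manifest` with scheme `"training_96000"` at the default
#'   size, `"custom"` otherwise.
#' @export
ab_training_set <- function(seed, total = 96000L) {
  if (length(total) != 1L || total < 320 || total %% 320 != 0) {
    stop(sprintf(
      "`total` must be a positive multiple of 320; smallest valid size >= %d is %d",
      max(320, total), max(320L, 320L * as.integer(ceiling(total / 320)))),
      call. = FALSE)
  }
  set.seed(seed)
  per_zero <- total / 64L          # no-effect graphs per combination
  per_smd <- total / 320L          # graphs per (combination x positive SMD)
  grid <- characteristic_grid()
  spec_df <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    data.frame(grid[i, , drop = FALSE],
               smd = c(rep(0L, per_zero), rep(1:5, each = per_smd)),
               row.names = NULL)
  }))
  scheme <- if (total == 96000) "training_96000" else "custom"
  new_manifest(spec_df, simulate_rows(spec_df), seed, scheme)
}

#' Cell identifiers for counterbalancing
#'
#' Returns the factor that crosses the 32 binary-characteristic combinations
#' with the SMD level; these cells are the unit of counterbalancing in the
#' training scheme and of class-balanced subsampling.
#'
#' @param manifest An `ab_manifest`.
#' @return A factor of length `length(manifest)`.
#' @export
manifest_cells <- function(manifest) {
  stopifnot(inherits(manifest, "ab_manifest"))
  s <- manifest$spec
  interaction(s$n_a, s$n_b, s$autocorr, s$trend_deg, s$var_level, s$smd,
              drop = TRUE)
}
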