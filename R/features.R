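# Per-graph standardization and the 8-feature representation used by the
# classifiers.

FEATURE_NAMES <- c("mean_a", "mean_b", "sd_a", "sd_b",
                   "intercept_a", "slope_a", "intercept_b", "slope_b")

# population (n-denominator) standard deviation
sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Standardize a series to mean 0 and SD 1
#'
#' Centers and scales a whole graph (both phases pooled) to mean 0 and
#' standard deviation 1, using the population (n-denominator) SD. Every
#' feature is computed on this standardized series, which makes the feature
#' representation invariant to positive affine transforms of the raw data —
#' in particular to the variability/level manipulation of the simulator.
#'
#' @param values Numeric series of length at least 2.
#' @return The standardized series.
#' @export
standardize_series <- function(values) {
  if (length(values) < 2L) stop("series must have at least 2 points",
                                call. = FALSE)
  s <- sd_pop(values)
  if (s == 0) {
    stop("zero-variance series cannot be standardized", call. = FALSE)
  }
  (values - mean(values)) / s
}

#' Extract the 8 classifier features from an AB graph
#'
#' After standardizing the whole series ([standardize_series()]), computes
#' per-phase means, per-phase population SDs, and per-phase OLS intercepts
#' and slopes against the session index. Indices are 0-based and continue
#' across the series (Phase B is regressed on indices `n_a .. n_a+n_b-1`),
#' so both intercepts refer to the start of the graph.
#'
#' @param graph An [ab_graph()], or a numeric series (then `n_a` is
#'   required).
#' @param n_a Number of Phase A sessions when `graph` is a bare series.
#' @return Named numeric vector of length 8, in the fixed order
#'   `mean_a, mean_b, sd_a, sd_b, intercept_a, slope_a, intercept_b,
#'   slope_b`.
#' @export
extract_features <- function(graph, n_a = NULL) {
  if (inherits(graph, "ab_graph")) {
    values <- graph$values
    n_a <- graph$n_a
  } else {
    values <- as.numeric(graph)
    if (is.null(n_a)) stop("`n_a` is required for a bare series",
                           call. = FALSE)
  }
  len <- length(values)
  if (n_a < 2L || len - n_a < 2L) {
    stop("each phase needs at least 2 points for SD and slope features",
         call. = FALSE)
  }
  z <- standardize_series(values)
  a <- z[seq_len(n_a)]
  b <- z[(n_a + 1):len]
  fit_a <- ols_line(seq_len(n_a) - 1, a)
  fit_b <- ols_line(n_a:(len - 1), b)
  out <- c(mean(a), mean(b), sd_pop(a), sd_pop(b),
           fit_a[["intercept"]], fit_a[["slope"]],
           fit_b[["intercept"]], fit_b[["slope"]])
  names(out) <- FEATURE_NAMES
  out
}

#' Feature matrix of a manifest
#'
#' @param manifest An `ab_manifest`.
#' @return Numeric matrix, one row per graph in manifest order, columns the
#'   8 features of [extract_features()].
#' @export
feature_matrix <- function(manifest) {
  stopifnot(inherits(manifest, "ab_manifest"))
  out <- t(vapply(seq_len(length(manifest)), function(i) {
    extract_features(manifest$values[[i]], n_a = manifest$spec$n_a[i])
  }, numeric(8)))
  colnames(out) <- FEATURE_NAMES
  out
}
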