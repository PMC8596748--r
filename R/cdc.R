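# Conservative dual-criteria (CDC) decision rule.

# closed-form OLS of y on x; returns c(intercept, slope)
ols_line <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  dx <- x - mx
  slope <- sum(dx * (y - my)) / sum(dx * dx)
  c(intercept = my - slope * mx, slope = slope)
}

#' Conservative dual-criteria classification of one AB graph
#'
#' Projects the Phase A mean line and the Phase A ordinary-least-squares
#' trend line into Phase B, raises both by 0.25 x the sample standard
#' deviation of Phase A, counts the Phase B points strictly above both
#' raised lines, and declares an effect when that count reaches the
#' threshold: 5 of 5 points when Phase B has five sessions, 8 of 10 when it
#' has ten. Session indices continue across the series (0-based), so the
#' trend line is a genuine extrapolation of the baseline fit.
#'
#' @param graph An [ab_graph()], or a numeric series (then `n_a` is
#'   required).
#' @param n_a Number of Phase A sessions when `graph` is a bare numeric
#'   vector.
#' @param direction Direction of the anticipated change; only `"increase"`
#'   is supported (the simulator only produces increases).
#' @return An object of class `cdc_result`: list with `mean_line` and
#'   `trend_line` (raised projected values per Phase B session), `n_above`,
#'   `threshold`, and `decision` (0/1).
#' @examples
#' cdc_classify(c(10, 10, 10, 11, 11, 11, 11, 11), n_a = 3)
#' @export
cdc_classify <- function(graph, n_a = NULL, direction = c("increase",
                                                          "decrease")) {
  direction <- match.arg(direction)
  if (direction != "increase") {
    stop("only the \"increase\" direction is implemented", call. = FALSE)
  }
  if (inherits(graph, "ab_graph")) {
    values <- graph$values
    n_a <- graph$n_a
  } else {
    values <- as.numeric(graph)
    if (is.null(n_a)) stop("`n_a` is required for a bare series",
                           call. = FALSE)
  }
  n_b <- length(values) - n_a
  if (!n_b %in% c(5L, 10L)) {
    stop("thresholds are defined only for Phase B lengths 5 and 10",
         call. = FALSE)
  }
  if (n_a < 2L) stop("at least 2 Phase A points are needed to fit the trend line",
                     call. = FALSE)
  a_vals <- values[seq_len(n_a)]
  b_vals <- values[(n_a + 1):length(values)]
  idx_a <- seq_len(n_a) - 1
  idx_b <- n_a:(length(values) - 1)
  raise <- 0.25 * stats::sd(a_vals)
  fit <- ols_line(idx_a, a_vals)
  mean_line <- rep(mean(a_vals) + raise, n_b)
  trend_line <- fit[["intercept"]] + fit[["slope"]] * idx_b + raise
  n_above <- sum(b_vals > mean_line & b_vals > trend_line)
  threshold <- if (n_b == 5L) 5L else 8L
  structure(
    list(mean_line = mean_line, trend_line = trend_line,
         n_above = as.integer(n_above), threshold = threshold,
         decision = as.integer(n_above >= threshold)),
    class = "cdc_result"
  )
}

#' @export
print.cdc_result <- function(x, ...) {
  cat(sprintf("<cdc_result> %d/%d Phase B points above both lines (threshold %d): %s\n",
              x$n_above, length(x$mean_line), x$threshold,
              if (x$decision == 1) "effect" else "no effect"))
  invisible(x)
}

#' Apply the conservative dual-criteria rule to a whole manifest
#'
#' @param manifest An `ab_manifest`.
#' @return Integer 0/1 decision vector in manifest order.
#' @export
cdc_batch <- function(manifest) {
  stopifnot(inherits(manifest, "ab_manifest"))
  vapply(seq_len(length(manifest)), function(i) {
    cdc_classify(manifest$values[[i]], n_a = manifest$spec$n_a[i])$decision
  }, integer(1))
}
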