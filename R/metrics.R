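# Accuracy, Type I error rate, power, agreement, confidence intervals, and
# characteristic-stratified breakdowns.

check_pair <- function(pred, truth) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) {
    stop("prediction and truth vectors must have equal length", call. = FALSE)
  }
  if (!all(pred %in% c(0L, 1L)) || !all(truth %in% c(0L, 1L))) {
    stop("decision vectors must contain only 0 and 1", call. = FALSE)
  }
  list(pred = pred, truth = truth)
}

#' Proportion of agreement between two decision vectors
#'
#' The number of positions with identical decisions divided by the total
#' number of graphs; with the true labels as the second vector this is the
#' accuracy of a method.
#'
#' @param pred,truth Aligned 0/1 decision vectors.
#' @return A proportion in \[0, 1\].
#' @export
accuracy <- function(pred, truth) {
  d <- check_pair(pred, truth)
  mean(d$pred == d$truth)
}

#' Type I error rate
#'
#' Proportion of graphs without a true effect on which the method declared
#' an effect: `P(pred = 1 | truth = 0)`.
#'
#' @inheritParams accuracy
#' @return A proportion in \[0, 1\].
#' @export
type1_rate <- function(pred, truth) {
  d <- check_pair(pred, truth)
  neg <- d$truth == 0L
  if (!any(neg)) stop("Type I error rate is undefined: no graphs without a true effect",
                      call. = FALSE)
  mean(d$pred[neg] == 1L)
}

#' Power
#'
#' Proportion of graphs with a true effect on which the method declared an
#' effect: `P(pred = 1 | truth = 1)`.
#'
#' @inheritParams accuracy
#' @return A proportion in \[0, 1\].
#' @export
power_rate <- function(pred, truth) {
  d <- check_pair(pred, truth)
  pos <- d$truth == 1L
  if (!any(pos)) stop("power is undefined: no graphs with a true effect",
                      call. = FALSE)
  mean(d$pred[pos] == 1L)
}

#' Pairwise agreement matrix
#'
#' Symmetric matrix of pairwise proportions of agreement among any number of
#' decision vectors (methods or raters); when `truth` is supplied it is
#' included as the first row/column under the name `"True"`.
#'
#' @param preds Named list of aligned 0/1 decision vectors.
#' @param truth Optional true-label vector.
#' @return Square numeric matrix with unit diagonal.
#' @export
agreement_matrix <- function(preds, truth = NULL) {
  if (!is.list(preds) || length(preds) < 1L) {
    stop("`preds` must be a non-empty list of decision vectors", call. = FALSE)
  }
  if (is.null(names(preds)) || any(names(preds) == "")) {
    names(preds) <- paste0("method", seq_along(preds))
  }
  if (!is.null(truth)) preds <- c(list(True = truth), preds)
  k <- length(preds)
  m <- matrix(1, k, k, dimnames = list(names(preds), names(preds)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) m[i, j] <- m[j, i] <- accuracy(preds[[i]], preds[[j]])
    }
  }
  m
}

#' Wald binomial confidence interval
#'
#' Normal-approximation interval `p +/- z * sqrt(p(1-p)/n)`, clipped to
#' \[0, 1\]. At `p = 0.80, n = 300` the half-width is 0.045, i.e. about
#' plus or minus .05.
#'
#' @param p Observed proportion.
#' @param n Number of trials.
#' @param level Confidence level.
#' @return Named numeric vector `c(low, high)`.
#' @export
binomial_ci <- function(p, n, level = 0.95) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  z <- qnorm(1 - (1 - level) / 2)
  hw <- z * sqrt(p * (1 - p) / n)
  c(low = max(0, p - hw), high = min(1, p + hw))
}

#' Significance by the point-versus-interval rule
#'
#' Flags a difference as significant when `p1` falls outside the binomial
#' confidence interval of `p2`. The rule is asymmetric; report both
#' orientations by swapping the argument pairs.
#'
#' @param p1,n1 First proportion and its sample size (`n1` is carried for
#'   the symmetric call, not used by this orientation).
#' @param p2,n2 Comparison proportion and its sample size, which define the
#'   interval.
#' @param level Confidence level of the interval.
#' @return Logical.
#' @export
significance_flag <- function(p1, n1, p2, n2, level = 0.95) {
  ci <- binomial_ci(p2, n2, level = level)
  p1 < ci[["low"]] || p1 > ci[["high"]]
}

# mapping from user-facing characteristic names to manifest columns
strat_column <- function(characteristic) {
  map <- c(n_a = "n_a", n_b = "n_b", autocorr = "autocorr",
           trend = "trend_deg", variability = "var_level", smd = "smd")
  if (!characteristic %in% names(map)) {
    stop("characteristic must be one of: ", paste(names(map), collapse = ", "),
         call. = FALSE)
  }
  map[[characteristic]]
}

metric_row <- function(method, variable, level_val, metric, est, n,
                       ci_level) {
  ci <- if (is.na(est)) c(low = NA_real_, high = NA_real_)
        else binomial_ci(est, n, ci_level)
  data.frame(method = method, stratum_variable = variable,
             stratum_level = as.character(level_val), metric = metric,
             estimate = est, ci_low = ci[["low"]], ci_high = ci[["high"]],
             n = n, stringsAsFactors = FALSE)
}

#' Metrics stratified by one graph characteristic
#'
#' Recomputes Type I error rate and power (and accuracy) within each level
#' of a manipulated characteristic. For `smd` the no-effect level 0 carries
#' only a Type I error rate and each positive level only a power, mirroring
#' the structure of an effect-size breakdown. Metrics undefined on a level
#' (no qualifying graphs) are reported as `NA`, never as 0.
#'
#' @param pred 0/1 decision vector in manifest order.
#' @param truth 0/1 true-label vector in manifest order.
#' @param manifest The `ab_manifest` the vectors are aligned to.
#' @param characteristic One of `"n_a"`, `"n_b"`, `"autocorr"`, `"trend"`,
#'   `"variability"`, `"smd"`.
#' @param method Label recorded in the output's `method` column.
#' @param ci_level Confidence level for the per-level intervals.
#' @return Tidy data frame with columns `method`, `stratum_variable`,
#'   `stratum_level`, `metric`, `estimate`, `ci_low`, `ci_high`, `n`.
#' @export
stratify_metrics <- function(pred, truth, manifest, characteristic,
                             method = "method", ci_level = 0.95) {
  stopifnot(inherits(manifest, "ab_manifest"))
  d <- check_pair(pred, truth)
  if (length(d$pred) != length(manifest)) {
    stop("vectors must align with the manifest", call. = FALSE)
  }
  col <- strat_column(characteristic)
  values <- manifest$spec[[col]]
  rows <- list()
  for (lv in sort(unique(values))) {
    in_lv <- values == lv
    p <- d$pred[in_lv]; tr <- d$truth[in_lv]
    n_neg <- sum(tr == 0L); n_pos <- sum(tr == 1L)
    if (characteristic == "smd") {
      if (lv == 0) {
        rows[[length(rows) + 1L]] <- metric_row(
          method, characteristic, lv, "type1",
          if (n_neg > 0) mean(p[tr == 0L] == 1L) else NA_real_,
          n_neg, ci_level)
      } else {
        rows[[length(rows) + 1L]] <- metric_row(
          method, characteristic, lv, "power",
          if (n_pos > 0) mean(p[tr == 1L] == 1L) else NA_real_,
          n_pos, ci_level)
      }
    } else {
      rows[[length(rows) + 1L]] <- metric_row(
        method, characteristic, lv, "accuracy", mean(p == tr), sum(in_lv),
        ci_level)
      rows[[length(rows) + 1L]] <- metric_row(
        method, characteristic, lv, "type1",
        if (n_neg > 0) mean(p[tr == 0L] == 1L) else NA_real_, n_neg,
        ci_level)
      rows[[length(rows) + 1L]] <- metric_row(
        method, characteristic, lv, "power",
        if (n_pos > 0) mean(p[tr == 1L] == 1L) else NA_real_, n_pos,
        ci_level)
    }
  }
  do.call(rbind, rows)
}

#' Full metrics report for one method
#'
#' Overall accuracy, Type I error rate, and power with binomial confidence
#' intervals, plus (when a manifest is supplied) the six per-characteristic
#' stratified breakdowns in one tidy table.
#'
#' @inheritParams stratify_metrics
#' @param manifest Optional `ab_manifest` for the stratified section.
#' @return An object of class `metrics_report`: list with `method`,
#'   `overall` (tidy data frame) and `strata` (tidy data frame or `NULL`).
#' @export
metrics_report <- function(pred, truth, manifest = NULL, method = "method",
                           ci_level = 0.95) {
  d <- check_pair(pred, truth)
  n <- length(d$pred)
  overall <- rbind(
    metric_row(method, "overall", "all", "accuracy",
               accuracy(d$pred, d$truth), n, ci_level),
    metric_row(method, "overall", "all", "type1",
               if (any(d$truth == 0L)) type1_rate(d$pred, d$truth)
               else NA_real_, sum(d$truth == 0L), ci_level),
    metric_row(method, "overall", "all", "power",
               if (any(d$truth == 1L)) power_rate(d$pred, d$truth)
               else NA_real_, sum(d$truth == 1L), ci_level)
  )
  strata <- NULL
  if (!is.null(manifest)) {
    strata <- do.call(rbind, lapply(
      c("n_a", "n_b", "autocorr", "trend", "variability", "smd"),
      function(ch) stratify_metrics(d$pred, d$truth, manifest, ch,
                                    method = method, ci_level = ci_level)))
  }
  structure(list(method = method, overall = overall, strata = strata),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> method \"%s\"\n", x$method))
  ov <- x$overall
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-8s %.3f [%.3f, %.3f] (n = %d)\n", ov$metric[i],
                ov$estimate[i], ov$ci_low[i], ov$ci_high[i], ov$n[i]))
  }
  if (!is.null(x$strata)) {
    cat(sprintf("  + stratified rows: %d\n", nrow(x$strata)))
  }
  invisible(x)
}

#' Write a metrics report as tidy CSV
#'
#' @param report A `metrics_report`.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  tidy <- rbind(report$overall, report$strata)
  write.csv(tidy, path, row.names = FALSE)
  invisible(path)
}
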