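# Training and prediction for the two effect-detection classifiers.

check_xy <- function(x, y) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("`x` must be a numeric matrix", call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("`y` must have one label per row of `x`",
                                 call. = FALSE)
  if (!all(y %in% c(0L, 1L))) stop("labels must be 0 (no change) or 1 (change)",
                                   call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("training labels contain a single class; two classes are required",
         call. = FALSE)
  }
  list(x = x, y = y)
}

#' Train the hinge-loss stochastic-gradient linear classifier
#'
#' Fits a linear decision function by stochastic gradient descent on the
#' regularized hinge loss (soft-margin SVM objective), one example at a
#' time, with the inverse-scaling "optimal" step size
#' `eta_t = 1 / (alpha * (t0 + t))`, `t0 = 1 / (alpha * sqrt(1/sqrt(alpha)))`.
#' The visiting order is reshuffled every epoch from `seed`. Training stops
#' when the mean epoch hinge loss has failed to improve by more than `tol`
#' for `n_iter_no_change` consecutive epochs, or at `max_iter` epochs.
#'
#' @param x Numeric feature matrix (one row per graph).
#' @param y Integer 0/1 labels (1 = change).
#' @param seed Integer seed for the per-epoch shuffling.
#' @param alpha L2 penalty strength.
#' @param max_iter Maximum number of epochs.
#' @param tol Minimum epoch-loss improvement that counts as progress.
#' @param n_iter_no_change Epochs without improvement before stopping.
#' @return An object of class `scd_model` with `kind = "sgd_hinge"`,
#'   weights `w`, intercept `b`, the number of epochs run, and the training
#'   seed.
#' @export
train_sgd <- function(x, y, seed = 1L, alpha = 1e-4, max_iter = 1000L,
                      tol = 1e-3, n_iter_no_change = 5L) {
  d <- check_xy(x, y)
  x <- d$x
  yy <- ifelse(d$y == 1L, 1L, -1L)
  set.seed(seed)
  typw <- sqrt(1 / sqrt(alpha))
  t0 <- 1 / (alpha * typw)
  w <- numeric(ncol(x))
  b <- 0
  t <- 1
  best_loss <- Inf
  no_improve <- 0L
  n_iter <- 0L
  for (epoch in seq_len(max_iter)) {
    ord <- sample.int(nrow(x)) - 1L
    st <- sgd_epoch(x, yy, w, b, t, alpha, t0, ord)
    w <- st$w; b <- st$b; t <- st$t
    n_iter <- epoch
    loss <- st$sumloss / nrow(x)
    if (loss > best_loss - tol) no_improve <- no_improve + 1L
    else no_improve <- 0L
    if (loss < best_loss) best_loss <- loss
    if (no_improve >= n_iter_no_change) break
  }
  structure(
    list(kind = "sgd_hinge", w = as.numeric(w), b = as.numeric(b),
         n_iter = n_iter, alpha = alpha, tol = tol,
         feature_names = colnames(x), training_seed = seed),
    class = "scd_model"
  )
}

#' Class- and cell-balanced subsample of a training manifest
#'
#' Draws `size` graph indices so that the two classes contribute equally and,
#' within each class, the counterbalancing cells (characteristic combination
#' x SMD level, [manifest_cells()]) contribute as evenly as integer
#' arithmetic allows; any remainder is spread over a seed-shuffled cell
#' order.
#'
#' @param manifest The training `ab_manifest`.
#' @param size Total subsample size.
#' @param seed Integer seed for the within-cell draws.
#' @return Integer vector of `size` manifest indices.
#' @export
balanced_subsample <- function(manifest, size, seed = 1L) {
  stopifnot(inherits(manifest, "ab_manifest"))
  n <- length(manifest)
  if (size > n) stop("`size` exceeds the manifest size", call. = FALSE)
  if (size == n) return(seq_len(n))
  set.seed(seed)
  truth <- manifest_truth(manifest)
  cells <- manifest_cells(manifest)
  out <- integer(0)
  for (cl in c(0L, 1L)) {
    cl_idx <- which(truth == cl)
    cl_cells <- droplevels(cells[cl_idx])
    lev <- levels(cl_cells)
    quota_cl <- size %/% 2L + if (cl == 1L) size %% 2L else 0L
    base <- quota_cl %/% length(lev)
    rem <- quota_cl %% length(lev)
    extra <- lev[sample.int(length(lev))][seq_len(rem)]
    for (lv in lev) {
      pool <- cl_idx[cl_cells == lv]
      k <- base + (lv %in% extra)
      if (k > length(pool)) {
        stop("cell too small for the requested balanced subsample",
             call. = FALSE)
      }
      out <- c(out, pool[sample.int(length(pool), k)])
    }
  }
  sort(out)
}

#' Train the support vector classifier
#'
#' Fits a maximum-margin classifier with a radial-basis-function kernel,
#' regularization constant 1 and kernel width
#' `gamma = 1 / (n_features * pooled variance of the feature matrix)`.
#' Optionally trains on a class- and cell-balanced subsample
#' ([balanced_subsample()]) of the manifest, which cuts the quadratic
#' training cost at a small accuracy price.
#'
#' @param x Numeric feature matrix.
#' @param y Integer 0/1 labels.
#' @param seed Integer seed (used only for the subsample draw; the fit
#'   itself is deterministic given the data).
#' @param subsample Optional subsample size; requires `manifest`.
#' @param manifest The training `ab_manifest`, needed when `subsample` is
#'   given to identify the counterbalancing cells.
#' @param cost Regularization constant C.
#' @param gamma Kernel width; default `1 / (ncol(x) * pooled variance)`.
#' @return An object of class `scd_model` with `kind = "svc"`.
#' @export
train_svc <- function(x, y, seed = 1L, subsample = NULL, manifest = NULL,
                      cost = 1, gamma = NULL) {
  d <- check_xy(x, y)
  x <- d$x
  y <- d$y
  if (is.null(gamma)) {
    v <- mean((x - mean(x))^2)  # pooled population variance of all entries
    gamma <- 1 / (ncol(x) * v)
  }
  if (!is.null(subsample) && subsample < nrow(x)) {
    if (is.null(manifest)) {
      stop("`manifest` is required for a cell-balanced subsample",
           call. = FALSE)
    }
    idx <- balanced_subsample(manifest, subsample, seed = seed)
    x <- x[idx, , drop = FALSE]
    y <- y[idx]
  }
  fit <- e1071::svm(x, factor(y, levels = c(0L, 1L)), kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE)
  structure(
    list(kind = "svc", fit = fit, gamma = gamma, cost = cost,
         feature_names = colnames(x), training_seed = seed,
         subsample = if (is.null(subsample)) NA_integer_
                     else as.integer(subsample)),
    class = "scd_model"
  )
}

#' @export
print.scd_model <- function(x, ...) {
  if (x$kind == "sgd_hinge") {
    cat(sprintf("<scd_model> hinge-loss SGD linear classifier (%d epochs)\n",
                x$n_iter))
  } else {
    cat(sprintf("<scd_model> RBF support vector classifier (gamma %.4g, %d SVs)\n",
                x$gamma, nrow(x$fit$SV)))
  }
  invisible(x)
}

#' Predict 0/1 decisions for a feature matrix
#'
#' @param object A trained `scd_model`.
#' @param newdata Numeric feature matrix with the same 8 columns used in
#'   training.
#' @param ... Unused.
#' @return Integer 0/1 decision vector (1 = change detected), deterministic
#'   for a fixed fitted model.
#' @export
predict.scd_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  p_expected <- if (object$kind == "sgd_hinge") length(object$w)
                else ncol(object$fit$SV)
  if (ncol(newdata) != p_expected) {
    stop(sprintf("feature matrix has %d columns; model expects %d",
                 ncol(newdata), p_expected), call. = FALSE)
  }
  if (object$kind == "sgd_hinge") {
    as.integer(drop(newdata %*% object$w) + object$b > 0)
  } else {
    as.integer(as.character(predict(object$fit, newdata)))
  }
}

#' Save / load a trained model
#'
#' Persists the fitted state together with a metadata header (format
#' version, model kind, training seed, feature order, creation time).
#'
#' @param model An `scd_model`.
#' @param path Destination file.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `scd_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "scd_model"))
  payload <- list(format_version = 1L, kind = model$kind,
                  training_seed = model$training_seed,
                  feature_names = model$feature_names,
                  created = format(Sys.time(), tz = "UTC"),
                  model = model)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- readRDS(path)
  if (!is.list(payload) || is.null(payload$format_version) ||
      !inherits(payload$model, "scd_model")) {
    stop("not an abdetect model file", call. = FALSE)
  }
  payload$model
}
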