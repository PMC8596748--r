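# File input/output: decision vectors, rater files, manifests, and graph
# rendering.

#' Write / read a decision vector
#'
#' Decision vectors are stored as headerless single-column CSV files of 0/1
#' values in manifest order; `read_vector` is the exact inverse of
#' `write_vector` and rejects anything that is not a 0 or a 1, naming the
#' offending line.
#'
#' @param decisions Integer 0/1 vector.
#' @param path File path.
#' @return `write_vector` returns `path` invisibly; `read_vector` returns
#'   an integer 0/1 vector.
#' @export
write_vector <- function(decisions, path) {
  decisions <- as.integer(decisions)
  if (anyNA(decisions) || !all(decisions %in% c(0L, 1L))) {
    stop("decisions must be 0 or 1", call. = FALSE)
  }
  writeLines(as.character(decisions), path)
  invisible(path)
}

#' @rdname write_vector
#' @export
read_vector <- function(path) {
  lines <- trimws(readLines(path))
  # tolerate a single trailing blank line, nothing else
  if (length(lines) && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  bad <- which(!lines %in% c("0", "1"))
  if (length(bad)) {
    stop(sprintf("line %d of '%s' is not a 0/1 decision: \"%s\"",
                 bad[1], path, lines[bad[1]]), call. = FALSE)
  }
  as.integer(lines)
}

#' Read a human-rater file
#'
#' Reads one rater's judgments (one 0/1 value per graph, in graph order)
#' from a headerless CSV or, when the `readxl` package is available, from a
#' single-column spreadsheet (`.xlsx`/`.xls`). Missing or non-binary entries
#' raise a validation error naming the row.
#'
#' @param path CSV or spreadsheet file.
#' @param rater_id Optional label attached to the result.
#' @return Integer 0/1 vector with attribute `rater_id`.
#' @export
read_ratings <- function(path, rater_id = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading spreadsheets requires the 'readxl' package", call. = FALSE)
    }
    cells <- readxl::read_excel(path, col_names = FALSE, col_types = "text")
    vals <- trimws(as.character(cells[[1]]))
    bad <- which(is.na(vals) | !vals %in% c("0", "1"))
    if (length(bad)) {
      stop(sprintf("row %d of '%s' is not a 0/1 rating", bad[1], path),
           call. = FALSE)
    }
    out <- as.integer(vals)
  } else {
    out <- read_vector(path)
  }
  attr(out, "rater_id") <- if (is.null(rater_id)) {
    tools::file_path_sans_ext(basename(path))
  } else rater_id
  out
}

#' Write / read a dataset manifest
#'
#' One CSV row per graph: `graph_id`, the six characteristics, the true
#' label, then the session values in columns `v1, v2, ...` (shorter series
#' leave trailing value columns empty). The reader reconstructs the
#' `ab_manifest` exactly, including seed and scheme, which travel in a
#' comment-style header line.
#'
#' @param manifest An `ab_manifest`.
#' @param path CSV file path.
#' @return `write_manifest` returns `path` invisibly; `read_manifest`
#'   returns the `ab_manifest`.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ab_manifest"))
  lens <- lengths(manifest$values)
  vmax <- max(lens)
  vals <- t(vapply(manifest$values, function(v) {
    c(v, rep(NA_real_, vmax - length(v)))
  }, numeric(vmax)))
  colnames(vals) <- paste0("v", seq_len(vmax))
  out <- cbind(manifest$spec, as.data.frame(vals))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# abdetect manifest scheme=%s seed=%d",
                     manifest$scheme, manifest$seed), con)
  write.csv(out, con, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header,
                  regexec("^# abdetect manifest scheme=(\\S+) seed=(-?\\d+)",
                          header))[[1]]
  if (length(m) != 3L) {
    stop("not an abdetect manifest file (missing header line)", call. = FALSE)
  }
  df <- read.csv(path, skip = 1L, stringsAsFactors = FALSE)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  values <- lapply(seq_len(nrow(df)), function(i) {
    v <- as.numeric(df[i, vcols])
    v[!is.na(v)]
  })
  spec <- df[, c("graph_id", "n_a", "n_b", "autocorr", "trend_deg",
                 "var_level", "smd", "label")]
  structure(list(spec = spec, values = values, seed = as.integer(m[3]),
                 scheme = m[2]),
            class = "ab_manifest")
}

#' Render a manifest as a multi-page PDF of AB graphs
#'
#' One line graph per page in manifest order, with a dashed phase-change
#' line between the last Phase A session and the first Phase B session and
#' no annotation that reveals the generating parameters. The y-axis spans
#' the graph's own data range plus 10% headroom on each side.
#'
#' @param manifest An `ab_manifest`.
#' @param path Output PDF path.
#' @return `path`, invisibly.
#' @export
render_graphs <- function(manifest, path) {
  stopifnot(inherits(manifest, "ab_manifest"))
  if (length(manifest) == 0L) stop("manifest is empty", call. = FALSE)
  grDevices::pdf(path, width = 7, height = 5, onefile = TRUE)
  on.exit(grDevices::dev.off())
  for (i in seq_len(length(manifest))) {
    v <- manifest$values[[i]]
    n_a <- manifest$spec$n_a[i]
    pad <- 0.1 * diff(range(v))
    if (pad == 0) pad <- 1
    graphics::plot(seq_along(v), v, type = "o", pch = 19,
                   xlab = "Session", ylab = "Behavior",
                   ylim = range(v) + c(-pad, pad),
                   main = sprintf("Graph %d", i))
    graphics::abline(v = n_a + 0.5, lty = 2)
  }
  invisible(path)
}
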