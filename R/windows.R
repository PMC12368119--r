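# The labeled-window container: a numeric array (window x time x feature)
# plus a metadata tibble. Kept as an array because every window lives on the
# same fixed time grid; all per-window metadata stays tabular.

new_windows <- function(X, meta, features, sampling_rate) {
  stopifnot(is.array(X), length(dim(X)) == 3L, nrow(meta) == dim(X)[1])
  dimnames(X) <- list(NULL, NULL, features)
  structure(list(X = X, meta = as_tibble(meta), features = features,
                 sampling_rate = sampling_rate),
            class = "tepr_windows")
}

#' @export
print.tepr_windows <- function(x, ...) {
  d <- dim(x$X)
  cat(sprintf("<tepr_windows> %d windows x %d samples x %d features (%s)\n",
              d[1], d[2], d[3], paste(x$features, collapse = ", ")))
  if (d[1] > 0) {
    tab <- table(x$meta$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = " "),
        "| synthetic:", sum(x$meta$synthetic), "\n")
  }
  invisible(x)
}

#' Number of windows in a window set
#' @param w A `tepr_windows` object.
#' @return Integer count.
#' @export
n_windows <- function(w) dim(w$X)[1]

#' Subset or combine window sets
#'
#' `windows_subset()` keeps the windows at positions `idx`;
#' `windows_bind()` concatenates window sets with identical geometry.
#'
#' @param w A `tepr_windows` object.
#' @param idx Integer or logical index vector.
#' @param ws List of `tepr_windows` objects.
#' @return A `tepr_windows` object.
#' @export
windows_subset <- function(w, idx) {
  new_windows(w$X[idx, , , drop = FALSE], w$meta[idx, ], w$features, w$sampling_rate)
}

#' @rdname windows_subset
#' @export
windows_bind <- function(ws) {
  ws <- ws[purrr::map_int(ws, n_windows) > 0]
  if (length(ws) == 0L) abort("no non-empty window sets to bind")
  d <- dim(ws[[1]]$X)
  for (w in ws) stopifnot(identical(dim(w$X)[-1], d[-1]))
  n <- sum(purrr::map_int(ws, n_windows))
  X <- array(NA_real_, c(n, d[2], d[3]))
  at <- 0L
  for (w in ws) {
    k <- n_windows(w)
    X[at + seq_len(k), , ] <- w$X
    at <- at + k
  }
  meta <- purrr::list_rbind(purrr::map(ws, "meta"))
  meta$window_id <- seq_len(nrow(meta))
  new_windows(X, meta, ws[[1]]$features, ws[[1]]$sampling_rate)
}

#' Drop gaze features from a window set
#'
#' Keeps only the pupil-diameter channel, for the pupil-only ablation.
#'
#' @param w A `tepr_windows` object.
#' @param features Character vector of feature names to keep.
#' @return A `tepr_windows` object with the requested channels.
#' @export
select_features <- function(w, features = "pupil") {
  keep <- match(features, w$features)
  if (anyNA(keep)) abort(paste("unknown feature(s):",
                               paste(features[is.na(keep)], collapse = ", ")))
  new_windows(w$X[, , keep, drop = FALSE], w$meta, w$features[keep], w$sampling_rate)
}

#' Tidy a window set into a long tibble
#'
#' @param x A `tepr_windows` object.
#' @param ... Unused.
#' @return A tibble with one row per (window, time point, feature).
#' @method tidy tepr_windows
#' @export
tidy.tepr_windows <- function(x, ...) {
  d <- dim(x$X)
  long <- tibble(
    window_id = rep(x$meta$window_id, times = d[2] * d[3]),
    label = rep(x$meta$label, times = d[2] * d[3]),
    time_idx = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    feature = rep(x$features, each = d[1] * d[2]),
    value = as.vector(x$X)
  )
  arrange(long, .data$window_id, .data$feature, .data$time_idx)
}

#' Serialize a window set as plain text
#'
#' Writes a `manifest.csv` (per-window metadata) and a `values.csv` whose row
#' `i` is window `i` flattened time-major per feature (all time points of
#' feature 1, then feature 2, ...). `read_windows()` restores the set.
#'
#' @param w A `tepr_windows` object.
#' @param dir Directory to write to.
#' @return The directory (write) or a `tepr_windows` (read).
#' @export
write_windows <- function(w, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(w$X)
  flat <- matrix(w$X, nrow = d[1])  # columns ordered time-within-feature
  manifest <- w$meta
  manifest$features <- paste(w$features, collapse = ";")
  manifest$sampling_rate <- w$sampling_rate
  manifest$n_time <- d[2]
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(flat), file.path(dir, "values.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname write_windows
#' @export
read_windows <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  flat <- as.matrix(utils::read.csv(file.path(dir, "values.csv")))
  features <- strsplit(manifest$features[1], ";")[[1]]
  n_time <- manifest$n_time[1]
  fs <- manifest$sampling_rate[1]
  X <- array(flat, c(nrow(flat), n_time, length(features)))
  meta <- as_tibble(manifest[setdiff(names(manifest), c("features", "sampling_rate", "n_time"))])
  new_windows(X, meta, features, fs)
}
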