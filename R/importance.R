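#' Permute one feature across windows
#'
#' Randomly reassigns the whole feature-`j` column block across windows
#' (window i receives window perm(i)'s feature-j series), leaving all other
#' features untouched. Permuting whole windows preserves within-window
#' temporal structure while destroying the feature's association with the
#' label, which isolates its informational contribution.
#'
#' @param w A `tepr_windows` object.
#' @param feature Feature name (e.g. `"pupil"`, `"gaze_x"`, `"gaze_y"`).
#' @param within_window If `TRUE`, shuffle the feature's samples within each
#'   window instead (alternative reading of "shuffle all data within a
#'   feature").
#' @return A new `tepr_windows` with the feature permuted.
#' @export
permute_feature <- function(w, feature, within_window = FALSE) {
  j <- match(feature, w$features)
  if (is.na(j)) abort(sprintf("unknown feature '%s'", feature))
  X <- w$X
  n <- dim(X)[1]
  if (within_window) {
    for (i in seq_len(n)) X[i, , j] <- X[i, sample.int(dim(X)[2]), j]
  } else {
    X[, , j] <- X[sample.int(n), , j]
  }
  new_windows(X, w$meta, w$features, w$sampling_rate)
}

#' Permutation feature importance
#'
#' Measures each feature's contribution as the mean drop in MCC when that
#' feature is randomly permuted across the test windows: with baseline score
#' `s_base` (MCC on unaltered windows) and `s_ij` the MCC after the i-th
#' permutation of feature j, the importance is `I_j = mean(s_base - s_ij)`
#' over `n_iter` permutations. Each feature's drops are tested against zero
#' with a one-sample t-test.
#'
#' @param model A `tepr_model`.
#' @param windows Test `tepr_windows`.
#' @param n_iter Number of permutations per feature (default 100).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param within_window Passed to [permute_feature()].
#' @return A `tepr_importance` tibble: one row per feature with `importance`
#'   (mean drop), `sd`, `p_value`, `n_iter`; baseline MCC in attribute
#'   `"baseline_mcc"`.
#' @export
permutation_importance <- function(model, windows, n_iter = 100, seed = NULL,
                                   within_window = FALSE) {
  run <- function() {
    base_pred <- predict(model, windows)
    s_base <- mcc_value(confusion(base_pred$label, base_pred$pred))
    rows <- purrr::map(windows$features, function(f) {
      drops <- purrr::map_dbl(seq_len(n_iter), function(i) {
        wp <- permute_feature(windows, f, within_window = within_window)
        pr <- predict(model, wp)
        s_base - mcc_value(confusion(pr$label, pr$pred))
      })
      p <- if (n_iter >= 2 && sd(drops) > 0) t.test(drops, mu = 0)$p.value else NA_real_
      if (n_iter < 2) inform(sprintf("feature %s: n_iter < 2, significance omitted", f))
      tibble(feature = f, importance = mean(drops), sd = sd(drops),
             p_value = p, n_iter = n_iter)
    })
    out <- purrr::list_rbind(rows)
    attr(out, "baseline_mcc") <- s_base
    class(out) <- c("tepr_importance", class(out))
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Plot a permutation-importance report
#'
#' Bar chart of per-feature MCC drops with +/- 1 sd error bars and the
#' baseline MCC as a reference line.
#'
#' @param object A `tepr_importance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tepr_importance
#' @export
autoplot.tepr_importance <- function(object, ...) {
  ggplot(object, aes(x = .data$feature, y = .data$importance)) +
    geom_col(fill = "steelblue") +
    geom_errorbar(aes(ymin = .data$importance - .data$sd,
                      ymax = .data$importance + .data$sd), width = 0.2) +
    geom_hline(yintercept = attr(object, "baseline_mcc"), linetype = "dashed") +
    labs(x = NULL, y = "MCC drop after permutation",
         title = "Permutation feature importance",
         subtitle = sprintf("baseline MCC = %.3f", attr(object, "baseline_mcc"))) +
    theme_minimal()
}
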