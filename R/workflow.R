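#' Run the full detection experiment
#'
#' Orchestrates the pipeline end to end: generate a synthetic cohort, build
#' standardized labeled windows, split participants into folds, train the
#' generalized "All-task" model and the requested task-specific models
#' (task-specific models see only their task's windows; REST negatives are
#' shared by default), evaluate each on its held-out test windows, compare
#' every model against the generalized one (Pearson, McNemar), and optionally
#' compute permutation feature importance and the online streaming
#' simulation. Every stage draws its randomness from `seed`, so the whole
#' bundle — including trained-weight fingerprints — is reproducible.
#'
#' @param cfg A [tepr_config()] describing the cohort.
#' @param duration Window duration in seconds (0.5, 1, 2 or 3).
#' @param architecture Model architecture for all models.
#' @param model_set Models to train: `"All-task"` and/or task names.
#' @param features `"all"` (pupil + gaze) or `"pupil"` (pupil-only ablation).
#' @param n_folds,test_fold,val_fold Participant-level split controls.
#' @param rest_windows_per_session Passed to [make_windows()].
#' @param include_rest Share REST negatives with task-specific models?
#' @param smote_k SMOTE neighbourhood size.
#' @param training Named list of [model_config()] overrides (e.g.
#'   `list(max_epochs = 10)`).
#' @param importance_iters Permutation-importance iterations (0 skips).
#' @param online Run the streaming simulation on one test participant?
#' @param seed Master seed for the experiment.
#' @return A `tepr_experiment` bundle: `models`, `predictions`, `metrics`,
#'   `importance`, `online`, `folds`, `windows_summary`, `provenance`.
#' @export
run_experiment <- function(cfg = tepr_config(),
                           duration = 1,
                           architecture = "CNN",
                           model_set = c("All-task", TASKS),
                           features = c("all", "pupil"),
                           n_folds = 5, test_fold = 1, val_fold = 2,
                           rest_windows_per_session = NULL,
                           include_rest = TRUE,
                           smote_k = 5,
                           training = list(),
                           importance_iters = 0,
                           online = FALSE,
                           seed = 1) {
  features <- match.arg(features)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
    })
  }

  cohort <- stage("generate", generate_cohort(cfg))
  feat_cols <- if (features == "pupil") "pupil" else c("pupil", "gaze_x", "gaze_y")
  w <- stage("preprocess", make_windows(
    cohort, duration = duration,
    rest_windows_per_session = rest_windows_per_session,
    features = feat_cols, seed = derive_seed(seed, "rest-windows")
  ))
  folds <- stage("folds", make_folds(unique(w$meta$participant_id), n_folds,
                                     seed = derive_seed(seed, "folds")))
  split <- stage("split", assemble_split(w, folds, test_fold, val_fold,
                                         smote = FALSE))

  base_args <- utils::modifyList(list(
    architecture = architecture,
    n_features = length(feat_cols),
    window_length = dim(w$X)[2]
  ), training)

  model_subset <- function(set, model_name) {
    if (model_name == "All-task") return(set)
    keep_tasks <- if (include_rest) c(model_name, "REST") else model_name
    windows_subset(set, set$meta$task %in% keep_tasks)
  }

  models <- list(); predictions <- list()
  importance <- list()
  for (m in model_set) {
    mc <- do.call(model_config, c(base_args, list(seed = derive_seed(seed, paste("train", m)))))
    tr <- stage(paste("smote", m), smote_rebalance(
      model_subset(split$train, m), smote_k,
      seed = derive_seed(seed, paste("smote", m))
    ))
    va <- model_subset(split$val, m)
    te <- model_subset(split$test, m)
    models[[m]] <- stage(paste("train", m), tepr_train(mc, tr, va))
    predictions[[m]] <- stage(paste("predict", m), predict(models[[m]], te))
    if (importance_iters > 0) {
      importance[[m]] <- stage(paste("importance", m), permutation_importance(
        models[[m]], te, n_iter = importance_iters,
        seed = derive_seed(seed, paste("importance", m))
      ))
    }
  }

  ref <- if ("All-task" %in% model_set) "All-task" else model_set[1]
  metrics <- stage("evaluate", compare_models(predictions, reference = ref))

  online_res <- NULL
  if (online) {
    online_res <- stage("online", run_online_stage(
      models[[ref]], cohort, folds, test_fold, duration))
  }

  structure(list(
    models = models, predictions = predictions, metrics = metrics,
    importance = importance, online = online_res, folds = folds,
    windows_summary = dplyr::count(w$meta, .data$task, .data$label),
    provenance = list(seed = seed, duration = duration, features = features,
                      architecture = architecture, generator = cfg,
                      fingerprints = purrr::map_chr(models, "fingerprint"))
  ), class = "tepr_experiment")
}

run_online_stage <- function(model, cohort, folds, test_fold, duration) {
  test_pids <- folds$participant_id[folds$fold == test_fold]
  pid <- test_pids[1]
  recs <- cohort$samples |>
    filter(.data$participant_id == pid, .data$task != "REST") |>
    recording_groups()
  rows <- purrr::map(recs, function(g) {
    key <- g[1, ]
    ev <- cohort$events |>
      filter(.data$participant_id == key$participant_id,
             .data$session_id == key$session_id,
             .data$task == key$task)
    fs <- round(1 / median(diff(g$time_s)))
    if (nrow(g) / fs < 60 + duration + 3) return(NULL)  # too short to stream
    trace <- stream_predict(model, g, stride = 0.1, warmup = 60)
    attr(trace, "events") <- ev$stimulus_time_s
    rep <- score_online(trace, duration = duration)
    rep$model <- paste0("online/", key$task)
    rep
  })
  purrr::list_rbind(rows[!purrr::map_lgl(rows, is.null)])
}

#' @export
print.tepr_experiment <- function(x, ...) {
  cat("<tepr_experiment>", length(x$models), "model(s):",
      paste(names(x$models), collapse = ", "), "\n")
  print(x$metrics)
  invisible(x)
}

#' Write experiment tables to delimited files
#'
#' Emits the bundle's result tables as CSV: per-model metrics with the
#' cross-model comparison columns, per-feature permutation importance, the
#' online scores, and a provenance file (seed, fingerprints). In pupil-only
#' runs it is conventional to drop the DPT row from cross-model comparisons
#' (its pupillary light reflex dominates the single remaining channel); set
#' `exclude` accordingly.
#'
#' @param bundle A `tepr_experiment`.
#' @param dir Output directory.
#' @param exclude Model names to drop from the metrics table.
#' @return Invisibly, the paths written.
#' @export
render_tables <- function(bundle, dir, exclude = character(0)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  metrics <- filter(bundle$metrics, !.data$model %in% exclude)
  p <- file.path(dir, "metrics.csv")
  utils::write.csv(metrics, p, row.names = FALSE); paths <- c(paths, p)
  if (length(bundle$importance) > 0) {
    imp <- purrr::imap(bundle$importance, function(tb, nm) {
      tb2 <- as_tibble(tb); tb2$model <- nm
      tb2$baseline_mcc <- attr(tb, "baseline_mcc")
      tb2
    }) |> purrr::list_rbind()
    p <- file.path(dir, "importance.csv")
    utils::write.csv(imp, p, row.names = FALSE); paths <- c(paths, p)
  }
  if (!is.null(bundle$online)) {
    p <- file.path(dir, "online.csv")
    utils::write.csv(bundle$online, p, row.names = FALSE); paths <- c(paths, p)
  }
  p <- file.path(dir, "provenance.txt")
  writeLines(c(
    sprintf("seed: %s", bundle$provenance$seed),
    sprintf("architecture: %s", bundle$provenance$architecture),
    sprintf("duration_s: %s", bundle$provenance$duration),
    sprintf("features: %s", bundle$provenance$features),
    sprintf("fingerprint %s: %s", names(bundle$provenance$fingerprints),
            bundle$provenance$fingerprints)
  ), p)
  paths <- c(paths, p)
  invisible(paths)
}
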