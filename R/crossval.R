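# The five-fold cross-validation protocol: per fold, train on 80% of the
# non-test data with the remaining 20% as validation, select the best epoch
# on the validation metric, evaluate on the held-out test fold, and report
# the per-fold metrics with their median and standard deviation.

#' Five-fold cross-validated evaluation
#'
#' Runs the full evaluation protocol on a SMILES/label dataset: featurize
#' once (shared vocabulary and `n_max`), split into 5 stratified folds with
#' a 20% per-fold validation carve-out, compute the loss weights on each
#' fold's training labels only, train with best-epoch selection, score the
#' held-out test fold, and aggregate medians and standard deviations across
#' folds.
#'
#' @inheritParams bondgat
#' @param folds Number of folds (default 5).
#' @return An object of class `bondgat_cv`: list with `fold_metrics` (one
#'   row per fold), `summary` (median and SD per metric), `histories`,
#'   `config`, `seed` and `task`.
#' @export
run_cross_validation <- function(data, y = NULL, smiles_col = "smiles",
                                 label_col = "label", task = NULL,
                                 config = bondgat_config("complete"),
                                 weighted = TRUE, alpha = 0.55,
                                 epochs = 100L, batch_size = 32L, lr = 1e-3,
                                 folds = 5L, n_max = NULL, seed = 1L,
                                 verbose = FALSE) {
  if (is.character(data)) {
    smiles <- data
    stopifnot(!is.null(y), length(y) == length(smiles))
    label <- y
  } else {
    smiles <- as.character(data[[smiles_col]])
    label <- data[[label_col]]
  }
  if (is.null(task)) {
    task <- if (all(label %in% c(0, 1))) "classification" else "regression"
  }
  task <- match.arg(task, c("regression", "classification"))
  label <- if (task == "classification") as.integer(label) else
    as.numeric(label)

  vocab <- feature_vocabulary()
  graphs <- featurize_dataset(smiles, vocab, n_max = n_max)
  n_max <- attr(graphs, "n_max")
  plans <- split_cv(length(graphs),
                    labels = if (task == "classification") label else NULL,
                    seed = seed, folds = folds)
  loss_spec <- if (task == "regression") {
    list(type = if (weighted) "wrmse" else "rmse", alpha = alpha)
  } else {
    list(type = if (weighted) "wbce" else "bce")
  }

  rows <- list()
  histories <- list()
  for (plan in plans) {
    k <- plan$fold_id
    if (verbose) message("fold ", k, "/", folds)
    model <- assemble_model(config, task, n_max = n_max, vocab = vocab,
                            seed = seed + k)
    model <- train_model(
      model,
      train = list(graphs = graphs[plan$train_indices],
                   y = label[plan$train_indices]),
      val = list(graphs = graphs[plan$val_indices],
                 y = label[plan$val_indices]),
      loss_spec = loss_spec, epochs = epochs, batch_size = batch_size,
      lr = lr, seed = seed + k, verbose = verbose
    )
    preds <- predict_graphs(model, graphs[plan$test_indices])
    m <- if (task == "regression") {
      regression_metrics(label[plan$test_indices], preds)
    } else {
      classification_metrics(label[plan$test_indices], preds)
    }
    rows[[k]] <- data.frame(fold = k, as.data.frame(m))
    histories[[k]] <- model$history
  }
  fold_metrics <- do.call(rbind, rows)
  metric_names <- setdiff(names(fold_metrics), "fold")
  summary <- data.frame(
    metric = metric_names,
    median = vapply(metric_names, function(m)
      stats::median(fold_metrics[[m]]), numeric(1)),
    sd = vapply(metric_names, function(m)
      stats::sd(fold_metrics[[m]]), numeric(1)),
    row.names = NULL
  )
  structure(
    list(fold_metrics = fold_metrics, summary = summary,
         histories = histories, config = config, task = task,
         loss_spec = loss_spec, n_max = n_max, seed = seed,
         epochs = epochs, batch_size = batch_size, lr = lr),
    class = "bondgat_cv"
  )
}

#' @export
print.bondgat_cv <- function(x, ...) {
  cat("Five-fold cross-validation (", x$config$variant, " variant, ",
      x$task, ")\n", sep = "")
  cat("  seed ", x$seed, ", ", x$epochs, " epochs per fold\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-10s median %.4f  sd %.4f\n", s$metric[i], s$median[i],
                s$sd[i]))
  }
  invisible(x)
}

#' @export
summary.bondgat_cv <- function(object, ...) {
  cat("Per-fold test metrics:\n")
  print(object$fold_metrics, row.names = FALSE)
  cat("\n")
  print(object)
  invisible(object)
}

#' @export
plot.bondgat_cv <- function(x, ...) {
  m <- setdiff(names(x$fold_metrics), "fold")
  graphics::boxplot(x$fold_metrics[m], ylab = "test metric",
                    main = paste("5-fold CV,", x$config$variant), ...)
  invisible(x)
}

#' Serialize a cross-validation report
#'
#' Writes the report as JSON (full: per-fold metrics, summary, config,
#' seeds) plus a flat CSV of the per-fold metrics, and one CSV of training
#' curves per fold.
#'
#' @param cv A `bondgat_cv` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_cv_report <- function(cv, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(dir, "cv_report.json")
  csv_path <- file.path(dir, "fold_metrics.csv")
  jsonlite::write_json(
    list(task = cv$task, config = unclass(cv$config), seed = cv$seed,
         epochs = cv$epochs, batch_size = cv$batch_size, lr = cv$lr,
         loss = cv$loss_spec, n_max = cv$n_max,
         fold_metrics = cv$fold_metrics, summary = cv$summary),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(cv$fold_metrics, csv_path, row.names = FALSE)
  curve_paths <- vapply(seq_along(cv$histories), function(k) {
    p <- file.path(dir, sprintf("training_curve_fold%d.csv", k))
    utils::write.csv(cv$histories[[k]], p, row.names = FALSE)
    p
  }, character(1))
  invisible(c(json_path, csv_path, curve_paths))
}
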