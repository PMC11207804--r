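# The main fitting interface: bondgat() and its S3 methods.

#' Fit a bond-substructure graph attention network
#'
#' Featurizes the SMILES, carves out a validation split (stratified for
#' classification), computes the loss weights from the training labels,
#' assembles the network and trains it with per-epoch validation and
#' best-epoch selection.
#'
#' @param data Data frame holding the compounds, or a character vector of
#'   SMILES (then supply `y`).
#' @param y Labels, when `data` is a character vector.
#' @param smiles_col,label_col Column names used when `data` is a data
#'   frame.
#' @param task `"regression"` (continuous label, density-weighted RMSE
#'   loss) or `"classification"` (0/1 label, class-weighted BCE loss).
#'   Guessed from the labels when missing.
#' @param config A [bondgat_config()]; default is the complete
#'   (four-branch) architecture.
#' @param weighted Use the density-/class-weighted loss (default `TRUE`);
#'   `FALSE` trains on plain RMSE/BCE.
#' @param alpha Density-weighting strength in \eqn{[0, 1]} for regression
#'   (default 0.55).
#' @param validation Fraction of the data held out for epoch selection
#'   (default 0.2).
#' @param epochs,batch_size,lr Training schedule (defaults 100, 32, 1e-3).
#' @param n_max Atom capacity; defaults to the dataset maximum.
#' @param seed Seed for the validation split, weight initialization and
#'   shuffling.
#' @param verbose Print per-epoch progress.
#' @return An object of class `bondgat` with `print`, `summary`, `coef`,
#'   `predict`, `plot`, `fitted` and `residuals` methods.
#' @examples
#' \dontrun{
#' d <- generate_synthetic_dataset(200, "classification", seed = 1)
#' fit <- bondgat(d, task = "classification", epochs = 5, seed = 1)
#' predict(fit, c("CC#CC", "CCOCC"))
#' }
#' @export
bondgat <- function(data, y = NULL, smiles_col = "smiles",
                    label_col = "label", task = NULL,
                    config = bondgat_config("complete"), weighted = TRUE,
                    alpha = 0.55, validation = 0.2, epochs = 100L,
                    batch_size = 32L, lr = 1e-3, n_max = NULL, seed = 1L,
                    verbose = FALSE) {
  if (is.character(data)) {
    smiles <- data
    stopifnot(!is.null(y), length(y) == length(smiles))
    label <- y
  } else {
    stopifnot(is.data.frame(data))
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
  n <- length(graphs)

  # validation split (stratified for classification), seeded
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  n_val <- round(validation * n)
  if (task == "classification") {
    sizes <- vapply(c(0L, 1L), function(cl) sum(label == cl), integer(1))
    take <- .apportion(sizes, n_val)
    val_idx <- sort(unlist(lapply(1:2, function(i) {
      sample(which(label == c(0L, 1L)[i]), take[i])
    })))
  } else {
    val_idx <- sort(sample.int(n, n_val))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  train_idx <- setdiff(seq_len(n), val_idx)

  loss_spec <- if (task == "regression") {
    list(type = if (weighted) "wrmse" else "rmse", alpha = alpha)
  } else {
    list(type = if (weighted) "wbce" else "bce")
  }
  model <- assemble_model(config, task, n_max = n_max, vocab = vocab,
                          seed = seed)
  model <- train_model(
    model,
    train = list(graphs = graphs[train_idx], y = label[train_idx]),
    val = list(graphs = graphs[val_idx], y = label[val_idx]),
    loss_spec = loss_spec, epochs = epochs, batch_size = batch_size,
    lr = lr, seed = seed, verbose = verbose
  )
  fitted_vals <- predict_graphs(model, graphs)
  structure(
    list(model = model, task = task, smiles = smiles, y = label,
         fitted.values = fitted_vals, train_indices = train_idx,
         val_indices = val_idx, seed = seed, call = match.call()),
    class = "bondgat"
  )
}

#' @export
print.bondgat <- function(x, ...) {
  h <- x$model$history
  sel <- h[h$selected, ]
  cat("Bond-substructure graph attention network (", x$model$config$variant,
      " variant)\n", sep = "")
  cat("  task: ", x$task, ", ", parameter_count(x$model), " parameters, ",
      length(x$smiles), " molecules (", length(x$val_indices),
      " validation)\n", sep = "")
  cat(sprintf("  selected epoch %d/%d with validation %s = %.4f\n",
              sel$epoch, nrow(h),
              if (x$task == "regression") "RMSE" else "AUPRC",
              sel$val_metric))
  invisible(x)
}

#' @export
summary.bondgat <- function(object, ...) {
  tr <- object$train_indices
  va <- object$val_indices
  metr <- function(idx) {
    if (object$task == "regression") {
      regression_metrics(object$y[idx], object$fitted.values[idx])
    } else {
      classification_metrics(object$y[idx], object$fitted.values[idx])
    }
  }
  out <- list(fit = object, train_metrics = metr(tr), val_metrics = metr(va))
  class(out) <- "summary.bondgat"
  out
}

#' @export
print.summary.bondgat <- function(x, ...) {
  print(x$fit)
  fmt <- function(m) paste(sprintf("%s = %.4f", names(m), unlist(m)),
                           collapse = ", ")
  cat("  training:  ", fmt(x$train_metrics), "\n")
  cat("  validation:", fmt(x$val_metrics), "\n")
  invisible(x)
}

#' @export
coef.bondgat <- function(object, ...) {
  unpack_theta(object$model$theta, object$model$layout)
}

#' Predict molecular properties for new SMILES
#'
#' @param object A fitted [bondgat()] model.
#' @param newdata Character vector of SMILES, or a data frame with the
#'   fitting `smiles_col`. Missing `newdata` returns the fitted values.
#' @param ... Unused.
#' @return Numeric predictions: probabilities of class 1 for
#'   classification, unbounded values for regression.
#' @export
predict.bondgat <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  smiles <- if (is.data.frame(newdata)) as.character(newdata$smiles) else
    as.character(newdata)
  graphs <- featurize_dataset(smiles, object$model$vocab,
                              n_max = NULL)
  predict_graphs(object$model, graphs)
}

#' @export
fitted.bondgat <- function(object, ...) object$fitted.values

#' @export
residuals.bondgat <- function(object, ...) {
  if (object$task != "regression") {
    stop("residuals are defined for regression fits", call. = FALSE)
  }
  object$y - object$fitted.values
}

#' Plot the training history of a fit
#'
#' Training loss and validation metric per epoch, with the selected epoch
#' marked.
#'
#' @param x A fitted [bondgat()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.bondgat <- function(x, ...) {
  h <- x$model$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "loss", ...)
  vm <- if (x$task == "regression") "validation RMSE" else "validation AUPRC"
  graphics::plot(h$epoch, h$val_metric, type = "l", xlab = "epoch",
                 ylab = vm, main = vm, ...)
  sel <- h[h$selected, ]
  graphics::points(sel$epoch, sel$val_metric, pch = 19, col = "red")
  invisible(x)
}
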