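# Training loop: Adam on mini-batches of the chosen loss, with per-epoch
# validation and best-epoch checkpoint selection.

divergence_error <- function(epoch) {
  errorCondition(
    sprintf("training diverged: non-finite loss at epoch %d", epoch),
    epoch = epoch,
    class = c("bondgat_divergence_error", "bondgat_error")
  )
}

# Resolve the per-sample training weights for a loss specification.
# loss_spec: list(type = "wrmse"|"rmse"|"wbce"|"bce", alpha = ...).
# Weights are a pure function of the *training* labels.
loss_sample_weights <- function(loss_spec, y) {
  type <- loss_spec$type
  if (type == "wrmse") {
    density_weights(y, loss_spec$alpha)$weights
  } else if (type == "wbce") {
    cw <- class_weights(y)
    unname(cw$weights[as.character(as.integer(y))])
  } else if (type %in% c("rmse", "bce")) {
    rep(1, length(y))
  } else {
    stop("unknown loss type '", type, "'", call. = FALSE)
  }
}

#' Train a model with validation-based epoch selection
#'
#' Runs Adam on mini-batches of the training split; after every epoch the
#' model is scored on the validation split (RMSE for regression, minimized;
#' AUPRC for classification, maximized) and the parameters of the best epoch
#' are the ones returned. No early stopping is applied: all `epochs` run and
#' the checkpoint with the best validation score wins.
#'
#' @param model An untrained (or warm) `bondgat_model` from
#'   [assemble_model()].
#' @param train,val Lists with elements `graphs` (list of
#'   [featurize()]d molecules) and `y` (labels); train and val must be
#'   disjoint.
#' @param loss_spec List with `type` (`"wrmse"`, `"rmse"`, `"wbce"` or
#'   `"bce"`) and, for `"wrmse"`, `alpha`. Sample weights are computed once
#'   here, from the training labels only.
#' @param epochs Number of training epochs.
#' @param batch_size Mini-batch size.
#' @param lr Adam learning rate.
#' @param seed Seed controlling shuffling (and nothing else; the weights in
#'   `model` were already initialized by [assemble_model()]).
#' @param verbose Print one line per epoch.
#' @return The trained `bondgat_model` with `history`: a data frame with
#'   one row per epoch (`epoch`, `train_loss`, `val_metric`, `selected`),
#'   exactly one row selected.
#' @export
train_model <- function(model, train, val,
                        loss_spec = if (model$task == "regression")
                          list(type = "wrmse", alpha = 0.55) else
                          list(type = "wbce"),
                        epochs = 100L, batch_size = 32L, lr = 1e-3,
                        seed = 1L, verbose = FALSE) {
  stopifnot(inherits(model, "bondgat_model"))
  ng <- length(train$graphs)
  stopifnot(ng == length(train$y), length(val$graphs) == length(val$y))
  cfg <- engine_config(model$config, model$task, model$D)
  emols <- engine_graphs(train$graphs)
  vmols <- engine_graphs(val$graphs)
  sw <- loss_sample_weights(loss_spec, train$y)
  y <- as.numeric(train$y)

  theta <- model$theta
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  bn_mean <- model$bn_mean; bn_var <- model$bn_var
  bn_momentum <- 0.9
  step <- 0L

  minimize <- model$task == "regression"
  best <- if (minimize) Inf else -Inf
  best_theta <- theta; best_bn <- list(bn_mean, bn_var)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_metric = numeric(0))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(ng)
    batches <- split(ord, ceiling(seq_along(ord) / batch_size))
    ep_loss <- 0
    for (bt in batches) {
      res <- cpp_batch_grad(emols[bt], theta, model$layout, cfg,
                            y[bt], sw[bt], bn_mean, bn_var, bn_momentum)
      if (!is.finite(res$loss)) stop(divergence_error(ep))
      ep_loss <- ep_loss + res$loss * length(bt)
      bn_mean <- res$bn_mean; bn_var <- res$bn_var
      g <- res$grad
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    ep_loss <- ep_loss / ng
    vp <- cpp_batch_predict(vmols, theta, model$layout, cfg, bn_mean, bn_var)
    vm <- if (minimize) weighted_rmse(val$y, vp)
          else classification_metrics(val$y, vp)$AUPRC
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_metric = vm))
    if ((minimize && vm < best) || (!minimize && vm > best)) {
      best <- vm
      best_theta <- theta
      best_bn <- list(bn_mean, bn_var)
    }
    if (verbose) {
      message(sprintf("epoch %3d  train loss %.4f  val %s %.4f%s", ep,
                      ep_loss, if (minimize) "RMSE" else "AUPRC", vm,
                      if (vm == best) " *" else ""))
    }
  }
  sel <- if (minimize) which.min(hist$val_metric) else which.max(hist$val_metric)
  hist$selected <- seq_len(nrow(hist)) == sel
  model$theta <- best_theta
  model$bn_mean <- best_bn[[1]]
  model$bn_var <- best_bn[[2]]
  model$trained <- TRUE
  model$history <- hist
  model$loss_spec <- loss_spec
  model
}
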