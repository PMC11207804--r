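# Model configuration, parameter layout and assembly.
#
# All trainable parameters live in one flat numeric vector. model_layout()
# defines the canonical name -> (offset, nrow, ncol) packing; the compiled
# engine walks the same layout, so R-side initialization, Adam updates and
# coef() extraction all agree with the C++ forward/backward pass.

.variants <- c("complete", "whole_molecule", "convolutional")

#' Model configuration
#'
#' Architecture hyperparameters for [assemble_model()] and [bondgat()].
#'
#' The three variants mirror the ablation study:
#' * `complete` - four per-bond-class attention branches (two stacked
#'   multi-head attention layers each), masked-sum fusion, whole-molecule
#'   multi-head attention, gated attention pooling, batch norm + MLP;
#' * `whole_molecule` - the substructure branches are removed and the one-hot
#'   features feed the whole-molecule attention directly;
#' * `convolutional` - the whole-molecule attention layer is replaced by a
#'   symmetric-normalized graph convolution with the same output width
#'   (which has strictly fewer parameters than the multi-head layer).
#'
#' @param variant One of `"complete"`, `"whole_molecule"`, `"convolutional"`.
#' @param F Per-head output width of every attention head (default 32).
#' @param K Number of attention heads per layer (default 4). The
#'   whole-molecule layer concatenates its heads, so node features entering
#'   the pooling stage have width `Q = K * F`.
#' @param P Width of the pooled graph-level vector (default 64).
#' @param mlp_hidden Integer vector of MLP hidden-layer sizes (default
#'   `c(64, 32)`), LeakyReLU-activated; the output unit is linear for
#'   regression and sigmoid for classification.
#' @param leaky_slope Negative slope of every LeakyReLU (default 0.2).
#' @return An object of class `bondgat_config`.
#' @export
bondgat_config <- function(variant = c("complete", "whole_molecule",
                                       "convolutional"),
                           F = 32L, K = 4L, P = 64L,
                           mlp_hidden = c(64L, 32L), leaky_slope = 0.2) {
  variant <- match.arg(variant)
  stopifnot(F >= 1, K >= 1, P >= 1, leaky_slope > 0, all(mlp_hidden >= 1))
  structure(
    list(variant = variant, F = as.integer(F), K = as.integer(K),
         Q = as.integer(K * F), P = as.integer(P),
         mlp_hidden = as.integer(mlp_hidden), leaky_slope = leaky_slope),
    class = "bondgat_config"
  )
}

#' @export
print.bondgat_config <- function(x, ...) {
  cat("bondgat model configuration\n")
  cat("  variant:", x$variant, "\n")
  cat("  attention: K =", x$K, "heads, F =", x$F, "per head, Q =", x$Q, "\n")
  cat("  pooling: P =", x$P, "; MLP hidden:",
      paste(x$mlp_hidden, collapse = ", "), "\n")
  cat("  LeakyReLU slope:", x$leaky_slope, "\n")
  invisible(x)
}

# Canonical flat parameter layout: named list of c(offset0, nrow, ncol).
model_layout <- function(config, D = feature_vocabulary()$D) {
  F <- config$F; K <- config$K; Q <- config$Q; P <- config$P
  shapes <- list()
  add <- function(name, nr, nc) shapes[[name]] <<- c(nr, nc)
  if (config$variant != "whole_molecule") {
    for (k in 1:4) {
      for (h in 1:K) {
        add(sprintf("m1.b%d.l1.h%d.W", k, h), D, F)
        add(sprintf("m1.b%d.l1.h%d.a", k, h), 2L * F, 1L)
      }
      for (h in 1:K) {
        add(sprintf("m1.b%d.l2.h%d.W", k, h), K * F, F)
        add(sprintf("m1.b%d.l2.h%d.a", k, h), 2L * F, 1L)
      }
    }
  }
  if (config$variant == "convolutional") {
    add("m2.gc.W", F, Q)
  } else {
    in2 <- if (config$variant == "whole_molecule") D else F
    for (h in 1:K) {
      add(sprintf("m2.h%d.W", h), in2, F)
      add(sprintf("m2.h%d.a", h), 2L * F, 1L)
    }
  }
  add("pool.W1", Q, P); add("pool.W2", Q, P)
  add("pool.b1", P, 1L); add("pool.b2", P, 1L)
  add("bn.gamma", P, 1L); add("bn.beta", P, 1L)
  sizes <- c(P, config$mlp_hidden, 1L)
  for (i in seq_len(length(sizes) - 1L)) {
    add(sprintf("mlp.%d.W", i), sizes[i], sizes[i + 1L])
    add(sprintf("mlp.%d.b", i), sizes[i + 1L], 1L)
  }
  off <- 0L
  layout <- list()
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    layout[[nm]] <- c(off, d[1], d[2])
    off <- off + d[1] * d[2]
  }
  attr(layout, "length") <- off
  layout
}

# Engine-facing config list
engine_config <- function(config, task, D) {
  list(variant = match(config$variant, .variants) - 1L,
       F = config$F, K = config$K, Q = config$Q, P = config$P,
       D = as.integer(D),
       task = if (task == "classification") 1L else 0L,
       slope = config$leaky_slope,
       mlp = config$mlp_hidden)
}

# Variance-scaling (fan-average, uniform) initialization of the flat vector.
init_theta <- function(layout) {
  theta <- numeric(attr(layout, "length"))
  for (nm in names(layout)) {
    d <- layout[[nm]]
    idx <- d[1] + seq_len(d[2] * d[3])
    if (grepl("\\.W$|\\.W1$|\\.W2$|\\.a$", nm)) {
      fan_in <- d[2]; fan_out <- d[3]
      lim <- sqrt(6 / (fan_in + fan_out))
      theta[idx] <- stats::runif(length(idx), -lim, lim)
    } else if (nm == "bn.gamma") {
      theta[idx] <- 1
    } # biases and bn.beta stay 0
  }
  theta
}

#' Assemble an untrained model
#'
#' Instantiates the network of a given configuration: allocates and
#' initializes (variance-scaling uniform, seeded) the flat parameter vector,
#' the batch-normalization running statistics, and the metadata needed to
#' featurize inputs consistently (vocabulary, `D`, `n_max`).
#'
#' @param config A [bondgat_config()].
#' @param task `"regression"` or `"classification"`.
#' @param n_max Atom capacity the model was/will be trained with.
#' @param vocab The [feature_vocabulary()] serialized with the model.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `bondgat_model`.
#' @export
assemble_model <- function(config, task = c("regression", "classification"),
                           n_max, vocab = feature_vocabulary(), seed = 1L) {
  task <- match.arg(task)
  stopifnot(inherits(config, "bondgat_config"))
  layout <- model_layout(config, D = vocab$D)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  theta <- init_theta(layout)
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  structure(
    list(config = config, task = task, n_max = as.integer(n_max),
         vocab = vocab, D = vocab$D, layout = layout, theta = theta,
         bn_mean = numeric(config$P), bn_var = rep(1, config$P),
         seed = as.integer(seed), trained = FALSE, history = NULL),
    class = "bondgat_model"
  )
}

#' Number of trainable parameters
#'
#' @param model A `bondgat_model` (or a fitted `bondgat` object).
#' @param module Optional name prefix to count only one stage, e.g. `"m2"`
#'   for the whole-molecule layer, `"m1"` for the substructure branches,
#'   `"pool"`, `"bn"` or `"mlp"`.
#' @return Integer parameter count.
#' @examples
#' cfg <- bondgat_config("complete", F = 8, K = 2)
#' m <- assemble_model(cfg, "regression", n_max = 10)
#' parameter_count(m)
#' parameter_count(m, "m2")
#' @export
parameter_count <- function(model, module = NULL) {
  if (inherits(model, "bondgat")) model <- model$model
  layout <- model$layout
  nms <- names(layout)
  if (!is.null(module)) nms <- nms[startsWith(nms, paste0(module, "."))]
  sum(vapply(nms, function(nm) prod(layout[[nm]][2:3]), numeric(1)))
}

# Unpack the flat vector into named matrices/vectors.
unpack_theta <- function(theta, layout) {
  out <- list()
  for (nm in names(layout)) {
    d <- layout[[nm]]
    vals <- theta[d[1] + seq_len(d[2] * d[3])]
    out[[nm]] <- if (d[3] == 1L) vals else matrix(vals, d[2], d[3])
  }
  out
}

# Convert molecular graphs to the engine's input form. trim=TRUE drops the
# padded rows/columns (the forward pass is padding-invariant, so this is a
# pure speed optimization).
engine_graphs <- function(graphs, trim = TRUE) {
  lapply(graphs, function(g) {
    n <- if (trim) max(g$n_atoms, 1L) else g$n_max
    idx <- seq_len(n)
    list(fi = g$feature_idx[idx, , drop = FALSE],
         A = c(list(g$A_full[idx, idx, drop = FALSE]),
               lapply(g$A_sub, function(A) A[idx, idx, drop = FALSE])))
  })
}

#' Predict from an assembled or trained model on featurized graphs
#'
#' Low-level prediction: runs the forward pass (inference-mode batch
#' normalization, using the stored running statistics) on a list of
#' [featurize()]d graphs. Classification outputs are probabilities of class
#' 1, strictly inside (0, 1); regression outputs are unbounded.
#'
#' @param model A `bondgat_model`.
#' @param graphs A list of `molecular_graph` objects (or a single one).
#' @return Numeric vector, one prediction per molecule.
#' @export
predict_graphs <- function(model, graphs) {
  stopifnot(inherits(model, "bondgat_model"))
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  D <- unique(vapply(graphs, function(g) ncol(g$H), integer(1)))
  if (length(D) != 1 || D != model$D) {
    stop("graphs were featurized with a different vocabulary (D = ",
         paste(D, collapse = ","), " vs model D = ", model$D, ")",
         call. = FALSE)
  }
  cpp_batch_predict(engine_graphs(graphs), model$theta, model$layout,
                    engine_config(model$config, model$task, model$D),
                    model$bn_mean, model$bn_var)
}

#' @export
print.bondgat_model <- function(x, ...) {
  cat("<bondgat ", x$config$variant, " model> ",
      if (x$trained) "trained" else "untrained",
      ", task: ", x$task, "\n", sep = "")
  cat("  ", parameter_count(x), " parameters; D = ", x$D,
      ", n_max = ", x$n_max, "\n", sep = "")
  invisible(x)
}
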