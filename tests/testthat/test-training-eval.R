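# Cross-validation splitting, metrics and the training loop.

test_that("unstratified 5-fold plans satisfy the 80/20 arithmetic", {
  plans <- split_cv(100, seed = 1)
  expect_length(plans, 5)
  tests <- lapply(plans, `[[`, "test_indices")
  expect_equal(sort(unlist(tests)), 1:100)          # partition
  for (p in plans) {
    expect_length(p$test_indices, 20)
    expect_length(p$val_indices, 16)
    expect_length(p$train_indices, 64)
    expect_length(intersect(p$test_indices, p$val_indices), 0)
    expect_length(intersect(p$test_indices, p$train_indices), 0)
    expect_length(intersect(p$val_indices, p$train_indices), 0)
  }
})

test_that("stratified plans preserve prevalence within one record", {
  set.seed(2)
  labels <- rbinom(1000, 1, 0.2)
  labels[1:2] <- c(0, 1) # both classes guaranteed
  plans <- split_cv(1000, labels = labels, seed = 3)
  pi_hat <- mean(labels)
  for (p in plans) {
    for (set in list(p$test_indices, p$val_indices, p$train_indices)) {
      expected <- pi_hat * length(set)
      expect_lte(abs(sum(labels[set]) - expected), 1 + 1e-9)
    }
    expect_length(p$val_indices, round(0.2 * (1000 - length(p$test_indices))))
  }
})

test_that("splits are reproducible from the seed", {
  p1 <- split_cv(200, seed = 11)
  p2 <- split_cv(200, seed = 11)
  expect_identical(p1, p2)
  p3 <- split_cv(200, seed = 12)
  expect_false(identical(p1, p3))
  expect_error(split_cv(100, labels = rep(1, 100)),
               class = "bondgat_degenerate_error")
})

test_that("regression metrics match hand evaluations", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(m), c(RMSE = 0, MAE = 0, R2 = 1))
  y <- c(0, 0, 3)
  m <- regression_metrics(y, rep(mean(y), 3))
  expect_equal(m$R2, 0)
  m <- regression_metrics(y, c(0, 0, 0))
  expect_equal(m$MAE, 1)
  expect_equal(m$RMSE, sqrt(3))
  expect_warning(m <- regression_metrics(c(2, 2, 2), c(1, 2, 3)), "undefined")
  expect_true(is.na(m$R2))
})

test_that("AUROC equals trapezoidal ROC integration on random inputs", {
  trap_auroc <- function(y, s) {
    th <- sort(unique(s), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(s[y == 1] >= t), numeric(1)))
    fpr <- c(0, vapply(th, function(t) mean(s[y == 0] >= t), numeric(1)))
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(19)
  for (rep in 1:10) {
    n <- 60
    y <- rbinom(n, 1, 0.4); y[1:2] <- 0:1
    s <- rnorm(n)
    got <- classification_metrics(y, s)$AUROC
    expect_equal(got, trap_auroc(y, s), tolerance = 1e-9)
  }
})

test_that("AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(20)
  y <- rbinom(300, 1, 0.3); y[1:2] <- 0:1
  s <- rnorm(300) + y
  expect_equal(classification_metrics(y, s)$AUROC,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-9)
})

test_that("AUPRC equals an explicit precision-recall step sum", {
  step_ap <- function(y, s) {
    # walk thresholds one distinct score at a time, summing P * dR
    ths <- sort(unique(s), decreasing = TRUE)
    ap <- 0; prev_rec <- 0
    for (t in ths) {
      sel <- s >= t
      prec <- sum(y[sel]) / sum(sel)
      rec <- sum(y[sel]) / sum(y)
      ap <- ap + prec * (rec - prev_rec)
      prev_rec <- rec
    }
    ap
  }
  set.seed(21)
  for (rep in 1:10) {
    y <- rbinom(80, 1, 0.25); y[1:2] <- 0:1
    s <- round(rnorm(80), 1) # ties on purpose
    expect_equal(classification_metrics(y, s)$AUPRC, step_ap(y, s),
                 tolerance = 1e-12)
  }
})

test_that("no-skill classifiers attain the AUPRC prevalence baseline", {
  y <- c(rep(1, 30), rep(0, 120))
  m <- classification_metrics(y, rep(0.5, 150))
  expect_equal(m$AUPRC, 0.2)
  # perfect separation
  m <- classification_metrics(y, y + runif(150, 0, 0.1))
  expect_equal(m$AUROC, 1)
  expect_equal(m$AUPRC, 1)
  expect_error(classification_metrics(rep(1, 5), runif(5)),
               class = "bondgat_degenerate_error")
})

test_that("random scores give AUROC 0.5 at scale", {
  set.seed(22)
  n <- 1e5
  y <- rbinom(n, 1, 0.2)
  s <- runif(n)
  expect_equal(classification_metrics(y, s)$AUROC, 0.5, tolerance = 0.01)
})

test_that("training selects the best validation epoch and is deterministic", {
  d <- generate_synthetic_dataset(60, "classification", seed = 43,
                                  prevalence = 0.35)
  graphs <- featurize_dataset(d$smiles)
  n_max <- attr(graphs, "n_max")
  idx_tr <- 1:45; idx_va <- 46:60
  run <- function() {
    model <- assemble_model(tiny_config(), "classification", n_max = n_max,
                            seed = 8)
    train_model(model,
                train = list(graphs = graphs[idx_tr], y = d$label[idx_tr]),
                val = list(graphs = graphs[idx_va], y = d$label[idx_va]),
                loss_spec = list(type = "wbce"), epochs = 4L,
                batch_size = 16L, seed = 8)
  }
  m1 <- run()
  h <- m1$history
  expect_equal(nrow(h), 4)
  expect_equal(sum(h$selected), 1)
  expect_equal(h$val_metric[h$selected], max(h$val_metric))
  m2 <- run()
  expect_identical(m1$theta, m2$theta)
  expect_identical(m1$history, m2$history)
})

test_that("regression training selects the minimum validation RMSE", {
  d <- generate_synthetic_dataset(60, "regression", seed = 44)
  graphs <- featurize_dataset(d$smiles)
  model <- assemble_model(tiny_config(), "regression",
                          n_max = attr(graphs, "n_max"), seed = 9)
  fitm <- train_model(model,
                      train = list(graphs = graphs[1:45], y = d$label[1:45]),
                      val = list(graphs = graphs[46:60],
                                 y = d$label[46:60]),
                      loss_spec = list(type = "wrmse", alpha = 0.55),
                      epochs = 3L, batch_size = 16L, seed = 9)
  h <- fitm$history
  expect_equal(h$val_metric[h$selected], min(h$val_metric))
  expect_true(all(is.finite(h$train_loss)))
})

test_that("cross-validation aggregates five folds with median and SD", {
  d <- generate_synthetic_dataset(80, "classification", seed = 45,
                                  prevalence = 0.3)
  cv <- run_cross_validation(d, task = "classification",
                             config = tiny_config(), epochs = 2L,
                             batch_size = 16L, seed = 5)
  expect_s3_class(cv, "bondgat_cv")
  expect_equal(nrow(cv$fold_metrics), 5)
  expect_length(cv$histories, 5)
  for (m in cv$summary$metric) {
    vals <- cv$fold_metrics[[m]]
    expect_equal(cv$summary$median[cv$summary$metric == m],
                 sort(vals)[3]) # third order statistic
    expect_equal(cv$summary$sd[cv$summary$metric == m], sd(vals))
  }
  # report is serializable
  dir <- withr::local_tempdir()
  paths <- write_cv_report(cv, dir)
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::fromJSON(paths[1])
  expect_equal(nrow(rep$fold_metrics), 5)
})
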