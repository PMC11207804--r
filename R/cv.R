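# Five-fold cross-validation splitting with a 20% validation carve-out,
# stratified for classification.

# Largest-remainder apportionment of `total` draws across strata with sizes
# `sizes` (keeps every stratum within 1 of its proportional share).
.apportion <- function(sizes, total) {
  quota <- sizes / sum(sizes) * total
  base <- floor(quota)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Five-fold cross-validation plan
#'
#' Splits `n` records into 5 test folds that partition the data; within each
#' fold, 20% of the non-test records (rounded) form the validation set and
#' the rest the training set. With class `labels`, both the fold assignment
#' and the validation carve-out are stratified, keeping every subset's
#' positive prevalence within one record of the dataset's. Splits are fully
#' reproducible from `seed`; the validation draw of fold `k` is seeded
#' `seed + k`.
#'
#' @param n Dataset size (>= 10).
#' @param labels Optional 0/1 class labels of length `n` for stratification.
#' @param seed Integer seed.
#' @param folds Number of folds (5, the protocol's value).
#' @return List of `folds` plans, each with `fold_id`, `test_indices`,
#'   `val_indices`, `train_indices`.
#' @export
split_cv <- function(n, labels = NULL, seed = 1L, folds = 5L) {
  stopifnot(n >= 10)
  if (!is.null(labels)) {
    stopifnot(length(labels) == n)
    labels <- as.integer(labels)
    if (length(unique(labels)) < 2) {
      stop(degenerate_targets("single-class labels: stratified split undefined"))
    }
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold_of <- integer(n)
  if (is.null(labels)) {
    fold_of[sample.int(n)] <- rep_len(seq_len(folds), n)
  } else {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold_of[sample(idx)] <- rep_len(seq_len(folds), length(idx))
    }
  }
  lapply(seq_len(folds), function(k) {
    test <- which(fold_of == k)
    rest <- which(fold_of != k)
    n_val <- round(0.20 * length(rest))
    set.seed(seed + k)
    if (is.null(labels)) {
      val <- sort(sample(rest, n_val))
    } else {
      sizes <- vapply(c(0L, 1L), function(cl) sum(labels[rest] == cl),
                      integer(1))
      take <- .apportion(sizes, n_val)
      val <- sort(unlist(lapply(seq_along(take), function(i) {
        pool <- rest[labels[rest] == c(0L, 1L)[i]]
        sample(pool, take[i])
      })))
    }
    list(fold_id = k, test_indices = test, val_indices = val,
         train_indices = sort(setdiff(rest, val)))
  })
}
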