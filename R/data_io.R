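# Dataset readers and summaries.

input_error <- function(...) {
  errorCondition(paste0(...), class = c("bondgat_input_error",
                                        "bondgat_error"))
}

#' Read a SMILES/label table from a delimited text file
#'
#' Reads a CSV (comma-separated, header row, UTF-8), keeps the rows whose
#' SMILES parse, and reports how many were dropped. Labels are read as
#' numeric for regression and as 0/1 for classification (`"0.0"`/`"1.0"`
#' are accepted).
#'
#' @param path File path.
#' @param smiles_col,label_col Column names (defaults `"smiles"`,
#'   `"label"`).
#' @param task `"regression"` or `"classification"`.
#' @return List with `records` (data frame `id`, `smiles`, `label`) and
#'   `stats` (see [dataset_stats()]).
#' @export
read_smiles_csv <- function(path, smiles_col = "smiles",
                            label_col = "label",
                            task = c("regression", "classification")) {
  task <- match.arg(task)
  if (!file.exists(path)) stop(input_error("file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(input_error("empty dataset: ", path))
  for (col in c(smiles_col, label_col)) {
    if (!col %in% names(df)) {
      stop(input_error("column '", col, "' not found; available columns: ",
                       paste(names(df), collapse = ", ")))
    }
  }
  smiles <- as.character(df[[smiles_col]])
  label <- suppressWarnings(as.numeric(df[[label_col]]))
  if (anyNA(label)) stop(input_error("non-numeric labels in column '",
                                     label_col, "'"))
  if (task == "classification") {
    if (!all(label %in% c(0, 1))) {
      stop(input_error("classification labels must be 0/1"))
    }
    label <- as.integer(label)
  }
  parsed <- parse_smiles_batch(smiles)
  ok <- !vapply(parsed, inherits, logical(1), "bondgat_parse_error")
  n_dropped <- sum(!ok)
  if (n_dropped > 0) {
    message(n_dropped, " record(s) dropped: unparsable SMILES")
  }
  id <- if ("id" %in% names(df)) as.character(df$id) else
    sprintf("row_%05d", seq_len(nrow(df)))
  records <- data.frame(id = id[ok], smiles = smiles[ok], label = label[ok],
                        stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    stop(input_error("empty dataset after dropping unparsable SMILES"))
  }
  stats <- dataset_stats(records, task = task)
  stats$n_dropped <- n_dropped
  list(records = records, stats = stats)
}

#' Summary statistics of a SMILES/label dataset
#'
#' Counts, positive prevalence (classification) or label quantiles
#' (regression), and the maximum heavy-atom count (which feeds the padded
#' capacity `n_max`).
#'
#' @param records Data frame with `smiles` and `label` columns.
#' @param task `"regression"` or `"classification"`; guessed from the
#'   labels when missing.
#' @return List of class `bondgat_stats`.
#' @export
dataset_stats <- function(records, task = NULL) {
  stopifnot(nrow(records) > 0)
  if (is.null(task)) {
    task <- if (all(records$label %in% c(0, 1))) "classification" else
      "regression"
  }
  mols <- parse_smiles_batch(records$smiles)
  ok <- !vapply(mols, inherits, logical(1), "bondgat_parse_error")
  max_atoms <- max(vapply(mols[ok], function(m) m$n_atoms, integer(1)))
  out <- list(n_total = nrow(records), n_dropped = 0L, max_atoms = max_atoms,
              task = task)
  if (task == "classification") {
    out$n_positive <- sum(records$label == 1)
    out$n_negative <- sum(records$label == 0)
    out$positive_fraction <- out$n_positive / out$n_total
  } else {
    out$label_quantiles <- stats::quantile(records$label,
                                           c(0, 0.25, 0.5, 0.75, 1))
  }
  structure(out, class = "bondgat_stats")
}

#' @export
print.bondgat_stats <- function(x, ...) {
  cat("Dataset:", x$n_total, "records (", x$n_dropped, "dropped ),",
      "max heavy atoms:", x$max_atoms, "\n")
  if (x$task == "classification") {
    cat(sprintf("  positives: %d (%.2f%%), negatives: %d\n", x$n_positive,
                100 * x$positive_fraction, x$n_negative))
  } else {
    q <- x$label_quantiles
    cat("  label quantiles:", paste(sprintf("%s=%.3g", names(q), q),
                                    collapse = ", "), "\n")
  }
  invisible(x)
}

.benchmarks <- data.frame(
  name = c("lipo_az", "aqsoldb", "cyp2c9", "cyp2c19", "cyp2d6", "cyp3a4"),
  tdc_group = c("ADME", "ADME", "ADME", "ADME", "ADME", "ADME"),
  tdc_name = c("Lipophilicity_AstraZeneca", "Solubility_AqSolDB",
               "CYP2C9_Veith", "CYP2C19_Veith", "CYP2D6_Veith",
               "CYP3A4_Veith"),
  task = c("regression", "regression", "classification", "classification",
           "classification", "classification"),
  stringsAsFactors = FALSE
)

offline_error <- function(name, detail) {
  errorCondition(
    paste0("could not fetch benchmark '", name, "' from the Therapeutics ",
           "Data Commons (", detail, "). If you are offline, download the ",
           "dataset on a connected machine (Python: `from tdc.single_pred ",
           "import ADME; ADME(name = '...')`), export it as a CSV with ",
           "'smiles' and 'label' columns, and load it with ",
           "read_smiles_csv()."),
    class = c("bondgat_offline_error", "bondgat_error")
  )
}

#' Load one of the six ADMET benchmark datasets
#'
#' Fetches a benchmark (Lipophilicity AZ, AqSolDB, or one of the four CYP
#' P450 inhibition sets) through the Therapeutics Data Commons Python
#' client and caches the resulting CSV, so later calls work offline.
#' Records are passed through unmodified except for dropping unparsable
#' SMILES (each drop is counted in the returned stats).
#'
#' @param name One of `"lipo_az"`, `"aqsoldb"`, `"cyp2c9"`, `"cyp2c19"`,
#'   `"cyp2d6"`, `"cyp3a4"`.
#' @param cache_dir Directory for cached CSVs (default: the user cache dir,
#'   overridable via the `BONDGAT_CACHE` environment variable).
#' @return As [read_smiles_csv()]: list with `records` and `stats`.
#' @section Offline use: when the fetch fails (no network, or no Python
#'   `tdc` package) an error of class `bondgat_offline_error` explains how
#'   to supply the data as a local CSV instead.
#' @export
load_benchmark <- function(name, cache_dir = NULL) {
  row <- .benchmarks[.benchmarks$name == name, ]
  if (nrow(row) != 1) {
    stop(input_error("unknown benchmark '", name, "'; available: ",
                     paste(.benchmarks$name, collapse = ", ")))
  }
  if (is.null(cache_dir)) {
    cache_dir <- Sys.getenv("BONDGAT_CACHE",
                            tools::R_user_dir("bondgat", "cache"))
  }
  cached <- file.path(cache_dir, paste0(name, ".csv"))
  if (!file.exists(cached)) {
    dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
    script <- sprintf(
      "from tdc.single_pred import ADME\nimport pandas as pd\nd = ADME(name = '%s').get_data()\nd = d.rename(columns = {'Drug_ID': 'id', 'Drug': 'smiles', 'Y': 'label'})\nd[['id', 'smiles', 'label']].to_csv(r'%s', index = False)\n",
      row$tdc_name, cached)
    sf <- tempfile(fileext = ".py")
    writeLines(script, sf)
    status <- tryCatch(
      suppressWarnings(system2(bondgat_python(), shQuote(sf),
                               stdout = FALSE, stderr = FALSE)),
      error = function(e) -1L
    )
    unlink(sf)
    if (!identical(status, 0L) || !file.exists(cached)) {
      unlink(cached)
      stop(offline_error(name, "network or the Python 'tdc' package unavailable"))
    }
  }
  read_smiles_csv(cached, task = row$task)
}
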