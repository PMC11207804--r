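# SMILES parsing backend.
#
# Chemistry perception (aromaticity, ring membership, hybridization,
# chirality tags) is delegated to RDKit, invoked as a batch subprocess
# through the bundled inst/python/smiles_graph.py helper. One subprocess
# call parses an arbitrary number of SMILES; parsed molecules are cached for
# the session so repeated featurization of the same strings is free.

.parse_cache <- new.env(parent = emptyenv())

bondgat_python <- function() {
  py <- getOption("bondgat.python", "")
  if (!nzchar(py)) py <- Sys.getenv("BONDGAT_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("no 'python' interpreter found on the PATH; SMILES parsing needs ",
         "Python with rdkit (see ?parse_smiles)", call. = FALSE)
  }
  py
}

parse_error <- function(smiles, reason) {
  errorCondition(
    sprintf("failed to parse SMILES '%s': %s", smiles, reason),
    smiles = smiles,
    class = c("bondgat_parse_error", "bondgat_error")
  )
}

.bond_class_names <- c("single", "double", "triple", "aromatic")
.hyb_names <- c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "Other")
.chi_names <- c("Unspecified", "Clockwise", "Counter-clockwise", "Other")

# Run the RDKit helper on a character vector; returns a list of raw records
# (ok/atoms/bonds or ok=FALSE/error), one per input string.
.run_rdkit <- function(smiles) {
  script <- system.file("python", "smiles_graph.py", package = "bondgat")
  if (!nzchar(script)) stop("bundled smiles_graph.py not found", call. = FALSE)
  infile <- tempfile("smiles_")
  on.exit(unlink(infile), add = TRUE)
  writeLines(smiles, infile)
  out <- suppressWarnings(
    system2(bondgat_python(), shQuote(script), stdout = TRUE, stderr = FALSE,
            stdin = infile)
  )
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop("SMILES parsing subprocess failed (exit status ", status,
         "); is rdkit importable from ", bondgat_python(), "?", call. = FALSE)
  }
  if (length(out) != length(smiles)) {
    stop("SMILES parsing subprocess returned ", length(out), " records for ",
         length(smiles), " inputs", call. = FALSE)
  }
  lapply(out, jsonlite::fromJSON, simplifyMatrix = TRUE)
}

.record_to_molecule <- function(rec, smiles) {
  if (!isTRUE(rec$ok)) return(parse_error(smiles, rec$error))
  am <- rec$atoms
  if (is.list(am)) am <- do.call(rbind, am)
  am <- matrix(as.numeric(am), ncol = 6)
  atoms <- data.frame(
    atomic_number = as.integer(am[, 1]),
    formal_charge = as.integer(am[, 2]),
    hybridization = .hyb_names[am[, 3] + 1L],
    in_ring = am[, 4] == 1,
    aromatic = am[, 5] == 1,
    chirality = .chi_names[am[, 6] + 1L],
    stringsAsFactors = FALSE
  )
  if (length(rec$bonds) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0),
                        class = character(0), stringsAsFactors = FALSE)
  } else {
    bm <- rec$bonds
    if (is.list(bm)) bm <- do.call(rbind, bm)
    bm <- matrix(as.integer(bm), ncol = 3)
    bonds <- data.frame(i = bm[, 1], j = bm[, 2],
                        class = .bond_class_names[bm[, 3]],
                        stringsAsFactors = FALSE)
  }
  structure(
    list(atoms = atoms, bonds = bonds, n_atoms = nrow(atoms),
         source_smiles = smiles),
    class = "parsed_molecule"
  )
}

# Batch parse with caching; returns a list, one element per input, each either
# a parsed_molecule or a bondgat_parse_error condition object.
parse_smiles_batch <- function(smiles) {
  smiles <- as.character(smiles)
  keys <- smiles
  miss <- unique(keys[!vapply(keys, exists, logical(1), envir = .parse_cache)])
  if (length(miss) > 0) {
    recs <- .run_rdkit(miss)
    for (idx in seq_along(miss)) {
      assign(miss[idx], .record_to_molecule(recs[[idx]], miss[idx]),
             envir = .parse_cache)
    }
  }
  lapply(keys, get, envir = .parse_cache)
}

#' Parse SMILES into heavy-atom molecular graphs
#'
#' Converts SMILES strings into per-atom records (atomic number, formal
#' charge, hybridization, ring flag, aromatic flag, tetrahedral chirality
#' tag) and an undirected bond list with each bond classified as `single`,
#' `double`, `triple` or `aromatic`. Hydrogens stay implicit: they are never
#' nodes of the graph. Aromaticity is the parsing toolkit's (RDKit's) default
#' perception, applied before bond classification, so e.g. benzene written in
#' Kekule form still yields six aromatic bonds. Atom indices are 0-based, in
#' the order the parser emits them.
#'
#' @param smiles Character vector of SMILES strings (non-empty).
#' @return For a single string, a `parsed_molecule`: a list with `atoms`
#'   (data frame), `bonds` (data frame with 0-based `i`, `j` and `class`),
#'   `n_atoms` and `source_smiles`. For a vector, a list of such objects.
#' @section Errors: an unparsable SMILES raises a condition of class
#'   `bondgat_parse_error` carrying the offending string in its `smiles`
#'   field.
#' @examples
#' \dontrun{
#' m <- parse_smiles("c1ccccc1")
#' m$n_atoms            # 6
#' table(m$bonds$class) # aromatic: 6
#' }
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1, all(nzchar(smiles)))
  out <- parse_smiles_batch(smiles)
  bad <- vapply(out, inherits, logical(1), "bondgat_parse_error")
  if (any(bad)) stop(out[[which(bad)[1]]])
  if (length(out) == 1) out[[1]] else out
}

#' @export
print.parsed_molecule <- function(x, ...) {
  cat("<parsed molecule> ", x$source_smiles, "\n", sep = "")
  cat("  ", x$n_atoms, " heavy atoms, ", nrow(x$bonds), " bonds (",
      paste(sprintf("%s: %d", .bond_class_names,
                    vapply(.bond_class_names,
                           function(k) sum(x$bonds$class == k), integer(1))),
            collapse = ", "), ")\n", sep = "")
  invisible(x)
}
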