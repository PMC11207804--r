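# Molecular graph construction: padded one-hot node features plus the
# adjacency set (full molecule + one matrix per bond class).

capacity_error <- function(smiles, n_atoms, n_max) {
  errorCondition(
    sprintf("molecule '%s' has %d heavy atoms, exceeding n_max = %d",
            smiles, n_atoms, n_max),
    smiles = smiles,
    class = c("bondgat_capacity_error", "bondgat_error")
  )
}

#' Build the adjacency set of a parsed molecule
#'
#' Constructs the full-molecule adjacency matrix plus one adjacency matrix
#' per bond class (single, double, triple, aromatic), all `n_max` x `n_max`
#' and zero-padded past the molecule's real atoms.
#'
#' Self-loop convention: the full matrix carries a self-loop on every real
#' atom, while a substructure matrix carries a self-loop on atom `i` only
#' when `i` is incident to at least one bond of that class. Those diagonal
#' entries are exactly the masks the masked-sum fusion layer reads (see
#' [masked_sum()]), so a vacuous all-ones diagonal would disable the gating.
#'
#' @param mol A `parsed_molecule` from [parse_smiles()].
#' @param n_max Padded size; must be at least `mol$n_atoms`.
#' @return A list with `A_full` (matrix) and `A_sub` (named list of four
#'   matrices, in bond-class order single/double/triple/aromatic).
#' @export
build_adjacency_set <- function(mol, n_max = mol$n_atoms) {
  stopifnot(inherits(mol, "parsed_molecule"))
  n <- mol$n_atoms
  if (n > n_max) stop(capacity_error(mol$source_smiles, n, n_max))
  A_full <- matrix(0, n_max, n_max)
  if (n > 0) A_full[cbind(1:n, 1:n)] <- 1
  A_sub <- lapply(.bond_class_names, function(k) matrix(0, n_max, n_max))
  names(A_sub) <- .bond_class_names
  b <- mol$bonds
  for (r in seq_len(nrow(b))) {
    i <- b$i[r] + 1L
    j <- b$j[r] + 1L
    k <- b$class[r]
    A_full[i, j] <- A_full[j, i] <- 1
    A_sub[[k]][i, j] <- A_sub[[k]][j, i] <- 1
    A_sub[[k]][i, i] <- A_sub[[k]][j, j] <- 1 # participation self-loops
  }
  list(A_full = A_full, A_sub = A_sub)
}

#' Featurize a SMILES string into a padded molecular graph
#'
#' Composes [parse_smiles()], [encode_atom()] per atom and
#' [build_adjacency_set()]: the result holds the one-hot node feature matrix
#' `H` (`n_max` x `D`, rows past the real atoms all zero) and the five
#' adjacency matrices. The featurization is deterministic.
#'
#' @param smiles A single SMILES string.
#' @param vocab A [feature_vocabulary()].
#' @param n_max Padded atom capacity (defaults to the molecule's own size).
#' @return An object of class `molecular_graph`: list with `H`, `A_full`,
#'   `A_sub`, `n_atoms`, `n_max`, and `feature_idx` (the per-atom indices of
#'   the six one-hot entries, used internally by the fast model engine).
#' @examples
#' \dontrun{
#' g <- featurize("CC", n_max = 5)
#' dim(g$H)        # 5 x 124
#' g$A_sub$single  # self-loops + the C-C bond in the leading 2 x 2 block
#' }
#' @export
featurize <- function(smiles, vocab = feature_vocabulary(), n_max = NULL) {
  mol <- parse_smiles(smiles)
  featurize_parsed(mol, vocab, n_max)
}

featurize_parsed <- function(mol, vocab = feature_vocabulary(), n_max = NULL) {
  n <- mol$n_atoms
  if (is.null(n_max)) n_max <- n
  adj <- build_adjacency_set(mol, n_max)
  H <- matrix(0, n_max, vocab$D)
  feature_idx <- matrix(0L, n_max, 6)
  for (a in seq_len(n)) {
    lev <- atom_block_levels(mol$atoms[a, ], vocab)
    idx <- vocab$offsets + lev
    H[a, idx] <- 1
    feature_idx[a, ] <- as.integer(idx)
  }
  structure(
    list(H = H, A_full = adj$A_full, A_sub = adj$A_sub,
         n_atoms = n, n_max = n_max, feature_idx = feature_idx,
         source_smiles = mol$source_smiles),
    class = "molecular_graph"
  )
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular graph> ", x$source_smiles, ": ", x$n_atoms,
      " atoms padded to ", x$n_max, ", D = ", ncol(x$H), "\n", sep = "")
  invisible(x)
}

#' Featurize a set of SMILES under one shared vocabulary and padding
#'
#' Parses and featurizes a whole dataset. `n_max` defaults to the maximum
#' heavy-atom count over the inputs, which is then stored with the batch so
#' that train- and test-time featurization agree.
#'
#' @param smiles Character vector of SMILES (all parsable).
#' @param vocab A [feature_vocabulary()].
#' @param n_max Padded capacity; computed from the data when `NULL`.
#' @return A list of `molecular_graph` objects with attributes `vocab` and
#'   `n_max`.
#' @export
featurize_dataset <- function(smiles, vocab = feature_vocabulary(),
                              n_max = NULL) {
  mols <- parse_smiles_batch(smiles)
  bad <- vapply(mols, inherits, logical(1), "bondgat_parse_error")
  if (any(bad)) stop(mols[[which(bad)[1]]])
  sizes <- vapply(mols, function(m) m$n_atoms, integer(1))
  if (is.null(n_max)) n_max <- max(sizes)
  if (any(sizes > n_max)) {
    first <- which(sizes > n_max)[1]
    stop(capacity_error(smiles[first], sizes[first], n_max))
  }
  graphs <- lapply(mols, featurize_parsed, vocab = vocab, n_max = n_max)
  attr(graphs, "vocab") <- vocab
  attr(graphs, "n_max") <- n_max
  graphs
}
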