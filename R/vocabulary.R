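#' Atom feature vocabulary
#'
#' The fixed vocabulary used to one-hot encode atoms. Six blocks are
#' concatenated, in this order, into a feature vector of length
#' \eqn{D = 101 + 8 + 7 + 2 + 2 + 4 = 124}:
#'
#' 1. atomic number, 1--101;
#' 2. formal charge, \{-3, -2, -1, 0, 1, 2, 3, Extreme\} where "Extreme"
#'    collects any charge with absolute value above 3;
#' 3. hybridization, \{S, SP, SP2, SP3, SP3D, SP3D2, Other\};
#' 4. ring membership, \{No, Yes\};
#' 5. aromaticity, \{No, Yes\};
#' 6. tetrahedral chirality tag,
#'    \{Unspecified, Clockwise, Counter-clockwise, Other\}.
#'
#' The category order is fixed: it defines the meaning of every trained weight
#' matrix, so the vocabulary is stored with fitted models and embedded in
#' serialized graph batches.
#'
#' @return An object of class `bondgat_vocab`: a list with one character (or
#'   integer) vector per block, the block sizes, and the total width `D`.
#' @examples
#' v <- feature_vocabulary()
#' v$D # 124
#' @export
feature_vocabulary <- function() {
  blocks <- list(
    atomic_number = 1:101,
    formal_charge = c("-3", "-2", "-1", "0", "1", "2", "3", "Extreme"),
    hybridization = c("S", "SP", "SP2", "SP3", "SP3D", "SP3D2", "Other"),
    in_ring = c("No", "Yes"),
    aromatic = c("No", "Yes"),
    chirality = c("Unspecified", "Clockwise", "Counter-clockwise", "Other")
  )
  sizes <- vapply(blocks, length, integer(1))
  structure(
    list(
      blocks = blocks,
      sizes = sizes,
      offsets = c(0L, cumsum(sizes)[-length(sizes)]),
      D = sum(sizes)
    ),
    class = "bondgat_vocab"
  )
}

#' @export
print.bondgat_vocab <- function(x, ...) {
  cat("Atom feature vocabulary:", x$D, "binary features in", length(x$blocks),
      "one-hot blocks\n")
  for (nm in names(x$sizes)) cat(sprintf("  %-14s %d\n", nm, x$sizes[[nm]]))
  invisible(x)
}

# Per-block category index (1-based within the block) for one atom record.
# Returns an integer vector of length 6, in vocabulary block order.
atom_block_levels <- function(atom, vocab) {
  z <- as.integer(atom$atomic_number)
  if (is.na(z) || z < 1L || z > 101L) {
    stop("unsupported element: atomic number ", atom$atomic_number,
         " outside 1-101", call. = FALSE)
  }
  q <- as.integer(atom$formal_charge)
  charge_idx <- if (abs(q) > 3L) 8L else q + 4L
  hyb <- as.character(atom$hybridization)
  hyb_idx <- match(hyb, vocab$blocks$hybridization)
  if (is.na(hyb_idx)) hyb_idx <- match("Other", vocab$blocks$hybridization)
  ring_idx <- if (isTRUE(atom$in_ring) || identical(as.integer(atom$in_ring), 1L)) 2L else 1L
  arom_idx <- if (isTRUE(atom$aromatic) || identical(as.integer(atom$aromatic), 1L)) 2L else 1L
  chi <- as.character(atom$chirality)
  chi_idx <- match(chi, vocab$blocks$chirality)
  if (is.na(chi_idx)) chi_idx <- match("Other", vocab$blocks$chirality)
  c(z, charge_idx, hyb_idx, ring_idx, arom_idx, chi_idx)
}

#' One-hot encode a single atom
#'
#' Concatenates the six one-hot blocks of [feature_vocabulary()] for one atom
#' record. Out-of-list formal charges map to the "Extreme" slot; out-of-list
#' hybridizations and chirality tags map to "Other". Atomic numbers outside
#' 1--101 are a hard error: the vocabulary enumerates elements exhaustively
#' and has no catch-all slot for them.
#'
#' @param atom A list or one-row data frame with fields `atomic_number`,
#'   `formal_charge`, `hybridization`, `in_ring`, `aromatic`, `chirality`
#'   (as produced by [parse_smiles()]).
#' @param vocab A [feature_vocabulary()] object.
#' @return A binary vector of length `vocab$D` with exactly six ones.
#' @examples
#' v <- feature_vocabulary()
#' carbon <- list(atomic_number = 6, formal_charge = 0, hybridization = "SP3",
#'                in_ring = FALSE, aromatic = FALSE, chirality = "Unspecified")
#' sum(encode_atom(carbon, v)) # 6
#' @export
encode_atom <- function(atom, vocab = feature_vocabulary()) {
  lev <- atom_block_levels(atom, vocab)
  x <- numeric(vocab$D)
  x[vocab$offsets + lev] <- 1
  x
}
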