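# SMILES parsing, atom encoding and adjacency-set construction.

test_that("feature vocabulary has the fixed block structure", {
  v <- feature_vocabulary()
  expect_identical(unname(v$sizes), c(101L, 8L, 7L, 2L, 2L, 4L))
  expect_identical(v$D, 124L)
})

test_that("parse_smiles returns the expected atoms and bond classes", {
  m <- parse_smiles("C")
  expect_equal(m$n_atoms, 1L)
  expect_equal(m$atoms$atomic_number, 6L)
  expect_equal(nrow(m$bonds), 0L)

  m <- parse_smiles("C#N")
  expect_equal(m$n_atoms, 2L)
  expect_equal(m$bonds$class, "triple")

  m <- parse_smiles("c1ccccc1")
  expect_equal(m$n_atoms, 6L)
  expect_equal(nrow(m$bonds), 6L)
  expect_true(all(m$bonds$class == "aromatic"))
  expect_true(all(m$atoms$aromatic))
  expect_true(all(m$atoms$in_ring))
})

test_that("aromaticity perception is canonical, not notation-driven", {
  # benzene in Kekule form still comes out fully aromatic
  m <- parse_smiles("C1=CC=CC=C1")
  expect_true(all(m$bonds$class == "aromatic"))
})

test_that("unparsable SMILES raise a parse-failure condition with the string", {
  err <- tryCatch(parse_smiles("C((("), condition = identity)
  expect_s3_class(err, "bondgat_parse_error")
  expect_identical(err$smiles, "C(((")
})

test_that("encode_atom places exactly six ones at the documented offsets", {
  v <- feature_vocabulary()
  carbon <- list(atomic_number = 6, formal_charge = 0, hybridization = "SP3",
                 in_ring = FALSE, aromatic = FALSE,
                 chirality = "Unspecified")
  x <- encode_atom(carbon, v)
  expect_equal(sum(x), 6)
  # block offsets: Z=6 -> slot 6; charge 0 -> 4th of block 2; SP3 -> 4th of
  # block 3; No; No; Unspecified
  expect_equal(which(x == 1),
               c(6, 101 + 4, 101 + 8 + 4, 101 + 8 + 7 + 1,
                 101 + 8 + 7 + 2 + 1, 101 + 8 + 7 + 2 + 2 + 1))
})

test_that("out-of-list categories fall into Extreme/Other slots", {
  v <- feature_vocabulary()
  weird <- list(atomic_number = 15, formal_charge = 5, hybridization = "SP2D",
                in_ring = TRUE, aromatic = FALSE, chirality = "odd-tag")
  x <- encode_atom(weird, v)
  expect_equal(sum(x), 6)
  expect_equal(x[101 + 8], 1)                    # Extreme charge slot
  expect_equal(x[101 + 8 + 7], 1)                # Other hybridization slot
  expect_equal(x[v$D], 1)                        # Other chirality slot
})

test_that("elements beyond the vocabulary are a hard error", {
  v <- feature_vocabulary()
  fm <- list(atomic_number = 100, formal_charge = 0, hybridization = "SP3",
             in_ring = FALSE, aromatic = FALSE, chirality = "Unspecified")
  expect_equal(sum(encode_atom(fm, v)), 6) # fermium is still in range
  md <- fm; md$atomic_number <- 102
  expect_error(encode_atom(md, v), "unsupported element")
})

test_that("ethane adjacency matches the participation self-loop policy", {
  adj <- build_adjacency_set(parse_smiles("CC"), n_max = 2)
  expect_equal(adj$A_full, matrix(1, 2, 2))
  expect_equal(adj$A_sub$single, matrix(1, 2, 2))
  for (k in c("double", "triple", "aromatic")) {
    expect_equal(adj$A_sub[[k]], matrix(0, 2, 2))
  }
})

test_that("propyne's triple-bond substructure excludes the methyl carbon", {
  adj <- build_adjacency_set(parse_smiles("CC#C"), n_max = 3)
  tri <- matrix(0, 3, 3)
  tri[2:3, 2:3] <- 1
  expect_equal(adj$A_sub$triple, tri)
  expect_equal(adj$A_sub$single[1:2, 1:2], matrix(1, 2, 2))
})

test_that("capacity overflow names the molecule", {
  err <- tryCatch(build_adjacency_set(parse_smiles("CCCC"), n_max = 3),
                  condition = identity)
  expect_s3_class(err, "bondgat_capacity_error")
  expect_match(conditionMessage(err), "CCCC")
})

test_that("adjacency invariants hold across a varied corpus", {
  for (s in test_smiles()) {
    g <- featurize(s, n_max = parse_smiles(s)$n_atoms + 3)
    mol <- parse_smiles(s)
    n <- g$n_atoms
    all_A <- c(list(full = g$A_full), g$A_sub)
    for (A in all_A) {
      expect_equal(A, t(A))                              # symmetry
      if (n < g$n_max) {
        pad <- (n + 1):g$n_max
        expect_true(all(A[pad, ] == 0) && all(A[, pad] == 0))
      }
    }
    # full = union of substructure off-diagonals plus self-loops
    off <- function(A) { diag(A) <- 0; A }
    uni <- Reduce(`+`, lapply(g$A_sub, off))
    expect_equal(off(g$A_full) > 0, uni > 0)
    expect_equal(diag(g$A_full)[seq_len(n)], rep(1, n))
    # substructure diagonals = brute-force incidence scan of the bond list
    for (k in names(g$A_sub)) {
      incident <- rep(0, g$n_max)
      b <- mol$bonds[mol$bonds$class == k, ]
      incident[unique(c(b$i, b$j)) + 1L] <- 1
      expect_equal(diag(g$A_sub[[k]]), incident)
    }
    # one-hot structure of H
    rs <- rowSums(g$H)
    expect_equal(rs, c(rep(6, n), rep(0, g$n_max - n)))
  }
})

test_that("featurization is deterministic and padding-neutral", {
  g1 <- featurize("CC(=O)OC")
  g2 <- featurize("CC(=O)OC")
  expect_identical(g1, g2)
  n <- g1$n_atoms
  gp <- featurize("CC(=O)OC", n_max = n + 10)
  expect_equal(gp$H[seq_len(n), ], g1$H)
  expect_equal(gp$A_full[seq_len(n), seq_len(n)], g1$A_full)
  for (k in names(g1$A_sub)) {
    expect_equal(gp$A_sub[[k]][seq_len(n), seq_len(n)], g1$A_sub[[k]])
  }
})

test_that("the same molecule under different traversals gives permuted graphs", {
  g1 <- featurize("CCO")
  g2 <- featurize("OCC")
  # oxygen first vs last: same sorted feature rows, same bond-class counts
  expect_equal(g1$H[order(g1$H %*% seq_len(ncol(g1$H))), ],
               g2$H[order(g2$H %*% seq_len(ncol(g2$H))), ])
  expect_equal(sum(g1$A_sub$single), sum(g2$A_sub$single))
})

test_that("featurize_dataset shares n_max across molecules", {
  gs <- featurize_dataset(c("C", "CCCCC", "CCO"))
  expect_equal(attr(gs, "n_max"), 5L)
  expect_true(all(vapply(gs, function(g) nrow(g$H), integer(1)) == 5L))
})
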