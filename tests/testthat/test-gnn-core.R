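# Graph layers and assembled models.

test_that("attention head trivial cases behave as the definitions force", {
  W <- matrix(c(0.3, -0.2, 0.5, 0.4), 2, 2)
  a <- c(0.1, -0.3, 0.2, 0.05)
  # single node with self-loop: softmax of one element
  H1 <- matrix(c(1, -2), 1, 2)
  out <- attention_head(H1, matrix(1, 1, 1), W, a)
  expect_equal(out, leaky(H1 %*% W), tolerance = 1e-12)
  # identical rows on a complete graph: uniform attention
  H <- matrix(rep(c(0.4, 1.2), each = 4), 4, 2)
  res <- attention_head(H, matrix(1, 4, 4), W, a, return_attention = TRUE)
  expect_equal(res$lambda, matrix(0.25, 4, 4), tolerance = 1e-12)
})

test_that("attention head matches the brute-force per-node oracle", {
  set.seed(101)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    Din <- sample(2:5, 1)
    Fdim <- sample(2:4, 1)
    H <- matrix(rnorm(N * Din), N, Din)
    A <- random_adjacency(N)
    W <- matrix(rnorm(Din * Fdim), Din, Fdim)
    a <- rnorm(2 * Fdim)
    expect_equal(attention_head(H, A, W, a),
                 oracle_attention_head(H, A, W, a), tolerance = 1e-6)
  }
})

test_that("attention rows are stochastic over non-empty neighborhoods", {
  set.seed(7)
  smiles <- generate_synthetic_dataset(50, "regression", seed = 11)$smiles
  graphs <- featurize_dataset(smiles)
  Din <- ncol(graphs[[1]]$H)
  W <- matrix(rnorm(Din * 4, sd = 0.2), Din, 4)
  a <- rnorm(8, sd = 0.2)
  for (g in graphs) {
    for (A in c(list(g$A_full), g$A_sub)) {
      lam <- attention_head(g$H, A, W, a, return_attention = TRUE)$lambda
      rs <- rowSums(lam)
      nonempty <- rowSums(A) > 0
      expect_equal(rs[nonempty], rep(1, sum(nonempty)), tolerance = 1e-9)
      expect_equal(rs[!nonempty], rep(0, sum(!nonempty)))
    }
  }
})

test_that("multi-head combination obeys concat/average contracts", {
  set.seed(3)
  H <- matrix(rnorm(12), 4, 3)
  A <- random_adjacency(4)
  mk_head <- function() list(W = matrix(rnorm(12), 3, 4), a = rnorm(8))
  h1 <- mk_head()
  expect_equal(multi_head_attention(H, A, list(h1), "concat"),
               attention_head(H, A, h1$W, h1$a))
  # identical heads averaged equal any single head
  expect_equal(multi_head_attention(H, A, list(h1, h1, h1), "average"),
               attention_head(H, A, h1$W, h1$a))
  heads <- replicate(4, mk_head(), simplify = FALSE)
  expect_equal(ncol(multi_head_attention(H, A, heads, "concat")), 16)
  expect_equal(ncol(multi_head_attention(H, A, heads, "average")), 4)
  expect_error(multi_head_attention(H, A, list(), "concat"), "empty")
})

test_that("masked sum gates branch rows by substructure membership", {
  # toluene: methyl carbon is single-only, ring carbons aromatic (the
  # attachment carbon is in both substructures)
  g <- featurize("Cc1ccccc1", n_max = 9) # 7 atoms + 2 padding
  set.seed(5)
  branches <- lapply(g$A_sub, function(A) matrix(rnorm(9 * 3), 9, 3))
  out <- masked_sum(branches, g$A_sub)
  # atom 1 (methyl C): only in the single substructure
  expect_equal(out[1, ], branches$single[1, ])
  # atom 2 (attachment C): single + aromatic
  expect_equal(out[2, ], branches$single[2, ] + branches$aromatic[2, ])
  # atom 3 (pure ring C): aromatic only
  expect_equal(out[3, ], branches$aromatic[3, ])
  # padded atoms: zero rows
  expect_equal(out[8:9, ], matrix(0, 2, 3))
})

test_that("global attention pooling matches its closed forms", {
  set.seed(9)
  Hs <- matrix(rnorm(15), 3, 5)
  # zero parameters: sigmoid(0) * 0 = 0
  expect_equal(global_attention_pool(Hs, matrix(0, 5, 2), matrix(0, 5, 2),
                                     c(0, 0), c(0, 0)),
               c(0, 0))
  # single node: one gated term
  W1 <- matrix(rnorm(10), 5, 2); W2 <- matrix(rnorm(10), 5, 2)
  b1 <- rnorm(2); b2 <- rnorm(2)
  h <- Hs[1, , drop = FALSE]
  manual <- drop(1 / (1 + exp(-(h %*% W1 + rep(b1, each = 1)))) *
                   (h %*% W2 + rep(b2, each = 1)))
  expect_equal(global_attention_pool(h, W1, W2, b1, b2), manual)
  # permutation of rows (and mask) leaves the readout unchanged
  mask <- c(1, 1, 0)
  perm <- c(3, 1, 2)
  expect_equal(global_attention_pool(Hs, W1, W2, b1, b2, mask),
               global_attention_pool(Hs[perm, ], W1, W2, b1, b2, mask[perm]))
})

test_that("graph convolution matches the explicit edge-loop oracle", {
  set.seed(13)
  for (rep in 1:20) {
    N <- sample(2:6, 1)
    H <- matrix(rnorm(N * 3), N, 3)
    A <- random_adjacency(N)
    W <- matrix(rnorm(6), 3, 2)
    expect_equal(graph_convolution(H, A, W), oracle_graph_conv(H, A, W),
                 tolerance = 1e-6)
  }
  # single node with self-loop: normalization is the identity
  H1 <- matrix(c(1, 2, 3), 1, 3)
  W <- matrix(rnorm(6), 3, 2)
  expect_equal(graph_convolution(H1, matrix(1, 1, 1), W), leaky(H1 %*% W))
})

test_that("a graph convolution has fewer parameters than any K-head MHAL", {
  Din <- 32; Fdim <- 32
  gc_params <- Din * Fdim
  for (K in 1:6) {
    expect_lt(gc_params, K * (Din * Fdim + 2 * Fdim))
  }
})

test_that("model variants assemble with the documented structure", {
  n_max <- 12
  complete <- assemble_model(bondgat_config("complete"), "regression", n_max)
  whole <- assemble_model(bondgat_config("whole_molecule"), "regression",
                          n_max)
  conv <- assemble_model(bondgat_config("convolutional"), "regression",
                         n_max)
  # complete has exactly 4 substructure branches
  branch_names <- grep("^m1\\.b", names(complete$layout), value = TRUE)
  expect_equal(sort(unique(sub("^m1\\.(b\\d).*", "\\1", branch_names))),
               c("b1", "b2", "b3", "b4"))
  # whole-molecule drops module 1 entirely
  expect_length(grep("^m1\\.", names(whole$layout)), 0)
  # convolutional module 2 is strictly smaller, all other stages equal
  expect_lt(parameter_count(conv, "m2"), parameter_count(complete, "m2"))
  for (stage in c("m1", "pool", "bn", "mlp")) {
    expect_equal(parameter_count(conv, stage),
                 parameter_count(complete, stage))
  }
})

test_that("engine predictions equal the composition of the public layers", {
  graphs <- featurize_dataset(c("CC#CC", "c1ccccc1O", "C=CC"))
  for (variant in c("complete", "whole_molecule", "convolutional")) {
    for (task in c("regression", "classification")) {
      model <- assemble_model(tiny_config(variant), task,
                              n_max = attr(graphs, "n_max"), seed = 21)
      engine <- predict_graphs(model, graphs)
      composed <- vapply(graphs, function(g) compose_forward(model, g),
                         numeric(1))
      expect_equal(engine, composed, tolerance = 1e-8)
    }
  }
})

test_that("classification outputs lie strictly inside (0, 1)", {
  graphs <- featurize_dataset(test_smiles())
  model <- assemble_model(tiny_config(), "classification",
                          n_max = attr(graphs, "n_max"), seed = 2)
  p <- predict_graphs(model, graphs)
  expect_true(all(p > 0 & p < 1))
})

test_that("prediction is invariant to atom reindexing and padding", {
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1C#N", "N#Cc1ccccc1"),
                c("CC(=O)OC", "COC(=O)C"))
  for (variant in c("complete", "whole_molecule", "convolutional")) {
    model <- assemble_model(tiny_config(variant), "regression", n_max = 12,
                            seed = 4)
    for (pr in pairs) {
      g1 <- featurize(pr[1], n_max = 12)
      g2 <- featurize(pr[2], n_max = 12)
      p <- predict_graphs(model, list(g1, g2))
      expect_equal(p[1], p[2], tolerance = 1e-5)
      # padding invariance: same molecule, inflated capacity
      gpad <- featurize(pr[1], n_max = 22)
      expect_equal(predict_graphs(model, gpad), p[1], tolerance = 1e-5)
    }
  }
})

test_that("padded rows are inert: garbage features there change nothing", {
  model <- assemble_model(tiny_config(), "regression", n_max = 10, seed = 6)
  g <- featurize("CC#CC", n_max = 10)
  base <- compose_forward(model, g)
  g$H[5:10, ] <- matrix(rnorm(6 * ncol(g$H)), 6)
  expect_equal(compose_forward(model, g), base, tolerance = 1e-10)
})

test_that("analytic gradients match numerical differentiation", {
  graphs <- featurize_dataset(c("CC#C", "c1ccccc1", "C=CO"))
  for (variant in c("complete", "whole_molecule", "convolutional")) {
    cfg <- bondgat_config(variant, F = 3, K = 2, P = 4, mlp_hidden = c(5))
    model <- assemble_model(cfg, "classification",
                            n_max = attr(graphs, "n_max"), seed = 31)
    emols <- bondgat:::engine_graphs(graphs)
    ecfg <- bondgat:::engine_config(cfg, "classification", model$D)
    y <- c(1, 0, 1); sw <- c(1.2, 0.8, 1)
    th <- model$theta
    res <- bondgat:::cpp_batch_grad(emols, th, model$layout, ecfg, y, sw,
                                    model$bn_mean, model$bn_var, 0.9)
    f <- function(t) bondgat:::cpp_batch_grad(emols, t, model$layout, ecfg,
                                              y, sw, model$bn_mean,
                                              model$bn_var, 0.9)$loss
    set.seed(variant == "complete")
    idx <- sample(length(th), 40)
    num <- vapply(idx, function(i) {
      e <- 1e-5
      tp <- th; tp[i] <- tp[i] + e
      tm <- th; tm[i] <- tm[i] - e
      (f(tp) - f(tm)) / (2 * e)
    }, numeric(1))
    expect_equal(res$grad[idx], num, tolerance = 1e-4)
  }
})
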