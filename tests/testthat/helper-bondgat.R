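# Shared fixtures and independent reference implementations ("oracles").
# The oracles deliberately use naive per-node loops so they share no code
# path with the vectorized/compiled layers they are checked against.

leaky <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

# Brute-force per-node attention head: explicit neighborhood loops.
oracle_attention_head <- function(H, A, W, a, slope = 0.2) {
  Z <- H %*% W
  N <- nrow(H)
  Fdim <- ncol(W)
  out <- matrix(0, N, Fdim)
  for (j in seq_len(N)) {
    U <- which(A[j, ] != 0)
    if (length(U) == 0) next
    e <- vapply(U, function(l) leaky(sum(c(Z[j, ], Z[l, ]) * a), slope),
                numeric(1))
    lam <- exp(e - max(e))
    lam <- lam / sum(lam)
    s <- rep(0, Fdim)
    for (t in seq_along(U)) s <- s + lam[t] * Z[U[t], ]
    out[j, ] <- leaky(s, slope)
  }
  out
}

# Brute-force symmetric-normalized graph convolution: explicit edge loop
# with 1/sqrt(d_i d_j) weights.
oracle_graph_conv <- function(H, A, W, slope = 0.2) {
  M <- H %*% W
  N <- nrow(A)
  d <- rowSums(A)
  out <- matrix(0, N, ncol(W))
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (A[i, j] != 0 && d[i] > 0 && d[j] > 0) {
        out[i, ] <- out[i, ] + M[j, ] / sqrt(d[i] * d[j])
      }
    }
  }
  leaky(out, slope)
}

# Random symmetric 0/1 adjacency on N nodes; self-loops optional per node.
random_adjacency <- function(N, p_edge = 0.5, p_self = 0.7) {
  A <- matrix(0, N, N)
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      if (j < i && stats::runif(1) < p_edge) A[i, j] <- A[j, i] <- 1
    }
    if (stats::runif(1) < p_self) A[i, i] <- 1
  }
  A
}

# A small, varied bag of valid SMILES covering all four bond classes.
test_smiles <- function() {
  c("C", "CC", "CCO", "OCC", "C#N", "CC#C", "CC#CC", "C=CC", "CC=CC",
    "c1ccccc1", "Cc1ccccc1", "c1ccccc1C#N", "N#Cc1ccccc1", "CCNCC",
    "COC", "c1ccccc1Cc1ccccc1", "C=CC#C", "CC(=O)OC", "c1ccc(cc1)O")
}

# Tiny architecture used wherever a full-width model would waste time.
tiny_config <- function(variant = "complete") {
  bondgat_config(variant, F = 4, K = 2, P = 6, mlp_hidden = c(8))
}

# Compose the full forward pass out of the public R-level layers, in
# inference mode. Independent of the compiled batched engine.
compose_forward <- function(model, graph) {
  theta <- unpack_theta_for_tests(model)
  cfg <- model$config
  K <- cfg$K
  H <- graph$H
  mask <- as.numeric(rowSums(H) > 0)
  sub_names <- names(graph$A_sub)
  if (cfg$variant != "whole_molecule") {
    branches <- lapply(seq_len(4), function(k) {
      A <- graph$A_sub[[k]]
      h1 <- lapply(seq_len(K), function(h) list(
        W = theta[[sprintf("m1.b%d.l1.h%d.W", k, h)]],
        a = theta[[sprintf("m1.b%d.l1.h%d.a", k, h)]]))
      X1 <- multi_head_attention(H, A, h1, "concat", cfg$leaky_slope)
      h2 <- lapply(seq_len(K), function(h) list(
        W = theta[[sprintf("m1.b%d.l2.h%d.W", k, h)]],
        a = theta[[sprintf("m1.b%d.l2.h%d.a", k, h)]]))
      multi_head_attention(X1, A, h2, "average", cfg$leaky_slope)
    })
    names(branches) <- sub_names
    m2in <- masked_sum(branches, graph$A_sub)
  } else {
    m2in <- H
  }
  if (cfg$variant == "convolutional") {
    Hstar <- graph_convolution(m2in, graph$A_full, theta[["m2.gc.W"]],
                               cfg$leaky_slope)
  } else {
    h2 <- lapply(seq_len(K), function(h) list(
      W = theta[[sprintf("m2.h%d.W", h)]],
      a = theta[[sprintf("m2.h%d.a", h)]]))
    Hstar <- multi_head_attention(m2in, graph$A_full, h2, "concat",
                                  cfg$leaky_slope)
  }
  X <- global_attention_pool(Hstar, theta[["pool.W1"]], theta[["pool.W2"]],
                             theta[["pool.b1"]], theta[["pool.b2"]], mask)
  xhat <- (X - model$bn_mean) / sqrt(model$bn_var + 1e-5)
  cur <- theta[["bn.gamma"]] * xhat + theta[["bn.beta"]]
  n_mlp <- length(cfg$mlp_hidden) + 1L
  for (i in seq_len(n_mlp)) {
    cur <- drop(cur %*% theta[[sprintf("mlp.%d.W", i)]]) +
      theta[[sprintf("mlp.%d.b", i)]]
    if (i < n_mlp) cur <- leaky(cur, cfg$leaky_slope)
  }
  if (model$task == "classification") 1 / (1 + exp(-cur)) else cur
}

unpack_theta_for_tests <- function(model) {
  coefs <- list()
  layout <- model$layout
  for (nm in names(layout)) {
    d <- layout[[nm]]
    vals <- model$theta[d[1] + seq_len(d[2] * d[3])]
    coefs[[nm]] <- if (d[3] == 1L) vals else matrix(vals, d[2], d[3])
  }
  coefs
}
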