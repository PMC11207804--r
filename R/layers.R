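# User-facing graph layers. These wrap (or re-express in plain matrix
# algebra) the primitives the compiled training engine uses, so each layer
# can be inspected, unit-tested and composed by hand.

#' Single graph attention head
#'
#' Computes one attention head on node features `H` with neighborhoods given
#' by the rows of the 0/1 adjacency `A` (an atom attends to itself only when
#' the corresponding diagonal entry is 1):
#' \deqn{Z = H W,\quad e_{jl} = \mathrm{LeakyReLU}((z_j \oplus z_l) a^T),}
#' \deqn{\lambda_{jl} = \mathrm{softmax}_{l \in U(j)}(e_{jl}),\quad
#'   \tilde h_j = \mathrm{LeakyReLU}\left(\sum_{l \in U(j)} \lambda_{jl} z_l\right).}
#' Rows with empty neighborhoods (padded atoms, or atoms absent from a bond
#' substructure) come out identically zero.
#'
#' @param H Node feature matrix, N x D_in.
#' @param A Symmetric 0/1 adjacency matrix, N x N.
#' @param W Trainable weight matrix, D_in x F.
#' @param a Trainable attention vector of length 2F.
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @param return_attention Also return the normalized attention weights.
#' @return New node feature matrix, N x F; with `return_attention = TRUE`, a
#'   list with `output` and `lambda` (the N x N attention weight matrix,
#'   each real atom's row summing to 1 over its neighborhood).
#' @export
attention_head <- function(H, A, W, a, leaky_slope = 0.2,
                           return_attention = FALSE) {
  if (return_attention) {
    cpp_gat_head_attn(as.matrix(H), as.matrix(A), as.matrix(W),
                      as.numeric(a), leaky_slope)
  } else {
    cpp_gat_head(as.matrix(H), as.matrix(A), as.matrix(W), as.numeric(a),
                 leaky_slope)
  }
}

#' Multi-head graph attention layer
#'
#' Runs `K` independent [attention_head()]s on the same input and combines
#' them by concatenation (output width `K * F`, head order preserved) or by
#' element-wise averaging (output width `F`).
#'
#' @param H,A As in [attention_head()].
#' @param heads List of head parameter lists, each with elements `W` and `a`.
#' @param combine `"concat"` or `"average"`.
#' @param leaky_slope LeakyReLU negative slope.
#' @return Node feature matrix, N x (K*F) or N x F.
#' @export
multi_head_attention <- function(H, A, heads,
                                 combine = c("concat", "average"),
                                 leaky_slope = 0.2) {
  combine <- match.arg(combine)
  if (length(heads) == 0) stop("multi_head_attention: empty head list",
                               call. = FALSE)
  outs <- lapply(heads, function(h) {
    attention_head(H, A, h$W, h$a, leaky_slope)
  })
  if (combine == "concat") do.call(cbind, outs)
  else Reduce(`+`, outs) / length(outs)
}

#' Masked sum over bond-substructure branches
#'
#' Fuses the four per-bond-class branch outputs into one node feature
#' matrix: row `j` of the result is the sum of the branch rows gated by the
#' `j`-th diagonal element of the corresponding substructure adjacency,
#' \deqn{\hat h_j = \sum_k \tilde h_{k,j} \cdot a_{k,jj}.}
#' An atom outside every substructure (and every padded row) therefore maps
#' to a zero row.
#'
#' @param branch_outputs Named list of N x F matrices, one per bond class.
#' @param A_sub Named list of the matching substructure adjacency matrices.
#' @return N x F matrix.
#' @export
masked_sum <- function(branch_outputs, A_sub) {
  stopifnot(length(branch_outputs) == length(A_sub))
  dims <- unique(lapply(branch_outputs, dim))
  if (length(dims) != 1) {
    stop("masked_sum: branch outputs must share one shape", call. = FALSE)
  }
  out <- matrix(0, dims[[1]][1], dims[[1]][2])
  for (k in seq_along(branch_outputs)) {
    out <- out + branch_outputs[[k]] * diag(as.matrix(A_sub[[k]]))
  }
  out
}

#' Gated global attention pooling
#'
#' Order-free graph-level readout: each (real) node contributes a
#' sigmoid-gated projection, and the contributions are summed,
#' \deqn{X = \sum_j m_j\, \sigma(h^*_j W_1 + b_1) \odot (h^*_j W_2 + b_2).}
#'
#' @param H_star Node feature matrix, N x Q.
#' @param W1,W2 Q x P weight matrices.
#' @param b1,b2 Length-P bias vectors.
#' @param node_mask Length-N 0/1 vector marking real atoms (default all 1).
#' @return Numeric vector of length P.
#' @export
global_attention_pool <- function(H_star, W1, W2, b1, b2,
                                  node_mask = rep(1, nrow(H_star))) {
  H_star <- as.matrix(H_star)
  stopifnot(length(node_mask) == nrow(H_star))
  G1 <- sweep(H_star %*% W1, 2, b1, `+`)
  G2 <- sweep(H_star %*% W2, 2, b2, `+`)
  gates <- 1 / (1 + exp(-G1))
  colSums((gates * G2) * node_mask)
}

#' Graph convolution layer (ablation variant)
#'
#' Symmetric degree-normalized graph convolution with LeakyReLU activation,
#' \deqn{\mathrm{out} = \mathrm{LeakyReLU}(\tilde D^{-1/2} A \tilde D^{-1/2} H W),}
#' where \eqn{\tilde D} is the degree diagonal of `A` (self-loops included).
#' Zero-degree rows bypass the normalization and stay zero. For the same
#' input/output widths this layer has `D_in * F` trainable parameters,
#' strictly fewer than a K-head attention layer's `K * (D_in * F + 2F)`.
#'
#' @param H Node feature matrix, N x D_in.
#' @param A Adjacency with self-loops on real atoms, N x N.
#' @param W D_in x F weight matrix.
#' @param leaky_slope LeakyReLU negative slope.
#' @return N x F matrix.
#' @export
graph_convolution <- function(H, A, W, leaky_slope = 0.2) {
  cpp_graph_conv(as.matrix(H), as.matrix(A), as.matrix(W), leaky_slope)
}
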