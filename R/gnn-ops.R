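#' Graph signals
#'
#' A graph signal bundles a node feature matrix `H` (n x d), a directed
#' COO edge list `edge_index` (2 x 2m, 0-based, both directions of every
#' undirected edge present, no self-loops) and a batch assignment vector
#' mapping each node to the graph it belongs to. All layer operators in
#' this package act on graph signals.
#'
#' @param H Numeric matrix of node features (n x d).
#' @param edge_index Integer matrix (2 x E) of 0-based directed edges;
#'   may have zero columns for edgeless graphs.
#' @param batch Integer vector of length n assigning each node to a
#'   graph id in `1..n_graphs` (non-decreasing). Defaults to a single
#'   graph.
#' @return An object of class `graph_signal`.
#' @export
graph_signal <- function(H, edge_index = matrix(integer(0), nrow = 2),
                         batch = rep(1L, nrow(H))) {
  H <- as.matrix(H)
  storage.mode(edge_index) <- "integer"
  n <- nrow(H)
  if (ncol(edge_index) > 0L) {
    stopifnot(all(edge_index >= 0L), all(edge_index < n))
  }
  stopifnot(length(batch) == n)
  if (n > 1L) stopifnot(!is.unsorted(batch))
  structure(list(H = H, edge_index = edge_index, batch = as.integer(batch)),
            class = "graph_signal")
}

# 1-based source and target vectors of a signal's directed edges
edge_pairs <- function(signal) {
  list(src = signal$edge_index[1, ] + 1L, dst = signal$edge_index[2, ] + 1L)
}

# dense-free sparse adjacency (n x n, symmetric 0/1, no self-loops)
adjacency_matrix <- function(signal) {
  n <- nrow(signal$H)
  ep <- edge_pairs(signal)
  if (length(ep$src) == 0L) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  Matrix::sparseMatrix(i = ep$dst, j = ep$src, x = rep(1, length(ep$src)),
                       dims = c(n, n))
}

# S = Dtilde^{-1/2} (A + I) Dtilde^{-1/2}: normalized adjacency with self-loops
sgc_norm_adjacency <- function(signal) {
  n <- nrow(signal$H)
  A <- adjacency_matrix(signal) + Matrix::Diagonal(n)
  d <- Matrix::rowSums(A)
  Dm <- Matrix::Diagonal(n, 1 / sqrt(d))
  Dm %*% A %*% Dm
}

# Ltilde = I - L_sym = D^{-1/2} A D^{-1/2}; rows/cols of isolated nodes are 0
arma_modified_laplacian <- function(signal) {
  n <- nrow(signal$H)
  A <- adjacency_matrix(signal)
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(n, dinv)
  Dm %*% A %*% Dm
}

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

#' GIN node update
#'
#' One graph-isomorphism-network update: each node's representation
#' becomes `MLP((1 + eps) * h_v + sum of neighbor features)`. Nodes with
#' no neighbors aggregate a zero sum.
#'
#' @param signal A [graph_signal()].
#' @param params List with `eps` (scalar) and `mlp`, either `NULL` for
#'   the identity map or a list of layers, each a list `(W, b)` applied
#'   as `X %*% W + b` with ReLU between (not after) layers.
#' @return A [graph_signal()] with updated node features.
#' @export
gin_update <- function(signal, params) {
  A <- adjacency_matrix(signal)
  Z <- (1 + params$eps) * signal$H + as.matrix(A %*% signal$H)
  out <- apply_mlp(Z, params$mlp)
  graph_signal(out, signal$edge_index, signal$batch)
}

apply_mlp <- function(Z, mlp) {
  if (is.null(mlp)) return(Z)
  for (i in seq_along(mlp)) {
    Z <- sweep(Z %*% mlp[[i]]$W, 2, mlp[[i]]$b, "+")
    if (i < length(mlp)) Z <- relu(Z)
  }
  Z
}

#' GAT attention layer
#'
#' Graph-attention update: unnormalized scores
#' `e_ij = LeakyReLU(a . [W h_i || W h_j])` are softmax-normalized over
#' each target node's neighborhood and used to weight the transformed
#' neighbor features, `h'_i = sigma(sum_j a_ij W h_j)`. Self-loops are
#' added before attention so every node has a non-empty neighborhood.
#'
#' @param signal A [graph_signal()].
#' @param params List with `W` (d_in x d_out) and `a` (length
#'   2 * d_out attention vector; first half scores the target, second
#'   half the neighbor).
#' @param slope LeakyReLU negative slope (0.2).
#' @param sigma Output nonlinearity (ReLU).
#' @param add_self_loops Add i -> i edges before attention (default TRUE).
#' @return List with `attention` (tibble `src`, `dst`, `weight`; 0-based
#'   node ids; weights sum to 1 over each target) and `signal`, the
#'   updated graph signal.
#' @export
gat_attention <- function(signal, params, slope = 0.2, sigma = relu,
                          add_self_loops = TRUE) {
  n <- nrow(signal$H)
  ep <- edge_pairs(signal)
  src <- ep$src; dst <- ep$dst
  if (add_self_loops) {
    src <- c(src, seq_len(n)); dst <- c(dst, seq_len(n))
  }
  if (any(tabulate(dst, nbins = n) == 0L)) {
    stop("GAT contract error: node with empty neighborhood", call. = FALSE)
  }
  d_out <- ncol(params$W)
  Wh <- signal$H %*% params$W
  s_dst <- as.numeric(Wh %*% params$a[seq_len(d_out)])
  s_src <- as.numeric(Wh %*% params$a[d_out + seq_len(d_out)])
  e <- leaky_relu(s_dst[dst] + s_src[src], slope)
  gmax <- as.numeric(tapply(e, factor(dst, levels = seq_len(n)), max))[dst]
  ex <- exp(e - gmax)
  denom <- as.numeric(rowsum(ex, dst))[dst]
  alpha <- ex / denom
  pre <- rowsum(alpha * Wh[src, , drop = FALSE], dst)
  dimnames(pre) <- NULL
  out <- sigma(pre)
  list(attention = tibble::tibble(src = src - 1L, dst = dst - 1L,
                                  weight = alpha),
       signal = graph_signal(out, signal$edge_index, signal$batch))
}

#' ARMA graph convolution
#'
#' Output of K parallel stacks of T graph-convolutional-skip (GCS)
#' updates, `Xbar(t+1) = sigma(Ltilde Xbar(t) W(t) + X V(t))` with
#' `Ltilde = I - L` the modified (symmetric-normalized) Laplacian and
#' `X` the layer input; the layer output is the mean over the K stacks.
#'
#' @param signal A [graph_signal()].
#' @param params List with `stacks`: a list of K stacks, each a list
#'   with `W` (list of T weight matrices) and `V` (list of T skip
#'   matrices).
#' @param sigma Nonlinearity applied at each GCS step (ReLU).
#' @return A [graph_signal()] with updated node features.
#' @export
arma_layer <- function(signal, params, sigma = relu) {
  K <- length(params$stacks)
  if (K < 1L) stop("ARMA contract error: K must be >= 1", call. = FALSE)
  Lt <- arma_modified_laplacian(signal)
  X0 <- signal$H
  acc <- NULL
  for (k in seq_len(K)) {
    st <- params$stacks[[k]]
    T_ <- length(st$W)
    if (T_ < 1L) stop("ARMA contract error: T must be >= 1", call. = FALSE)
    Xb <- X0
    for (t in seq_len(T_)) {
      Xb <- sigma(as.matrix(Lt %*% Xb) %*% st$W[[t]] + X0 %*% st$V[[t]])
    }
    acc <- if (is.null(acc)) Xb else acc + Xb
  }
  graph_signal(acc / K, signal$edge_index, signal$batch)
}

#' SGC feature propagation
#'
#' Simple graph convolution: node features are propagated K times with
#' the normalized self-loop adjacency `S = Dtilde^{-1/2} (A + I)
#' Dtilde^{-1/2}` and then linearly transformed, `out = S^K X W`. No
#' softmax is applied: the result feeds a regression head.
#'
#' @param signal A [graph_signal()].
#' @param params List with `W` (d_in x d_out).
#' @param K Non-negative propagation depth.
#' @return A [graph_signal()] with updated node features.
#' @export
sgc_propagate <- function(signal, params, K = 2L) {
  stopifnot(K >= 0L)
  S <- sgc_norm_adjacency(signal)
  X <- signal$H
  for (i in seq_len(K)) X <- as.matrix(S %*% X)
  graph_signal(X %*% params$W, signal$edge_index, signal$batch)
}

#' Batch normalization
#'
#' Normalizes a minibatch of activations per channel: subtract the
#' minibatch mean, divide by the square root of the (population)
#' minibatch variance plus `eps`, then scale by `gamma` and shift by
#' `beta`.
#'
#' @param x Numeric matrix (rows = minibatch members, columns =
#'   channels) or vector (treated as one channel).
#' @param gamma,beta Scale and shift, scalar or per-channel.
#' @param eps Variance guard (default 1e-5).
#' @return Normalized activations with the shape of `x`.
#' @export
batch_norm <- function(x, gamma = 1, beta = 0, eps = 1e-5) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  m <- nrow(xm)
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  xhat <- sweep(sweep(xm, 2, mu, "-"), 2, sqrt(v + eps), "/")
  y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
  if (vec) as.numeric(y) else y
}
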