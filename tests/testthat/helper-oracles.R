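# Dense brute-force reference implementations of the layer operators,
# written directly from their defining equations with explicit loops and
# dense matrices. They are deliberately independent of the package's
# sparse/vectorized code paths.

dense_adj <- function(signal) {
  n <- nrow(signal$H)
  A <- matrix(0, n, n)
  if (ncol(signal$edge_index) > 0) {
    for (j in seq_len(ncol(signal$edge_index))) {
      A[signal$edge_index[2, j] + 1, signal$edge_index[1, j] + 1] <- 1
    }
  }
  A
}

oracle_gin <- function(signal, eps, mlp = NULL) {
  A <- dense_adj(signal)
  H <- signal$H
  Z <- matrix(0, nrow(H), ncol(H))
  for (v in seq_len(nrow(H))) {
    agg <- rep(0, ncol(H))
    for (u in seq_len(nrow(H))) if (A[v, u] == 1) agg <- agg + H[u, ]
    Z[v, ] <- (1 + eps) * H[v, ] + agg
  }
  if (!is.null(mlp)) {
    for (i in seq_along(mlp)) {
      Z <- Z %*% mlp[[i]]$W + matrix(mlp[[i]]$b, nrow(Z), length(mlp[[i]]$b),
                                     byrow = TRUE)
      if (i < length(mlp)) Z <- pmax(Z, 0)
    }
  }
  Z
}

oracle_sgc_S <- function(signal) {
  A <- dense_adj(signal)
  At <- A + diag(nrow(A))
  Dt <- diag(1 / sqrt(rowSums(At)))
  Dt %*% At %*% Dt
}

oracle_sgc <- function(signal, W, K) {
  S <- oracle_sgc_S(signal)
  X <- signal$H
  for (i in seq_len(K)) X <- S %*% X
  X %*% W
}

oracle_arma_Lt <- function(signal) {
  A <- dense_adj(signal)
  d <- rowSums(A)
  Dm <- diag(ifelse(d > 0, 1 / sqrt(d), 0), nrow(A))
  Dm %*% A %*% Dm
}

oracle_arma <- function(signal, stacks, sigma = function(x) pmax(x, 0)) {
  Lt <- oracle_arma_Lt(signal)
  X <- signal$H
  acc <- 0
  for (st in stacks) {
    Xb <- X
    for (t in seq_along(st$W)) {
      Xb <- sigma(Lt %*% Xb %*% st$W[[t]] + X %*% st$V[[t]])
    }
    acc <- acc + Xb
  }
  acc / length(stacks)
}

oracle_gat <- function(signal, W, a, slope = 0.2,
                       sigma = function(x) pmax(x, 0)) {
  A <- dense_adj(signal)
  diag(A) <- 1  # self-loops
  H <- signal$H
  n <- nrow(H)
  d_out <- ncol(W)
  Wh <- H %*% W
  out <- matrix(0, n, d_out)
  att <- matrix(0, n, n)
  lrelu <- function(x) ifelse(x > 0, x, slope * x)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    e <- vapply(nb, function(j) {
      lrelu(sum(a * c(Wh[i, ], Wh[j, ])))
    }, numeric(1))
    al <- exp(e - max(e)) / sum(exp(e - max(e)))
    att[i, nb] <- al
    s <- rep(0, d_out)
    for (k in seq_along(nb)) s <- s + al[k] * Wh[nb[k], ]
    out[i, ] <- sigma(s)
  }
  list(out = out, att = att)
}

# random connected-ish undirected graph as a graph_signal
random_signal <- function(n, d = 3, p_edge = 0.4) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p_edge
  e <- pairs[keep, , drop = FALSE]
  ei <- if (nrow(e) > 0) {
    rbind(c(e[, 1], e[, 2]), c(e[, 2], e[, 1])) - 1L
  } else matrix(integer(0), nrow = 2)
  graph_signal(matrix(stats::rnorm(n * d), n, d), ei)
}

# relabel the nodes of a graph_signal by a permutation
permute_signal <- function(signal, perm) {
  inv <- order(perm)  # new index of old node i is inv[i]
  ei <- signal$edge_index
  if (ncol(ei) > 0) ei <- matrix(as.integer(inv[ei + 1L] - 1L), nrow = 2)
  graph_signal(signal$H[perm, , drop = FALSE], ei, signal$batch[perm])
}

# relabel the atoms of a mol_graph by a permutation
permute_mol_graph <- function(g, perm) {
  inv <- order(perm)
  ei <- g$edge_index
  if (ncol(ei) > 0) ei <- matrix(as.integer(inv[ei + 1L] - 1L), nrow = 2)
  g$node_features <- g$node_features[perm, , drop = FALSE]
  g$edge_index <- ei
  g
}
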