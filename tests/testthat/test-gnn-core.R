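two_node_signal <- function(h = c(1, 2)) {
  graph_signal(matrix(h, ncol = 1), rbind(c(0L, 1L), c(1L, 0L)))
}

test_that("gin_update matches hand-evaluated aggregation", {
  iso <- graph_signal(matrix(1, 1, 1))
  expect_equal(gin_update(iso, list(eps = 0, mlp = NULL))$H,
               matrix(1, 1, 1))
  s <- two_node_signal()
  expect_equal(gin_update(s, list(eps = 0, mlp = NULL))$H,
               matrix(c(3, 3), ncol = 1))
  expect_equal(gin_update(s, list(eps = 1, mlp = NULL))$H,
               matrix(c(4, 5), ncol = 1))
})

test_that("gat attention is a normalized softmax over neighborhoods", {
  # one neighbor plus self-loop with identical features: both weights 0.5
  s <- two_node_signal(c(1, 1))
  res <- gat_attention(s, list(W = matrix(1), a = c(0.3, -0.2)))
  expect_equal(res$attention$weight, rep(0.5, 4))
  # attention sums to 1 over each target
  set.seed(5)
  sig <- random_signal(7, d = 4)
  W <- matrix(rnorm(4 * 3), 4, 3)
  res <- gat_attention(sig, list(W = W, a = rnorm(6)))
  sums <- tapply(res$attention$weight, res$attention$dst, sum)
  expect_equal(unname(as.numeric(sums)), rep(1, 7), tolerance = 1e-6)
  # softmax ratio identity: scores differing by c give weight ratio exp(c)
  e <- c(1.7, 1.7 - 0.9)
  w <- exp(e) / sum(exp(e))
  expect_equal(w[1] / w[2], exp(0.9), tolerance = 1e-12)
})

test_that("arma_layer reduces to its skip term in degenerate settings", {
  set.seed(1)
  sig <- random_signal(5, d = 3)
  V <- matrix(rnorm(6), 3, 2)
  W0 <- matrix(0, 3, 2)
  # W = 0 with identity sigma: output is XV
  out <- arma_layer(sig, list(stacks = list(list(W = list(W0), V = list(V)))),
                    sigma = identity)
  expect_equal(out$H, sig$H %*% V)
  # edgeless graph: Ltilde = 0, so output is sigma(XV)
  edgeless <- graph_signal(sig$H)
  W <- matrix(rnorm(6), 3, 2)
  out2 <- arma_layer(edgeless, list(stacks = list(list(W = list(W), V = list(V)))))
  expect_equal(out2$H, pmax(edgeless$H %*% V, 0))
  # K identical stacks equal a single stack
  st <- list(W = list(W), V = list(V))
  expect_equal(arma_layer(sig, list(stacks = list(st, st)))$H,
               arma_layer(sig, list(stacks = list(st)))$H)
  expect_error(arma_layer(sig, list(stacks = list())), "K must be")
})

test_that("sgc_propagate follows the normalized self-loop adjacency", {
  # edgeless graph: S = I for any K
  X <- matrix(c(1, 3, -2, 0.5), 2, 2)
  s <- graph_signal(X)
  W <- diag(2)
  expect_equal(sgc_propagate(s, list(W = W), K = 3)$H, X)
  # two-node single-edge graph: S has all entries 1/2
  s2 <- two_node_signal(c(1, 3))
  expect_equal(sgc_propagate(s2, list(W = matrix(1)), K = 1)$H,
               matrix(c(2, 2), ncol = 1))
  # S is idempotent for this graph, so K = 2 gives the same result
  expect_equal(sgc_propagate(s2, list(W = matrix(1)), K = 2)$H,
               matrix(c(2, 2), ncol = 1))
})

test_that("batch_norm normalizes per channel", {
  expect_equal(batch_norm(c(1, 2, 3), eps = 1e-12),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  expect_equal(batch_norm(c(5, 5, 5)), c(0, 0, 0))
  set.seed(2)
  x <- matrix(rnorm(300, mean = 4, sd = 3), 100, 3)
  y <- batch_norm(x, eps = 1e-8)
  expect_equal(unname(colMeans(y)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(y, 2, function(c) mean(c^2))), rep(1, 3),
               tolerance = 1e-3)
  # inverse affine recovers the inputs as eps -> 0
  mu <- colMeans(x)
  sd_b <- sqrt(colMeans(x^2) - mu^2)
  rec <- batch_norm(x, gamma = sd_b, beta = mu, eps = 1e-12)
  expect_equal(rec, x, tolerance = 1e-6)
})

test_that("all four layer operators agree with dense oracles on random graphs", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(2:8, 1)
    d <- sample(2:4, 1)
    sig <- random_signal(n, d)
    d_out <- sample(2:3, 1)

    # GIN with a 2-layer MLP
    eps <- rnorm(1)
    mlp <- list(list(W = matrix(rnorm(d * d_out), d, d_out), b = rnorm(d_out)),
                list(W = matrix(rnorm(d_out^2), d_out, d_out), b = rnorm(d_out)))
    expect_equal(gin_update(sig, list(eps = eps, mlp = mlp))$H,
                 oracle_gin(sig, eps, mlp), tolerance = 1e-8)

    # SGC
    W <- matrix(rnorm(d * d_out), d, d_out)
    K <- sample(0:3, 1)
    expect_equal(sgc_propagate(sig, list(W = W), K)$H,
                 oracle_sgc(sig, W, K), tolerance = 1e-8)

    # ARMA with K stacks of T steps
    Ks <- sample(1:2, 1); Ts <- sample(1:2, 1)
    stacks <- lapply(seq_len(Ks), function(k) {
      list(W = lapply(seq_len(Ts), function(t) {
             din <- if (t == 1) d else d_out
             matrix(rnorm(din * d_out), din, d_out)
           }),
           V = lapply(seq_len(Ts), function(t) matrix(rnorm(d * d_out), d, d_out)))
    })
    expect_equal(arma_layer(sig, list(stacks = stacks))$H,
                 oracle_arma(sig, stacks), tolerance = 1e-8)

    # GAT
    Wg <- matrix(rnorm(d * d_out), d, d_out)
    a <- rnorm(2 * d_out)
    got <- gat_attention(sig, list(W = Wg, a = a))
    ora <- oracle_gat(sig, Wg, a)
    expect_equal(got$signal$H, ora$out, tolerance = 1e-8)
    att_dense <- matrix(0, n, n)
    att_dense[cbind(got$attention$dst + 1, got$attention$src + 1)] <-
      got$attention$weight
    expect_equal(att_dense, ora$att, tolerance = 1e-8)
  }
})

test_that("S is symmetric with spectral radius at most 1", {
  set.seed(7)
  for (rep in 1:20) {
    sig <- random_signal(sample(2:8, 1))
    S <- as.matrix(multignn:::sgc_norm_adjacency(sig))
    expect_equal(S, t(S), tolerance = 1e-12)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    expect_lte(max(abs(ev)), 1 + 1e-10)
  }
})

test_that("layer operators are permutation equivariant", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    d <- 3; d_out <- 2
    sig <- random_signal(n, d)
    perm <- sample(n)
    psig <- permute_signal(sig, perm)

    W <- matrix(rnorm(d * d_out), d, d_out)
    a <- rnorm(2 * d_out)
    mlp <- list(list(W = W, b = rnorm(d_out)))
    st <- list(W = list(W), V = list(matrix(rnorm(d * d_out), d, d_out)))

    expect_equal(gin_update(psig, list(eps = 0.3, mlp = mlp))$H,
                 gin_update(sig, list(eps = 0.3, mlp = mlp))$H[perm, ],
                 tolerance = 1e-12)
    expect_equal(sgc_propagate(psig, list(W = W), 2)$H,
                 sgc_propagate(sig, list(W = W), 2)$H[perm, ],
                 tolerance = 1e-12)
    expect_equal(arma_layer(psig, list(stacks = list(st)))$H,
                 arma_layer(sig, list(stacks = list(st)))$H[perm, ],
                 tolerance = 1e-12)
    expect_equal(gat_attention(psig, list(W = W, a = a))$signal$H,
                 gat_attention(sig, list(W = W, a = a))$signal$H[perm, ],
                 tolerance = 1e-6)
  }
})

test_that("gin_update with identity MLP equals (A + (1+eps) I) H", {
  set.seed(13)
  for (rep in 1:10) {
    sig <- random_signal(sample(2:8, 1), d = 3)
    A <- dense_adj(sig)
    expect_equal(gin_update(sig, list(eps = 0, mlp = NULL))$H,
                 (A + diag(nrow(A))) %*% sig$H, tolerance = 1e-12)
  }
})
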