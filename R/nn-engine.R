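# Minimal reverse-mode engine for the graph regression models.
#
# A model is a list of layers; each layer is a list(kind, params, hyper,
# state). Forward passes cache exactly what their hand-derived backward
# passes need. All math is double precision.

# add/multiply a per-column vector across all rows without sweep()'s copies
addr <- function(M, v) M + rep(v, each = nrow(M))
mulr <- function(M, v) M * rep(v, each = nrow(M))

glorot <- function(fan_in, fan_out) {
  r <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -r, r), fan_in, fan_out)
}

layer_linear <- function(d_in, d_out) {
  list(kind = "linear",
       params = list(W = glorot(d_in, d_out), b = numeric(d_out)))
}
layer_relu <- function() list(kind = "relu", params = list())
layer_dropout <- function(p) list(kind = "dropout", params = list(),
                                  hyper = list(p = p))
layer_bn <- function(d, eps = 1e-5, momentum = 0.1) {
  list(kind = "bn",
       params = list(gamma = rep(1, d), beta = numeric(d)),
       hyper = list(eps = eps, momentum = momentum),
       state = list(mean = numeric(d), var = rep(1, d)))
}
layer_gin <- function(d_in, d_out) {
  list(kind = "gin",
       params = list(eps = 0,
                     W1 = glorot(d_in, d_out), b1 = numeric(d_out),
                     W2 = glorot(d_out, d_out), b2 = numeric(d_out)))
}
layer_gat <- function(d_in, d_out, heads = 1L, slope = 0.2) {
  params <- list(b = numeric(d_out))
  for (h in seq_len(heads)) {
    params[[paste0("W", h)]] <- glorot(d_in, d_out)
    params[[paste0("a", h)]] <- as.numeric(glorot(2L * d_out, 1L))
  }
  list(kind = "gat", params = params,
       hyper = list(heads = heads, slope = slope, d_out = d_out))
}
layer_arma <- function(d_in, d_out, K = 1L, T_ = 1L) {
  params <- list()
  for (k in seq_len(K)) {
    for (t in seq_len(T_)) {
      din_t <- if (t == 1L) d_in else d_out
      params[[paste0("W", k, "_", t)]] <- glorot(din_t, d_out)
      params[[paste0("V", k, "_", t)]] <- glorot(d_in, d_out)
      params[[paste0("b", k, "_", t)]] <- numeric(d_out)
    }
  }
  list(kind = "arma", params = params, hyper = list(K = K, T_ = T_))
}
layer_sgc <- function(d_in, d_out, K = 2L) {
  list(kind = "sgc", params = list(W = glorot(d_in, d_out),
                                   b = numeric(d_out)),
       hyper = list(K = K))
}
layer_pool <- function() list(kind = "pool", params = list())

# --- batch context ----------------------------------------------------------

# Stack molecule graphs into one block-diagonal batch with precomputed
# propagation matrices and the pooling operator.
prepare_graph_batch <- function(graphs, pooling = "sum") {
  ns <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  if (any(ns == 0L)) stop("empty graph in batch", call. = FALSE)
  offs <- cumsum(c(0L, ns[-length(ns)]))
  X <- do.call(rbind, lapply(graphs, function(g) g$node_features))
  ei <- do.call(cbind, lapply(seq_along(graphs), function(i) {
    e <- graphs[[i]]$edge_index
    if (ncol(e) == 0L) matrix(integer(0), nrow = 2) else e + offs[i]
  }))
  if (is.null(ei)) ei <- matrix(integer(0), nrow = 2)
  batch <- rep(seq_along(graphs), ns)
  sig <- graph_signal(X, ei, batch)
  n <- nrow(X)
  w <- if (pooling == "mean") 1 / ns[batch] else rep(1, n)
  P <- matrix(0, length(graphs), n)
  P[cbind(batch, seq_len(n))] <- w
  ep <- edge_pairs(sig)
  # dense propagation operators: molecule batches are small, and dense
  # base-matrix products avoid per-call sparse dispatch overhead
  A <- matrix(0, n, n)
  if (length(ep$src) > 0) A[cbind(ep$dst, ep$src)] <- 1
  deg <- rowSums(A)
  dt <- 1 / sqrt(deg + 1)
  S <- (A + diag(n)) * tcrossprod(dt)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  Lt <- A * tcrossprod(dinv)
  list(X = X, A = A, S = S, Lt = Lt,
       A_sp = as_dgc(A), S_sp = as_dgc(S), Lt_sp = as_dgc(Lt),
       gat_src = c(ep$src, seq_len(n)),   # with self-loops
       gat_dst = c(ep$dst, seq_len(n)),
       batch = batch, P = P, n_graphs = length(graphs),
       labels = vapply(graphs, function(g) g$label %||% NA_real_, numeric(1)))
}

# --- forward ----------------------------------------------------------------

layer_forward <- function(layer, X, ctx, mode) {
  p <- layer$params
  switch(layer$kind,
    linear = {
      list(out = addr(X %*% p$W, p$b), cache = list(X = X))
    },
    relu = list(out = pmax(X, 0), cache = list(mask = X > 0)),
    dropout = {
      if (mode == "train" && layer$hyper$p > 0) {
        mask <- (matrix(stats::runif(length(X)), nrow(X)) > layer$hyper$p) /
          (1 - layer$hyper$p)
        list(out = X * mask, cache = list(mask = mask))
      } else list(out = X, cache = list(mask = NULL))
    },
    bn = {
      eps <- layer$hyper$eps
      if (mode == "train") {
        m <- nrow(X)
        mu <- colMeans(X)
        v <- colMeans(X^2) - mu^2
        ivar <- 1 / sqrt(v + eps)
        xhat <- mulr(addr(X, -mu), ivar)
        Y <- addr(mulr(xhat, p$gamma), p$beta)
        list(out = Y, cache = list(xhat = xhat, ivar = ivar, m = m,
                                   mu = mu, v = v))
      } else {
        xhat <- mulr(addr(X, -layer$state$mean),
                     1 / sqrt(layer$state$var + eps))
        Y <- addr(mulr(xhat, p$gamma), p$beta)
        list(out = Y, cache = NULL)
      }
    },
    gin = {
      Z <- (1 + p$eps) * X + ctx$A %*% X
      L1 <- addr(Z %*% p$W1, p$b1)
      R <- pmax(L1, 0)
      Y <- addr(R %*% p$W2, p$b2)
      list(out = Y, cache = list(X = X, Z = Z, m1 = L1 > 0, R = R))
    },
    arma = {
      K <- layer$hyper$K; T_ <- layer$hyper$T_
      stacks <- vector("list", K)
      acc <- NULL
      for (k in seq_len(K)) {
        Xb <- X
        steps <- vector("list", T_)
        for (t in seq_len(T_)) {
          LXb <- ctx$Lt %*% Xb
          Z <- addr(LXb %*% p[[paste0("W", k, "_", t)]] +
                      X %*% p[[paste0("V", k, "_", t)]],
                    p[[paste0("b", k, "_", t)]])
          steps[[t]] <- list(LXb = LXb, mask = Z > 0)
          Xb <- pmax(Z, 0)
        }
        stacks[[k]] <- steps
        acc <- if (is.null(acc)) Xb else acc + Xb
      }
      list(out = acc / K, cache = list(X = X, stacks = stacks))
    },
    gat = {
      heads <- layer$hyper$heads; d_out <- layer$hyper$d_out
      slope <- layer$hyper$slope
      src <- ctx$gat_src; dst <- ctx$gat_dst
      hcaches <- vector("list", heads)
      pre <- NULL
      for (h in seq_len(heads)) {
        W <- p[[paste0("W", h)]]; a <- p[[paste0("a", h)]]
        Wh <- X %*% W
        s_dst <- as.numeric(Wh %*% a[seq_len(d_out)])
        s_src <- as.numeric(Wh %*% a[d_out + seq_len(d_out)])
        elin <- s_dst[dst] + s_src[src]
        e <- ifelse(elin > 0, elin, slope * elin)
        gmax <- as.numeric(tapply(e, factor(dst, levels = seq_len(nrow(X))),
                                  max))[dst]
        ex <- exp(e - gmax)
        denom <- as.numeric(rowsum(ex, dst))[dst]
        alpha <- ex / denom
        ph <- rowsum(alpha * Wh[src, , drop = FALSE], dst)
        dimnames(ph) <- NULL
        hcaches[[h]] <- list(Wh = Wh, elin = elin, alpha = alpha, pre = ph)
        pre <- if (is.null(pre)) ph else pre + ph
      }
      pre <- addr(pre / heads, p$b)
      list(out = pmax(pre, 0),
           cache = list(X = X, heads = hcaches, mask = pre > 0,
                        src = src, dst = dst))
    },
    sgc = {
      K <- layer$hyper$K
      XK <- X
      for (i in seq_len(K)) XK <- ctx$S %*% XK
      list(out = addr(XK %*% p$W, p$b), cache = list(XK = XK))
    },
    pool = list(out = ctx$P %*% X, cache = NULL),
    stop("unknown layer kind: ", layer$kind)
  )
}

engine_forward <- function(model, ctx, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- ctx$X
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    fw <- layer_forward(model$layers[[i]], X, ctx, mode)
    caches[[i]] <- fw$cache
    X <- fw$out
  }
  list(pred = as.numeric(X), caches = caches)
}

# --- backward ---------------------------------------------------------------

layer_backward <- function(layer, dY, cache, ctx) {
  p <- layer$params
  switch(layer$kind,
    linear = list(dX = dY %*% t(p$W),
                  grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    relu = list(dX = dY * cache$mask, grads = list()),
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = list())
      else list(dX = dY * cache$mask, grads = list())
    },
    bn = {
      m <- cache$m
      dxhat <- mulr(dY, p$gamma)
      sum_dxhat <- colSums(dxhat)
      sum_dxhat_xhat <- colSums(dxhat * cache$xhat)
      dX <- mulr(m * dxhat - rep(sum_dxhat, each = m) -
                   mulr(cache$xhat, sum_dxhat_xhat),
                 cache$ivar / m)
      list(dX = dX,
           grads = list(gamma = colSums(dY * cache$xhat), beta = colSums(dY)))
    },
    gin = {
      dR <- dY %*% t(p$W2)
      dL1 <- dR * cache$m1
      dZ <- dL1 %*% t(p$W1)
      dX <- (1 + p$eps) * dZ + ctx$A %*% dZ  # A symmetric
      list(dX = dX,
           grads = list(eps = sum(dZ * cache$X),
                        W1 = crossprod(cache$Z, dL1), b1 = colSums(dL1),
                        W2 = crossprod(cache$R, dY), b2 = colSums(dY)))
    },
    arma = {
      K <- layer$hyper$K; T_ <- layer$hyper$T_
      X0 <- cache$X
      grads <- list()
      dX <- matrix(0, nrow(X0), ncol(X0))
      for (k in seq_len(K)) {
        steps <- cache$stacks[[k]]
        dXb <- dY / K
        for (t in rev(seq_len(T_))) {
          Wname <- paste0("W", k, "_", t); Vname <- paste0("V", k, "_", t)
          dZ <- dXb * steps[[t]]$mask
          grads[[Wname]] <- crossprod(steps[[t]]$LXb, dZ)
          grads[[Vname]] <- crossprod(X0, dZ)
          grads[[paste0("b", k, "_", t)]] <- colSums(dZ)
          dX <- dX + dZ %*% t(p[[Vname]])
          dXb <- ctx$Lt %*% (dZ %*% t(p[[Wname]]))  # Lt symmetric
        }
        dX <- dX + dXb  # Xbar(0) is the layer input
      }
      list(dX = dX, grads = grads)
    },
    gat = {
      heads <- layer$hyper$heads; d_out <- layer$hyper$d_out
      slope <- layer$hyper$slope
      src <- cache$src; dst <- cache$dst
      X <- cache$X
      dpre_b <- dY * cache$mask
      dpre <- dpre_b / heads
      grads <- list(b = colSums(dpre_b))
      dX <- matrix(0, nrow(X), ncol(X))
      for (h in seq_len(heads)) {
        hc <- cache$heads[[h]]
        W <- p[[paste0("W", h)]]; a <- p[[paste0("a", h)]]
        a1 <- a[seq_len(d_out)]; a2 <- a[d_out + seq_len(d_out)]
        dmsg <- dpre[dst, , drop = FALSE]
        dWh <- rowsum(hc$alpha * dmsg, src)
        dalpha <- rowSums(hc$Wh[src, , drop = FALSE] * dmsg)
        t1 <- hc$alpha * dalpha
        gsum <- as.numeric(rowsum(t1, dst))[dst]
        de <- t1 - hc$alpha * gsum
        dl <- de * ifelse(hc$elin > 0, 1, slope)
        ds_dst <- as.numeric(rowsum(dl, dst))
        ds_src <- as.numeric(rowsum(dl, src))
        dWh <- dWh + outer(ds_dst, a1) + outer(ds_src, a2)
        grads[[paste0("W", h)]] <- crossprod(X, dWh)
        grads[[paste0("a", h)]] <- c(colSums(hc$Wh * ds_dst),
                                     colSums(hc$Wh * ds_src))
        dX <- dX + dWh %*% t(W)
      }
      list(dX = dX, grads = grads)
    },
    sgc = {
      K <- layer$hyper$K
      dXK <- dY %*% t(p$W)
      for (i in seq_len(K)) dXK <- ctx$S %*% dXK  # S symmetric
      list(dX = dXK, grads = list(W = crossprod(cache$XK, dY),
                                  b = colSums(dY)))
    },
    pool = list(dX = crossprod(ctx$P, dY), grads = list()),
    stop("unknown layer kind: ", layer$kind)
  )
}

engine_backward <- function(model, caches, ctx, dpred) {
  dX <- matrix(dpred, ncol = 1)
  grads <- vector("list", length(model$layers))
  for (i in rev(seq_along(model$layers))) {
    bw <- layer_backward(model$layers[[i]], dX, caches[[i]], ctx)
    grads[[i]] <- bw$grads
    dX <- bw$dX
  }
  grads
}

# update BN running statistics from the caches of a training forward pass
engine_update_bn <- function(model, caches) {
  for (i in seq_along(model$layers)) {
    if (model$layers[[i]]$kind == "bn" && !is.null(caches[[i]])) {
      mom <- model$layers[[i]]$hyper$momentum
      st <- model$layers[[i]]$state
      model$layers[[i]]$state$mean <- (1 - mom) * st$mean + mom * caches[[i]]$mu
      model$layers[[i]]$state$var <- (1 - mom) * st$var + mom * caches[[i]]$v
    }
  }
  model
}

# --- flat parameter layout --------------------------------------------------

# All layer parameters are packed into one numeric vector with a fixed
# index map; the optimizer (in-place Adam, compiled) and the fused
# forward/backward pass both address parameters through it.
adam_map <- function(model) {
  map <- list(); off <- 0L
  for (i in seq_along(model$layers)) {
    prm <- model$layers[[i]]$params
    for (nm in names(prm)) {
      len <- length(prm[[nm]])
      map[[length(map) + 1L]] <- list(layer = i, name = nm, off = off,
                                      len = len, dim = dim(prm[[nm]]))
      off <- off + len
    }
  }
  list(entries = map, total = off)
}

pack_values <- function(entries, getter) {
  out <- vector("list", length(entries))
  for (j in seq_along(entries)) out[[j]] <- getter(entries[[j]])
  unlist(out, use.names = FALSE)
}

with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# --- compiled execution path ------------------------------------------------
# The training loop runs the fused C++ forward/backward over a flat
# parameter vector; the R layer implementations above remain the
# reference path (predict/forward and the equivalence tests use them).

engine_plan <- function(model, map = adam_map(model)) {
  plan <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    par <- list()
    hyper <- switch(l$kind,
      bn = list(eps = l$hyper$eps),
      dropout = list(p = l$hyper$p),
      arma = list(K = l$hyper$K, T = l$hyper$T_),
      gat = list(heads = l$hyper$heads, slope = l$hyper$slope,
                 d_out = l$hyper$d_out),
      sgc = list(K = l$hyper$K),
      list())
    plan[[i]] <- list(kind = l$kind, par = par, hyper = hyper)
  }
  for (e in map$entries) {
    d <- e$dim %||% c(e$len, 1L)
    plan[[e$layer]]$par[[e$name]] <- as.integer(c(e$off, d[1], d[2]))
  }
  plan
}

pack_theta <- function(model, map) {
  pack_values(map$entries, function(e) model$layers[[e$layer]]$params[[e$name]])
}

unpack_theta <- function(model, map, theta) {
  for (e in map$entries) {
    val <- theta[(e$off + 1L):(e$off + e$len)]
    if (!is.null(e$dim)) dim(val) <- e$dim
    model$layers[[e$layer]]$params[[e$name]] <- val
  }
  model
}

bn_state_list <- function(model) {
  lapply(model$layers, function(l) {
    if (l$kind == "bn") list(mean = l$state$mean, var = l$state$var) else NULL
  })
}

dropout_mask_list <- function(model, n_nodes) {
  masks <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$kind == "dropout" && l$hyper$p > 0) {
      width <- model$config$gnn_hidden
      masks[[i]] <- (stats::runif(n_nodes * width) > l$hyper$p) /
        (1 - l$hyper$p)
    }
  }
  masks
}

# C++-path forward over a prepared batch (used by the training loop)
engine_forward_cpp <- function(plan, ctx, theta, bn_state, mode = "eval",
                               masks = NULL, labels = NULL) {
  .engine_run_cpp(plan, ctx, theta, bn_state,
                  masks %||% vector("list", length(plan)),
                  mode == "train", !is.null(labels),
                  labels %||% numeric(0))
}

# general (non-symmetric-storage) column-compressed sparse matrix; the
# C++ engine requires dgCMatrix, not the dsCMatrix that symmetric dense
# matrices coerce to by default
as_dgc <- function(M) {
  nz <- which(M != 0, arr.ind = TRUE)
  Matrix::sparseMatrix(i = nz[, 1], j = nz[, 2], x = M[nz],
                       dims = dim(M))
}
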