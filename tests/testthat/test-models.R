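test_that("build_model is seeded and validates its configuration", {
  cfg <- model_config("GIAN", seed = 1)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$layers, m2$layers)
  expect_error(model_config("FOO"), "unknown architecture")
  # single-layer baselines share the same head
  mg <- build_model(model_config("GIN", seed = 2))
  kinds <- vapply(mg$layers, function(l) l$kind, character(1))
  expect_equal(kinds, c("gin", "pool", "linear", "relu", "linear", "relu",
                        "linear", "relu", "linear"))
})

test_that("composite architectures chain the expected blocks", {
  kinds <- function(a) vapply(build_model(model_config(a, seed = 1))$layers,
                              function(l) l$kind, character(1))
  expect_equal(kinds("GIAN")[1:4], c("gin", "bn", "arma", "dropout"))
  expect_equal(kinds("GIAT")[1:4], c("gin", "bn", "gat", "dropout"))
  expect_equal(kinds("SGCA")[1:4], c("sgc", "bn", "arma", "dropout"))
  # FC head widths 100 -> 200 -> 300 -> 200 -> 1, last layer unactivated
  m <- build_model(model_config("GIAN", seed = 1))
  lin <- Filter(function(l) l$kind == "linear", m$layers)
  expect_equal(vapply(lin, function(l) dim(l$params$W), integer(2)),
               matrix(c(100, 200, 200, 300, 300, 200, 200, 1), 2))
  expect_equal(m$layers[[length(m$layers)]]$kind, "linear")
})

test_that("readout pools per graph and is order invariant", {
  H <- matrix(1:6, 3, 2)
  sig <- graph_signal(H, batch = c(1L, 1L, 2L))
  expect_equal(readout(sig, "sum"), rbind(colSums(H[1:2, ]), H[3, ]))
  expect_equal(readout(sig, "mean"), rbind(colMeans(H[1:2, ]), H[3, ]))
  # single-node graph: embedding equals the node row
  one <- graph_signal(matrix(c(3, 7), 1, 2))
  expect_equal(readout(one, "sum"), matrix(c(3, 7), 1, 2))
})

test_that("forward is deterministic in eval mode and repeats across copies", {
  d <- tiny_compounds()
  m <- build_model(model_config("GIAN", seed = 4))
  p1 <- forward(m, d)
  p2 <- forward(m, d)
  expect_identical(p1, p2)
  # repeated molecule gives equal predictions
  rep3 <- d[c(3, 3, 3), ]
  pr <- forward(m, rep3)
  expect_equal(pr, rep(pr[1], 3))
  # mismatched feature width is rejected
  bad <- d$graph[[1]]
  bad$node_features <- bad$node_features[, 1:10, drop = FALSE]
  expect_error(forward(m, list(bad)), "width mismatch")
})

test_that("predictions are invariant to atom relabeling", {
  d <- synthetic_benchmark()[1:50, ]
  set.seed(8)
  for (arch in c("GIAN", "GIAT", "SGCA")) {
    m <- build_model(model_config(arch, seed = 6))
    orig <- forward(m, d)
    permuted <- lapply(d$graph, function(g) {
      permute_mol_graph(g, sample(nrow(g$node_features)))
    })
    perm <- forward(m, permuted)
    expect_equal(perm, orig, tolerance = 1e-5)
  }
})

test_that("analytic gradients match finite differences on a 3-molecule batch", {
  d <- tiny_compounds()[c(3, 4, 5), ]
  g <- d$graph
  for (i in 1:3) g[[i]]$label <- d$pic50[i]
  ctx <- multignn:::prepare_graph_batch(g, "mean")
  loss_at <- function(model) {
    f <- multignn:::engine_forward(model, ctx, "train")
    mean((f$pred - ctx$labels)^2)
  }
  for (arch in c("GIAN", "GIAT", "SGCA")) {
    cfg <- model_config(arch, gnn_hidden = 10, dropout_arma = 0,
                        dropout_gat = 0, seed = 3)
    m <- build_model(cfg)
    fw <- multignn:::engine_forward(m, ctx, "train")
    resid <- fw$pred - ctx$labels
    grads <- multignn:::engine_backward(m, fw$caches, ctx,
                                        2 * resid / length(resid))
    set.seed(17)
    for (li in seq_along(m$layers)) {
      for (nm in names(m$layers[[li]]$params)) {
        p <- m$layers[[li]]$params[[nm]]
        for (j in sample(length(p), min(3, length(p)))) {
          h <- 1e-6
          mp <- m; mp$layers[[li]]$params[[nm]][j] <- p[j] + h
          mm <- m; mm$layers[[li]]$params[[nm]][j] <- p[j] - h
          fd <- (loss_at(mp) - loss_at(mm)) / (2 * h)
          an <- grads[[li]][[nm]][j]
          # parameters feeding straight into batch norm have exactly
          # zero gradient; there the central difference only carries
          # truncation noise, so tiny gradients are compared absolutely
          if (abs(fd) < 1e-6 && abs(an) < 1e-6) {
            expect_lt(abs(fd - an), 1e-6)
          } else {
            expect_lt(abs(fd - an) / (abs(fd) + abs(an)), 1e-4)
          }
        }
      }
    }
  }
})

test_that("each architecture can fit a small noiseless dataset", {
  # pure capacity check: dropout off, single batch (keeps the batch-norm
  # statistics consistent between training and evaluation), final-epoch
  # weights, and the error measured on the molecules actually trained on
  d <- noiseless_50()
  for (arch in c("GIAN", "GIAT", "SGCA")) {
    fit <- train_gnn(d, model_config(arch, dropout_arma = 0,
                                     dropout_gat = 0, seed = 1),
                     train_config(max_epochs = 1000, patience = 999,
                                  batch_size = 64, restore_best = FALSE,
                                  seed = 1))
    trained <- d[-fit$val_idx, ]
    expect_lt(rmse(predict(fit, trained), trained$pic50), 0.1)
  }
})

test_that("the compiled training path matches the reference layers exactly", {
  d <- tiny_compounds()
  g <- d$graph
  for (i in seq_along(g)) g[[i]]$label <- d$pic50[i]
  ctx <- multignn:::prepare_graph_batch(g, "mean")
  for (arch in c("GIAN", "GIAT", "SGCA", "GIN", "GAT", "ARMA", "SGC")) {
    m <- build_model(model_config(arch, gnn_hidden = 12, dropout_arma = 0,
                                  dropout_gat = 0, seed = 9))
    map <- multignn:::adam_map(m)
    plan <- multignn:::engine_plan(m, map)
    theta <- multignn:::pack_theta(m, map)
    bs <- multignn:::bn_state_list(m)
    fwR <- multignn:::engine_forward(m, ctx, "train")
    resid <- fwR$pred - ctx$labels
    gR <- multignn:::engine_backward(m, fwR$caches, ctx,
                                     2 * resid / length(resid))
    gvR <- multignn:::pack_values(map$entries,
                                  function(e) gR[[e$layer]][[e$name]])
    resC <- multignn:::engine_forward_cpp(plan, ctx, theta, bs, "train",
                                          labels = ctx$labels)
    expect_equal(resC$pred, fwR$pred, tolerance = 1e-12)
    expect_equal(resC$grad, gvR, tolerance = 1e-12)
    # eval path too
    evR <- multignn:::engine_forward(m, ctx, "eval")$pred
    evC <- multignn:::engine_forward_cpp(plan, ctx, theta, bs, "eval")$pred
    expect_equal(evC, evR, tolerance = 1e-12)
  }
})
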