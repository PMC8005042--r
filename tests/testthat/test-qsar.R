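# brute-force two-pass Pearson correlation straight from the
# sums-of-products formula
brute_corr <- function(m) {
  p <- ncol(m); n <- nrow(m)
  out <- matrix(NA_real_, p, p, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      x <- m[, i]; y <- m[, j]
      num <- n * sum(x * y) - sum(x) * sum(y)
      den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
      out[i, j] <- num / den
    }
  }
  out
}

random_table <- function(n = 30, p = 6, seed = 1) {
  set.seed(seed)
  d <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(d) <- paste0("d", seq_len(p))
  descriptor_table(cbind(id = paste0("c", seq_len(n)), d),
                   labels = rnorm(n))
}

test_that("correlation_matrix matches a brute-force implementation", {
  tab <- random_table(40, 7, seed = 11)
  cm <- correlation_matrix(tab)
  expect_equal(cm, brute_corr(as.matrix(tibble::as_tibble(tab))),
               tolerance = 1e-10)
  expect_equal(unname(diag(cm)), rep(1, 7))
  expect_equal(cm, t(cm))
})

test_that("correlation handles duplicates, negation and zero variance", {
  df <- tibble::tibble(id = paste0("c", 1:20), a = rnorm(20))
  df$b <- df$a
  df$c <- -df$a
  df$z <- rep(2, 20)
  tab <- descriptor_table(df)
  expect_warning(cm <- correlation_matrix(tab), "zero-variance")
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], -1)
  expect_true(all(is.na(cm["z", ])))
})

test_that("independent columns are near-orthogonal at n = 1000", {
  set.seed(42)
  m <- matrix(rnorm(1000 * 12), 1000, 12)
  colnames(m) <- paste0("d", 1:12)
  cm <- correlation_matrix(m)
  off <- abs(cm[upper.tri(cm)])
  expect_gte(mean(off < 0.1), 0.95)
})

test_that("variance_filter keeps columns above the threshold", {
  df <- tibble::tibble(id = paste0("c", 1:50),
                       const = rep(1, 50),
                       tiny = rnorm(50, sd = sqrt(0.005)),
                       ok = rnorm(50, sd = sqrt(0.02)),
                       big = rnorm(50, sd = 2))
  tab <- descriptor_table(df)
  filtered <- variance_filter(tab, 0.01)
  expect_false("const" %in% names(filtered))
  expect_true("big" %in% names(filtered))
  # a column engineered to variance 0.02 survives the 0.01 cutoff
  v <- scale(rnorm(50))[, 1] * sqrt(0.02)
  tab2 <- descriptor_table(tibble::tibble(id = paste0("c", 1:50), v = v))
  expect_true("v" %in% names(variance_filter(tab2, 0.01)))
  expect_error(variance_filter(descriptor_table(
    tibble::tibble(id = "a", k = 1)), 0.01), "every descriptor")
})

test_that("standardize centers, scales, transfers and inverts", {
  tab <- random_table(40, 5, seed = 2)
  st <- standardize(tab)
  m <- as.matrix(tibble::as_tibble(st))
  expect_equal(unname(colMeans(m)), rep(0, 5), tolerance = 1e-8)
  expect_equal(unname(apply(m, 2, sd)), rep(1, 5), tolerance = 1e-8)
  tr <- attr(st, "transform")
  # re-applying the fitted transform to already-standardized data is a
  # genuine second affine map, not the identity
  twice <- apply_standardize(st, tr)
  expect_false(isTRUE(all.equal(as.matrix(tibble::as_tibble(twice)), m)))
  # the inverse transform recovers the original values
  back <- apply_standardize(st, tr, inverse = TRUE)
  expect_equal(as.matrix(tibble::as_tibble(back)),
               unname(as.matrix(tibble::as_tibble(tab))), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("lasso recovers a planted signal among decoys", {
  set.seed(77)
  n <- 200
  col_a <- rnorm(n)
  decoys <- matrix(rnorm(n * 20), n, 20,
                   dimnames = list(NULL, paste0("decoy", 1:20)))
  y <- 3 * col_a + rnorm(n, sd = 0.01)
  df <- tibble::tibble(id = paste0("c", 1:n), col_a = col_a)
  df <- dplyr::bind_cols(df, tibble::as_tibble(decoys))
  tab <- standardize(descriptor_table(df, labels = y))
  sel <- lasso_select(tab, seed = 1)
  expect_true("col_a" %in% sel)
  expect_gte(mean(!paste0("decoy", 1:20) %in% sel), 0.9)
  # infinite penalty shrinks everything away
  expect_warning(sel0 <- lasso_select(tab, lambda = 1e6, seed = 1),
                 "zero")
  expect_length(sel0, 0)
  expect_error(lasso_select(tab, labels = rep(1, n)), "degenerate|zero")
})

test_that("pca_project orders components and matches an SVD oracle", {
  # data on an (almost exact) 1-D line: first component explains
  # everything; an infinitesimal second direction keeps the rank at 2
  set.seed(3)
  t1 <- rnorm(30)
  df <- tibble::tibble(id = paste0("c", 1:30), a = t1, b = 2 * t1,
                       c = -t1 + 1e-8 * rnorm(30))
  p <- pca_project(descriptor_table(df), 2)
  expect_gte(p$explained[1], 1 - 1e-10)
  # isotropic noise: near-equal explained variance
  big <- descriptor_table(tibble::tibble(id = paste0("c", 1:2000),
                                         x = rnorm(2000), y = rnorm(2000),
                                         z = rnorm(2000)))
  pb <- pca_project(standardize(big), 3)
  expect_lt(max(pb$explained) - min(pb$explained), 0.1)
  expect_true(all(diff(pb$explained) <= 1e-12))
  # scores match a direct SVD up to sign
  tab <- standardize(random_table(25, 4, seed = 9))
  m <- as.matrix(tibble::as_tibble(tab))
  sv <- svd(m)
  p2 <- pca_project(tab, 2)
  for (k in 1:2) {
    sc <- sv$u[, k] * sv$d[k]
    expect_equal(abs(cor(p2$scores[[k + 1]], sc)), 1, tolerance = 1e-8)
  }
  expect_error(pca_project(descriptor_table(
    tibble::tibble(id = c("a", "b"), x = c(1, 2), y = c(2, 4))), 3),
    "rank")
})

test_that("random forest fits a deterministic function and is seeded", {
  set.seed(5)
  n <- 200
  x <- runif(n, -2, 2)
  df <- tibble::tibble(id = paste0("c", 1:n), x = x,
                       noise = rnorm(n))
  y <- sin(2 * x) + 0.5 * x
  tab <- descriptor_table(df, labels = y)
  f1 <- fit_rf(tab)
  expect_gte(f1$metrics$r_squared, 0.95)
  f2 <- fit_rf(tab)
  expect_identical(f1$fitted, f2$fitted)
})

test_that("svr respects its epsilon tube and learns linear labels", {
  set.seed(6)
  n <- 100
  # labels within +/- epsilon of a constant: near-flat model
  df <- tibble::tibble(id = paste0("c", 1:n), x = rnorm(n))
  yc <- 5 + runif(n, -0.09, 0.09)
  fc <- fit_svr(descriptor_table(df, labels = yc))
  expect_lte(fc$metrics$rmse, 0.1 + 0.0017)
  # duplicating the training rows of a zero-loss fit changes nothing:
  # every point sits inside the tube, so the duplicated problem has the
  # same (minimum-norm) solution
  df2 <- tibble::tibble(id = paste0("d", 1:(2 * n)), x = rep(df$x, 2))
  fc2 <- fit_svr(descriptor_table(df2, labels = rep(yc, 2)))
  expect_equal(fc2$predict(tibble::tibble(x = c(-1, 0, 1))),
               fc$predict(tibble::tibble(x = c(-1, 0, 1))),
               tolerance = 1e-6)
  # exact linear labels generalize to a held-out 20%
  set.seed(61)
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- x %*% c(0.2, -0.3, 0.15)
  idx <- sample(n, 20)
  tr <- descriptor_table(cbind(id = paste0("c", 1:80),
                               as.data.frame(x[-idx, ])),
                         labels = y[-idx])
  trs <- standardize(tr)
  fit <- fit_svr(trs)
  te <- apply_standardize(as.data.frame(x[idx, ]), attr(trs, "transform"))
  pred <- fit$predict(te)
  expect_gte(r_squared(pred, y[idx]), 0.8)
  # away from the zero-loss regime duplication re-weights the loss term
  # (effectively doubling the cost parameter), so predictions are only
  # required to stay close, not identical
  dup <- descriptor_table(
    cbind(id = paste0("d", 1:160), as.data.frame(x[c(1:80, 1:80), ])),
    labels = y[c(1:80, 1:80)])
  fit_dup <- fit_svr(standardize(dup))
  pred_dup <- fit_dup$predict(te)
  expect_lt(max(abs(pred_dup - pred)), 0.2)
})

test_that("descriptor_table drops rows with missing values", {
  df <- tibble::tibble(id = c("a", "b", "c"), x = c(1, NA, 3),
                       y = c(1, 2, 3))
  expect_message(tab <- descriptor_table(df, labels = c(1, 2, 3)),
                 "dropping 1")
  expect_equal(nrow(tab), 2)
  expect_equal(attr(tab, "labels"), c(1, 3))
})
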