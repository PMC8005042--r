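#' Training configuration
#'
#' @param learning_rate Adam learning rate (0.001).
#' @param max_epochs Maximum training epochs (1000).
#' @param patience Early-stopping patience: training halts once the
#'   monitored validation RMSE has not improved (strict decrease by
#'   more than 1e-6) for this many consecutive epochs (60).
#' @param batch_size Number of molecules per minibatch (32).
#' @param test_fraction Held-out test fraction for [split_dataset()]
#'   (0.2).
#' @param val_fraction Fraction of the training partition held out as
#'   the validation set monitored by early stopping (0.1).
#' @param cv_folds Folds for [cross_validate()] (10).
#' @param restore_best Return the parameters of the best validation
#'   epoch (default). `FALSE` keeps the final-epoch parameters, which
#'   is what a pure capacity / overfitting experiment wants.
#' @param seed Master seed; the data split, batch order, parameter
#'   initialization and dropout draws all flow from it.
#' @return A `train_config` object.
#' @export
train_config <- function(learning_rate = 0.001, max_epochs = 1000L,
                         patience = 60L, batch_size = 32L,
                         test_fraction = 0.2, val_fraction = 0.1,
                         cv_folds = 10L, restore_best = TRUE, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            patience < max_epochs, cv_folds >= 2L)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 test_fraction = test_fraction,
                 val_fraction = val_fraction,
                 cv_folds = as.integer(cv_folds),
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Random train/test split
#'
#' @param data A data frame of compounds (any columns; rows are split).
#' @param test_fraction Fraction assigned to the test set; the test set
#'   size is `round(test_fraction * n)`.
#' @param seed Seed making the split reproducible.
#' @return List with `train` and `test` tibbles forming a disjoint
#'   cover of the input rows.
#' @export
split_dataset <- function(data, test_fraction = 0.2, seed = 1L) {
  n <- nrow(data)
  stopifnot(n >= 1L)
  n_test <- round(test_fraction * n)
  if (n_test < 1L || n_test >= n) {
    stop("test_fraction ", test_fraction, " yields an empty split for n = ",
         n, call. = FALSE)
  }
  idx <- with_preserved_seed(seed, sample.int(n, n_test))
  list(train = tibble::as_tibble(data[-idx, , drop = FALSE]),
       test = tibble::as_tibble(data[idx, , drop = FALSE]))
}

#' Root-mean-square error
#' @param predicted,observed Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    stop("rmse: vectors must have equal length >= 1", call. = FALSE)
  }
  sqrt(mean((predicted - observed)^2))
}

#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot` with `SS_tot` taken about the observed
#' mean.
#' @inheritParams rmse
#' @return A real number no greater than 1.
#' @export
r_squared <- function(predicted, observed) {
  if (length(predicted) != length(observed)) {
    stop("r_squared: length mismatch", call. = FALSE)
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("r_squared undefined: observations have zero variance",
                        call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Pearson correlation coefficient
#'
#' Computed from the sums-of-products form
#' `r = (N sum(xy) - sum(x) sum(y)) / (sqrt(N sum(x^2) - sum(x)^2) *
#' sqrt(N sum(y^2) - sum(y)^2))`.
#' @param x,y Equal-length numeric vectors of length >= 2 with nonzero
#'   variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("pearson_r: vectors must have equal length >= 2", call. = FALSE)
  }
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  d1 <- n * sum(x^2) - sum(x)^2
  d2 <- n * sum(y^2) - sum(y)^2
  if (d1 <= 0 || d2 <= 0) {
    stop("pearson_r undefined: zero variance", call. = FALSE)
  }
  num / (sqrt(d1) * sqrt(d2))
}

#' Regression metrics bundle
#' @inheritParams rmse
#' @return Tibble with `rmse`, `r_squared`, `pearson_r` and `n`.
#' @export
regression_metrics <- function(predicted, observed) {
  tibble::tibble(rmse = rmse(predicted, observed),
                 r_squared = r_squared(predicted, observed),
                 pearson_r = pearson_r(predicted, observed),
                 n = length(observed))
}

#' Train a graph regression model
#'
#' Minimizes mean-squared error with Adam. A seeded fraction of the
#' training rows is held out as a validation set; after every epoch the
#' validation RMSE is evaluated (deterministic mode) and training stops
#' early once it has not improved for `patience` consecutive epochs.
#' The parameters from the best validation epoch are restored.
#'
#' @param data Tibble with a `graph` list-column (labels are read from
#'   each graph; see [featurize_compounds()]) and a `pic50` column.
#' @param config A [model_config()].
#' @param tc A [train_config()].
#' @return A `multignn_fit`: the trained model, per-epoch `history`
#'   tibble (`epoch`, `train_loss`, `val_rmse`), `best_epoch`,
#'   `epochs_run`, `val_idx` (row indices of the internal validation
#'   holdout) and the configurations.
#' @export
train_gnn <- function(data, config = model_config("GIAN"),
                      tc = train_config()) {
  stopifnot(nrow(data) >= 4L)
  graphs <- as_graph_list(data)
  labels <- data$pic50
  for (i in seq_along(graphs)) graphs[[i]]$label <- labels[i]

  with_preserved_seed(tc$seed, {
    n <- length(graphs)
    n_val <- max(1L, round(tc$val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    order_tr <- sample(tr_idx)
    nb <- ceiling(length(order_tr) / tc$batch_size)
    batch_of <- rep(seq_len(nb), each = tc$batch_size)[seq_along(order_tr)]
    batches <- lapply(split(order_tr, batch_of), function(ix) {
      prepare_graph_batch(graphs[ix], config$pooling)
    })
    val_ctx <- prepare_graph_batch(graphs[val_idx], config$pooling)
    val_y <- labels[val_idx]

    model <- build_model(config)
    map <- adam_map(model)
    plan <- engine_plan(model, map)
    theta <- pack_theta(model, map)
    adam_m <- numeric(map$total); adam_v <- numeric(map$total)
    bn_state <- bn_state_list(model)
    bn_layers <- which(vapply(model$layers, function(l) l$kind == "bn",
                              logical(1)))
    bn_mom <- if (length(bn_layers)) model$layers[[bn_layers[1]]]$hyper$momentum
              else 0.1

    best <- Inf; best_theta <- theta; best_bn <- bn_state; best_epoch <- 0L
    since_best <- 0L; step <- 0L
    history <- vector("list", tc$max_epochs)

    for (epoch in seq_len(tc$max_epochs)) {
      epoch_loss <- 0
      for (b in batches) {
        masks <- dropout_mask_list(model, nrow(b$X))
        res <- engine_forward_cpp(plan, b, theta, bn_state, "train",
                                  masks, labels = b$labels)
        if (!is.finite(res$loss)) {
          stop("training aborted: non-finite loss at epoch ", epoch,
               call. = FALSE)
        }
        step <- step + 1L
        .adam_update_cpp(theta, res$grad, adam_m, adam_v, step,
                         tc$learning_rate, 0.9, 0.999, 1e-8)
        for (bi in bn_layers) {
          bn_state[[bi]]$mean <- (1 - bn_mom) * bn_state[[bi]]$mean +
            bn_mom * res$bn_mu[[bi]]
          bn_state[[bi]]$var <- (1 - bn_mom) * bn_state[[bi]]$var +
            bn_mom * res$bn_var[[bi]]
        }
        epoch_loss <- epoch_loss + res$loss * length(b$labels)
      }
      val_pred <- engine_forward_cpp(plan, val_ctx, theta, bn_state)$pred
      val_rmse <- rmse(val_pred, val_y)
      history[[epoch]] <- c(epoch = epoch,
                            train_loss = epoch_loss / length(order_tr),
                            val_rmse = val_rmse)
      if (best - val_rmse > 1e-6) {
        best <- val_rmse; best_epoch <- epoch
        best_theta <- theta + 0  # force a copy: theta is updated in place
        best_bn <- bn_state
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
      }
      if (since_best >= tc$patience) break
    }
    history <- tibble::as_tibble(do.call(rbind, history[!vapply(history, is.null,
                                                                logical(1))]))
    if (!isTRUE(tc$restore_best)) {
      best_theta <- theta
      best_bn <- bn_state
    }
    model <- unpack_theta(model, map, best_theta)
    for (bi in bn_layers) model$layers[[bi]]$state <- best_bn[[bi]]
    structure(list(model = model, config = config, train_config = tc,
                   history = history, best_epoch = best_epoch,
                   epochs_run = nrow(history),
                   val_rmse = best, val_idx = sort(val_idx)),
              class = "multignn_fit")
  })
}

#' @export
print.multignn_fit <- function(x, ...) {
  cat("<multignn_fit> ", x$config$architecture,
      ": ", x$epochs_run, " epochs (best ", x$best_epoch,
      "), validation RMSE ", signif(x$val_rmse, 4), "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy multignn_fit
#' @export
tidy.multignn_fit <- function(x, ...) x$history

#' @method glance multignn_fit
#' @export
glance.multignn_fit <- function(x, ...) {
  tibble::tibble(architecture = x$config$architecture,
                 epochs_run = x$epochs_run, best_epoch = x$best_epoch,
                 val_rmse = x$val_rmse, seed = x$train_config$seed)
}

#' K-fold cross-validation over candidate configurations
#'
#' Partitions the data into near-equal folds (sizes differ by at most
#' one); every fold is validated exactly once per candidate, and the
#' configuration with the lowest mean validation RMSE is selected.
#'
#' @param data Tibble with `graph` and `pic50` columns.
#' @param configs List of [model_config()] candidates.
#' @param folds Number of folds (default 10).
#' @param tc A [train_config()] used for each fold's fit.
#' @param seed Seed for the fold assignment.
#' @return List with `best_config`, `metrics` (tibble: `candidate`,
#'   `architecture`, `fold`, `rmse`) and `summary` (mean RMSE per
#'   candidate).
#' @export
cross_validate <- function(data, configs, folds = 10L,
                           tc = train_config(), seed = 1L) {
  if (length(configs) == 0L) stop("empty candidate list", call. = FALSE)
  n <- nrow(data)
  stopifnot(folds <= n)
  fold_id <- with_preserved_seed(seed,
    sample(rep(seq_len(folds), length.out = n)))
  rows <- list()
  for (ci in seq_along(configs)) {
    for (f in seq_len(folds)) {
      tr <- data[fold_id != f, , drop = FALSE]
      va <- data[fold_id == f, , drop = FALSE]
      fit <- train_gnn(tr, configs[[ci]], tc)
      pred <- predict(fit, va)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        candidate = ci, architecture = configs[[ci]]$architecture,
        fold = f, rmse = rmse(pred, va$pic50))
    }
  }
  metrics <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(dplyr::group_by(metrics, .data$candidate,
                                              .data$architecture),
                              mean_rmse = mean(.data$rmse), .groups = "drop")
  best <- summary$candidate[which.min(summary$mean_rmse)]
  list(best_config = configs[[best]], metrics = metrics, summary = summary,
       fold_id = fold_id)
}
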