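# 2D-QSAR descriptor pipeline: correlation diagnostics, variance
# filtering, standardization, Lasso feature selection, PCA, and the
# random-forest / support-vector baseline regressors.
#
# The canonical order is: variance_filter -> standardize -> lasso_select
# -> model fit, with every transform fitted on training data only and
# re-applied to new compounds.

#' Assemble a descriptor table
#'
#' @param data Data frame whose first column is `id`, remaining columns
#'   numeric descriptors; rows with missing descriptor values are
#'   dropped (with a message).
#' @param labels Numeric pIC50 vector aligned with `data`, or the name
#'   of a column of `data` holding the labels.
#' @return A `descriptor_table`: tibble of descriptors with attributes
#'   `ids` and `labels`.
#' @export
descriptor_table <- function(data, labels = NULL) {
  stopifnot("id" %in% names(data))
  if (is.character(labels) && length(labels) == 1L) {
    lab <- data[[labels]]
    data <- data[, setdiff(names(data), labels), drop = FALSE]
  } else {
    lab <- labels
  }
  desc <- data[, setdiff(names(data), "id"), drop = FALSE]
  stopifnot(all(vapply(desc, is.numeric, logical(1))))
  keep <- stats::complete.cases(desc)
  if (!all(keep)) {
    message("dropping ", sum(!keep), " row(s) with missing descriptors")
  }
  structure(tibble::as_tibble(desc[keep, , drop = FALSE]),
            ids = data$id[keep],
            labels = if (!is.null(lab)) lab[keep] else NULL,
            class = c("descriptor_table", class(tibble::tibble())))
}

dt_matrix <- function(table) {
  m <- as.matrix(tibble::as_tibble(table))
  rownames(m) <- attr(table, "ids")
  m
}

dt_labels <- function(table, labels = NULL) {
  if (!is.null(labels)) labels else attr(table, "labels")
}

rewrap <- function(df, template) {
  structure(tibble::as_tibble(df),
            ids = attr(template, "ids"),
            labels = attr(template, "labels"),
            class = class(template))
}

#' Pairwise Pearson correlation matrix of descriptors
#'
#' @param table A [descriptor_table()] (or plain data frame of numeric
#'   columns).
#' @return Symmetric matrix of Pearson correlations with unit diagonal;
#'   entries involving zero-variance descriptors are `NA` and flagged
#'   with a warning.
#' @export
correlation_matrix <- function(table) {
  m <- if (inherits(table, "descriptor_table")) dt_matrix(table) else
    as.matrix(table)
  stopifnot(nrow(m) >= 2L)
  zero_var <- apply(m, 2, stats::var) == 0
  cm <- suppressWarnings(stats::cor(m))
  if (any(zero_var)) {
    warning("zero-variance descriptor(s): ",
            paste(colnames(m)[zero_var], collapse = ", "),
            "; correlations set to NA")
    cm[zero_var, ] <- NA_real_
    cm[, zero_var] <- NA_real_
  }
  diag(cm) <- ifelse(zero_var, NA_real_, 1)
  cm
}

#' Drop low-variance descriptors
#'
#' Keeps descriptors whose variance (computed before any
#' standardization) exceeds `threshold`.
#'
#' @param table A [descriptor_table()].
#' @param threshold Variance cutoff (default 0.01).
#' @return The filtered `descriptor_table`.
#' @export
variance_filter <- function(table, threshold = 0.01) {
  m <- dt_matrix(table)
  v <- apply(m, 2, stats::var)
  keep <- !is.na(v) & v > threshold   # single-row tables have NA variance
  if (!any(keep)) stop("variance_filter removed every descriptor",
                       call. = FALSE)
  rewrap(tibble::as_tibble(table)[, keep, drop = FALSE], table)
}

#' Standardize descriptors to zero mean and unit variance
#'
#' @param table A [descriptor_table()] whose columns all have nonzero
#'   variance (apply [variance_filter()] first).
#' @return The standardized `descriptor_table` with a `transform`
#'   attribute (`center`, `scale`) reusable on new compounds via
#'   [apply_standardize()] and invertible via `inverse = TRUE`.
#' @export
standardize <- function(table) {
  m <- dt_matrix(table)
  center <- colMeans(m)
  scale <- apply(m, 2, stats::sd)
  if (any(scale == 0)) stop("zero-variance column; filter before standardizing",
                            call. = FALSE)
  out <- rewrap(tibble::as_tibble(sweep(sweep(m, 2, center), 2, scale, "/")),
                table)
  attr(out, "transform") <- list(center = center, scale = scale)
  out
}

#' Apply (or invert) a fitted standardization
#'
#' @param table A data frame or `descriptor_table` with the same
#'   columns the transform was fitted on.
#' @param transform The `transform` attribute of a [standardize()]
#'   result.
#' @param inverse If `TRUE`, map standardized values back to the
#'   original scale.
#' @return Transformed table of the same shape.
#' @export
apply_standardize <- function(table, transform, inverse = FALSE) {
  m <- if (inherits(table, "descriptor_table")) dt_matrix(table) else
    as.matrix(table)
  m <- m[, names(transform$center), drop = FALSE]
  out <- if (inverse) {
    sweep(sweep(m, 2, transform$scale, "*"), 2, transform$center, "+")
  } else {
    sweep(sweep(m, 2, transform$center), 2, transform$scale, "/")
  }
  if (inherits(table, "descriptor_table")) rewrap(tibble::as_tibble(out), table)
  else tibble::as_tibble(out)
}

#' Lasso feature selection
#'
#' Fits an L1-penalized linear regression of the labels on the
#' (standardized) descriptors, with the penalty chosen by internal
#' cross-validation over glmnet's logarithmic grid, and returns the
#' descriptors with nonzero coefficients at the selected penalty.
#'
#' @param table A standardized [descriptor_table()].
#' @param labels Numeric labels (defaults to the table's `labels`
#'   attribute).
#' @param nfolds Internal CV folds for the penalty (default 5).
#' @param lambda Optional fixed penalty overriding the CV choice.
#' @param seed Seed for the CV fold assignment.
#' @return Character vector of selected descriptor names (empty, with a
#'   warning, if the penalty shrinks every coefficient to zero).
#' @export
lasso_select <- function(table, labels = NULL, nfolds = 5L, lambda = NULL,
                         seed = 1L) {
  m <- dt_matrix(table)
  y <- dt_labels(table, labels)
  if (is.null(y)) stop("no labels supplied", call. = FALSE)
  if (stats::var(y) == 0) stop("degenerate labels: zero variance",
                               call. = FALSE)
  fit <- with_preserved_seed(seed, {
    if (is.null(lambda)) {
      cv <- glmnet::cv.glmnet(m, y, alpha = 1, nfolds = nfolds)
      glmnet::glmnet(m, y, alpha = 1, lambda = cv$lambda.min)
    } else {
      glmnet::glmnet(m, y, alpha = 1, lambda = lambda)
    }
  })
  coefs <- as.numeric(stats::coef(fit))[-1]
  sel <- colnames(m)[coefs != 0]
  if (length(sel) == 0L) warning("lasso penalty shrank every coefficient to zero")
  sel
}

#' PCA projection of a descriptor table
#'
#' Diagnostic projection of (standardized) descriptors onto the top
#' principal components.
#'
#' @param table A standardized [descriptor_table()].
#' @param n_components 2 or 3.
#' @return List with `scores` (tibble, one column per component plus
#'   `id`), `explained` (variance fractions, non-increasing) and the
#'   `prcomp` object.
#' @export
pca_project <- function(table, n_components = 2L) {
  stopifnot(n_components %in% c(2L, 3L))
  m <- dt_matrix(table)
  pc <- stats::prcomp(m, center = FALSE, scale. = FALSE)
  rank <- sum(pc$sdev > 1e-10)
  if (n_components > rank) {
    stop("n_components exceeds the rank (", rank, ") of the table",
         call. = FALSE)
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  scores <- tibble::add_column(scores, id = attr(table, "ids") %||%
                                 seq_len(nrow(scores)), .before = 1)
  list(scores = scores, explained = explained[seq_len(n_components)],
       prcomp = pc)
}

#' Random-forest baseline regressor
#'
#' An ensemble of fully grown regression trees with 225 trees,
#' considering all descriptors at every split (`mtry = p`), fitted
#' under a fixed seed.
#'
#' @param table A [descriptor_table()] (typically filtered,
#'   standardized and Lasso-selected).
#' @param labels Numeric labels (defaults to the table attribute).
#' @param n_estimators Number of trees (225).
#' @param seed Seed for the forest's bootstrap draws (2).
#' @return A `qsar_fit` with elements `model`, `predict` (function of a
#'   new descriptor table), `fitted` and `metrics`
#'   ([regression_metrics()] on the training data).
#' @export
fit_rf <- function(table, labels = NULL, n_estimators = 225L, seed = 2L) {
  m <- dt_matrix(table)
  y <- dt_labels(table, labels)
  stopifnot(nrow(m) >= 10L, !is.null(y))
  model <- with_preserved_seed(seed, {
    randomForest::randomForest(x = m, y = y, ntree = n_estimators,
                               mtry = ncol(m), nodesize = 1)
  })
  fitted <- as.numeric(stats::predict(model, m))
  new_qsar_fit("rf", model, colnames(m), fitted, y)
}

#' Support-vector baseline regressor
#'
#' Radial-basis-kernel epsilon-SVR with the solver tolerance and
#' epsilon-tube width fixed at 0.0017 and 0.1. The solver is
#' deterministic for fixed inputs; a `seed` argument is accepted and
#' recorded for interface fidelity only.
#'
#' @inheritParams fit_rf
#' @param tol Solver termination tolerance (0.0017).
#' @param epsilon Epsilon-tube half-width (0.1).
#' @param seed Recorded but without effect (55).
#' @return A `qsar_fit`; see [fit_rf()].
#' @export
fit_svr <- function(table, labels = NULL, tol = 0.0017, epsilon = 0.1,
                    seed = 55L) {
  m <- dt_matrix(table)
  y <- dt_labels(table, labels)
  stopifnot(!is.null(y))
  model <- e1071::svm(x = m, y = y, type = "eps-regression",
                      kernel = "radial", tolerance = tol, epsilon = epsilon,
                      scale = FALSE, fitted = FALSE)
  fitted <- svr_predict(model, m)
  new_qsar_fit("svr", model, colnames(m), fitted, y)
}

# epsilon-SVR prediction that tolerates a model with no support vectors
# (every training point inside the epsilon tube): the decision function
# is then the constant -rho
svr_predict <- function(model, m) {
  if (isTRUE(model$tot.nSV == 0)) return(rep(-model$rho, nrow(m)))
  as.numeric(stats::predict(model, m))
}

new_qsar_fit <- function(kind, model, features, fitted, y) {
  structure(list(
    kind = kind, model = model, features = features, fitted = fitted,
    observed = y,
    predict = function(newtable) {
      nm <- if (inherits(newtable, "descriptor_table")) dt_matrix(newtable)
            else as.matrix(newtable)
      nm <- nm[, features, drop = FALSE]
      if (kind == "svr") svr_predict(model, nm)
      else as.numeric(stats::predict(model, nm))
    },
    metrics = regression_metrics(fitted, y)),
    class = "qsar_fit")
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat("<qsar_fit> ", toupper(x$kind), " on ", length(x$features),
      " descriptors; train RMSE ", signif(x$metrics$rmse, 4),
      ", R^2 ", signif(x$metrics$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' @method glance qsar_fit
#' @export
glance.qsar_fit <- function(x, ...) {
  tibble::add_column(x$metrics, model = toupper(x$kind), .before = 1)
}

#' @method tidy qsar_fit
#' @export
tidy.qsar_fit <- function(x, ...) {
  tibble::tibble(id = names(x$fitted) %||% seq_along(x$fitted),
                 observed = x$observed, fitted = x$fitted)
}
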