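#' Model configuration
#'
#' Describes one of the seven regression architectures. The composite
#' ("multi-GNN") models chain two different graph-layer operators with
#' batch normalization between them; the single-layer models serve as
#' baselines. Every architecture ends in pooled readout followed by the
#' same fully connected head (100 -> 200 -> 300 -> 200 -> 1, ReLU
#' between layers, no activation on the last).
#'
#' * `GIAN`: GIN block + BN + ARMA block (dropout 0.35 after ARMA)
#' * `GIAT`: GIN block + BN + GAT block (dropout 0.06 after GAT)
#' * `SGCA`: SGC block + BN + ARMA block (dropout 0.35 after ARMA)
#' * `GIN`, `GAT`, `ARMA`, `SGC`: one block of the named kind
#'
#' @param architecture One of `"GIAN"`, `"GIAT"`, `"SGCA"`, `"GIN"`,
#'   `"GAT"`, `"ARMA"`, `"SGC"`.
#' @param gnn_hidden Width of every graph block (default 100, which is
#'   also the input width of the fully connected head).
#' @param dropout_arma,dropout_gat Dropout rates applied to the output
#'   of ARMA (0.35) and GAT (0.06) blocks, training mode only.
#' @param arma_K,arma_T Number of parallel ARMA stacks and GCS depth.
#' @param sgc_K SGC propagation depth.
#' @param gat_heads Number of attention heads (head outputs averaged).
#' @param pooling `"mean"` (default) or `"sum"` readout; mean pooling
#'   normalizes the graph embedding for molecule size, which
#'   generalizes markedly better on small training sets.
#' @param in_width Node feature width (46, the atom feature schema).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(architecture = c("GIAN", "GIAT", "SGCA",
                                          "GIN", "GAT", "ARMA", "SGC"),
                         gnn_hidden = 100L,
                         dropout_arma = 0.35, dropout_gat = 0.06,
                         arma_K = 1L, arma_T = 1L, sgc_K = 2L,
                         gat_heads = 1L, pooling = c("mean", "sum"),
                         in_width = 46L, seed = 1L) {
  if (length(architecture) == 1L && !architecture %in%
      c("GIAN", "GIAT", "SGCA", "GIN", "GAT", "ARMA", "SGC")) {
    stop("unknown architecture: '", architecture, "'", call. = FALSE)
  }
  architecture <- match.arg(architecture)
  pooling <- match.arg(pooling)
  structure(list(architecture = architecture,
                 gnn_hidden = as.integer(gnn_hidden),
                 fc_widths = c(200L, 300L, 200L, 1L),
                 dropout_arma = dropout_arma, dropout_gat = dropout_gat,
                 arma_K = as.integer(arma_K), arma_T = as.integer(arma_T),
                 sgc_K = as.integer(sgc_K), gat_heads = as.integer(gat_heads),
                 pooling = pooling, in_width = as.integer(in_width),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Build an (untrained) model from a configuration
#'
#' Instantiates the layer stack for the configured architecture with
#' Glorot-uniform parameter initialization seeded from `config$seed`,
#' so the same configuration always yields identical initial
#' parameters.
#'
#' @param config A [model_config()].
#' @return A `multignn_model` object (layer stack + config).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  d_in <- config$in_width; d_h <- config$gnn_hidden
  with_preserved_seed(config$seed, {
    gnn <- switch(config$architecture,
      GIAN = list(layer_gin(d_in, d_h), layer_bn(d_h),
                  layer_arma(d_h, d_h, config$arma_K, config$arma_T),
                  layer_dropout(config$dropout_arma)),
      GIAT = list(layer_gin(d_in, d_h), layer_bn(d_h),
                  layer_gat(d_h, d_h, config$gat_heads),
                  layer_dropout(config$dropout_gat)),
      SGCA = list(layer_sgc(d_in, d_h, config$sgc_K), layer_bn(d_h),
                  layer_arma(d_h, d_h, config$arma_K, config$arma_T),
                  layer_dropout(config$dropout_arma)),
      GIN = list(layer_gin(d_in, d_h)),
      GAT = list(layer_gat(d_in, d_h, config$gat_heads),
                 layer_dropout(config$dropout_gat)),
      ARMA = list(layer_arma(d_in, d_h, config$arma_K, config$arma_T),
                  layer_dropout(config$dropout_arma)),
      SGC = list(layer_sgc(d_in, d_h, config$sgc_K)))
    widths <- c(d_h, config$fc_widths)
    head <- list()
    for (i in seq_len(length(widths) - 1L)) {
      head <- c(head, list(layer_linear(widths[i], widths[i + 1L])))
      if (i < length(widths) - 1L) head <- c(head, list(layer_relu()))
    }
    structure(list(layers = c(gnn, list(layer_pool()), head),
                   config = config, version = "1"),
              class = "multignn_model")
  })
}

#' @export
print.multignn_model <- function(x, ...) {
  cat("<multignn_model> ", x$config$architecture,
      " (", length(x$layers), " layers, hidden ", x$config$gnn_hidden,
      ", pooling ", x$config$pooling, ")\n", sep = "")
  invisible(x)
}

#' Pooled readout of a graph signal
#'
#' Reduces per-node embeddings to one embedding row per graph by
#' summing (default) or averaging node rows within each graph.
#'
#' @param signal A [graph_signal()].
#' @param pooling `"sum"` or `"mean"`.
#' @return Matrix with `n_graphs` rows.
#' @export
readout <- function(signal, pooling = c("sum", "mean")) {
  pooling <- match.arg(pooling)
  n <- nrow(signal$H)
  counts <- tabulate(signal$batch)
  if (any(counts == 0L)) stop("empty graph in batch", call. = FALSE)
  w <- if (pooling == "mean") 1 / counts[signal$batch] else rep(1, n)
  P <- Matrix::sparseMatrix(i = signal$batch, j = seq_len(n), x = w,
                            dims = c(max(signal$batch), n))
  as.matrix(P %*% signal$H)
}

#' Forward pass of a model over a batch of molecular graphs
#'
#' @param model A `multignn_model` (from [build_model()]) or
#'   `multignn_fit` (from [train_gnn()]).
#' @param graphs A list of `mol_graph` objects or a tibble with a
#'   `graph` list-column.
#' @param mode `"eval"` (deterministic; dropout off, batch norm uses
#'   running statistics) or `"train"`.
#' @return Numeric vector with one predicted pIC50 per graph.
#' @export
forward <- function(model, graphs, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (inherits(model, "multignn_fit")) model <- model$model
  graphs <- as_graph_list(graphs)
  ok <- vapply(graphs, function(g) ncol(g$node_features) == model$config$in_width,
               logical(1))
  if (!all(ok)) stop("node feature width mismatch", call. = FALSE)
  ctx <- prepare_graph_batch(graphs, model$config$pooling)
  engine_forward(model, ctx, mode)$pred
}

as_graph_list <- function(graphs) {
  if (is.data.frame(graphs)) graphs <- graphs$graph
  if (inherits(graphs, "mol_graph")) graphs <- list(graphs)
  stopifnot(all(vapply(graphs, inherits, logical(1), "mol_graph")))
  graphs
}

#' @export
predict.multignn_fit <- function(object, newdata, ...) {
  forward(object$model, newdata, mode = "eval")
}
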