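#' Benchmark the multi-GNN models on a compounds CSV
#'
#' End-to-end evaluation harness for a real inhibitor dataset (for
#' example the 532-compound DHODH set retrievable from ChEMBL): reads a
#' compounds CSV with columns `id`, `smiles` and `ic50_nM` or `pic50`,
#' featurizes it, makes a seeded 80/20 train/test split, trains the
#' requested architectures across seeds and reports seed-averaged train
#' and test metrics.
#'
#' @param compounds A data frame (or path to a CSV) with columns `id`,
#'   `smiles` and `ic50_nM` or `pic50`.
#' @param architectures Architectures to benchmark.
#' @param seeds Integer vector of seeds to average over.
#' @param tc A [train_config()]; its `test_fraction` drives the split.
#' @param out Optional path to write the metrics as JSON.
#' @return Tibble with one row per architecture and seed plus the
#'   seed-averaged summary rows (`seed = NA`): columns `architecture`,
#'   `seed`, `rmse_train`, `rmse_test`, `r2_train`, `r2_test`,
#'   `epochs_run`.
#' @export
benchmark_architectures <- function(compounds,
                                    architectures = c("GIAN", "GIAT", "SGCA"),
                                    seeds = 1:3,
                                    tc = train_config(),
                                    out = NULL) {
  if (is.character(compounds)) {
    compounds <- utils::read.csv(compounds, stringsAsFactors = FALSE)
  }
  d <- featurize_compounds(compounds)
  rows <- list()
  for (arch in architectures) {
    for (s in seeds) {
      tcs <- tc; tcs$seed <- as.integer(s)
      sp <- split_dataset(d, tc$test_fraction, seed = s)
      fit <- train_gnn(sp$train, model_config(arch, seed = s), tcs)
      ptr <- predict(fit, sp$train); pte <- predict(fit, sp$test)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        architecture = arch, seed = s,
        rmse_train = rmse(ptr, sp$train$pic50),
        rmse_test = rmse(pte, sp$test$pic50),
        r2_train = r_squared(ptr, sp$train$pic50),
        r2_test = r_squared(pte, sp$test$pic50),
        epochs_run = fit$epochs_run)
    }
  }
  per_seed <- dplyr::bind_rows(rows)
  summary <- dplyr::summarise(
    dplyr::group_by(per_seed, .data$architecture),
    seed = NA_integer_,
    rmse_train = mean(.data$rmse_train), rmse_test = mean(.data$rmse_test),
    r2_train = mean(.data$r2_train), r2_test = mean(.data$r2_test),
    epochs_run = mean(.data$epochs_run), .groups = "drop")
  res <- dplyr::bind_rows(per_seed, summary)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res, out, dataframe = "rows", na = "null",
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
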