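# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a small featurized molecule set with hand-picked functional diversity
tiny_compounds <- function() {
  cached("tiny_compounds", {
    featurize_compounds(tibble::tibble(
      id = paste0("M", 1:8),
      smiles = c("C", "CC", "CCO", "c1ccccc1", "CC(=O)[O-]", "C[NH3+]",
                 "C1CC1CN", "c1ccc2[nH]ccc2c1"),
      pic50 = c(4.0, 4.1, 4.9, 4.3, 5.3, 4.5, 4.8, 4.4)))
  })
}

# the default synthetic benchmark dataset (n = 200, sigma = 0.2, seed 7)
synthetic_benchmark <- function() {
  cached("synthetic_benchmark", make_synthetic_dataset(synthetic_spec()))
}

# a labeled 50-molecule noiseless set for capacity checks
noiseless_50 <- function() {
  cached("noiseless_50",
         make_synthetic_dataset(synthetic_spec(n_molecules = 50, seed = 21,
                                               sigma = 0)))
}
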