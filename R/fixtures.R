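# Deterministic synthetic-molecule generators. A fragment grammar over
# curated, concatenation-safe SMILES pieces guarantees chemical
# validity without any valence-repair pass, while covering the atom
# symbols, ring sizes 3-8, aromatic/aliphatic systems and formal
# charges that the 46-slot atom schema encodes.

# middle fragments: begin with an atom that accepts a preceding single
# bond and leave an open attachment point at their last atom
synth_mid_fragments <- function() {
  c("C", "CC", "CCC", "C(C)C", "O", "N", "S", "CO", "CN",
    "C1CC1", "C1CCC1", "C1CCCC1", "C1CCCCC1", "C1CCCCCC1", "C1CCCCCCC1",
    "c1ccccc1", "c1ccncc1", "c1ccsc1", "c1ccoc1", "c1cc[nH]c1",
    "C(=O)N", "C(=O)O")
}

# terminal caps: consume the open attachment point (single-bond atoms,
# charged groups, hypervalent centers)
synth_cap_fragments <- function() {
  c("F", "Cl", "Br", "I", "C#N", "C(=O)[O-]", "C[NH3+]", "[O-]",
    "OP(=O)(O)O", "[Si](C)(C)C", "S(=O)(=O)O", "C(F)(F)F")
}

#' Specification of a synthetic compound library
#'
#' Defines a deterministic library of valid drug-like SMILES and the
#' synthetic activity model used to label them:
#' `pIC50 = b0 + b1 * (#N + #O) + b2 * #aromatic_atoms + b3 * #rings +
#' noise`, with Gaussian noise of standard deviation `sigma`.
#'
#' @param n_molecules Library size.
#' @param seed Master seed: the same spec reproduces the identical
#'   dataset bit for bit.
#' @param sigma Activity noise standard deviation (pIC50 units).
#' @param beta Coefficients `(b0, b1, b2, b3)`; defaults
#'   `(4.0, 0.4, 0.05, -0.1)` place labels in a realistic 4-8 pIC50
#'   range.
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_molecules = 200L, seed = 7L, sigma = 0.2,
                           beta = c(4.0, 0.4, 0.05, -0.1)) {
  stopifnot(n_molecules >= 1L, sigma >= 0, length(beta) == 4L)
  structure(list(n_molecules = as.integer(n_molecules),
                 seed = as.integer(seed), sigma = sigma, beta = beta),
            class = "synthetic_spec")
}

#' Generate a library of valid SMILES
#'
#' Samples molecules from the fragment grammar: one to three chained
#' middle fragments, optionally finished with a terminal cap. Every
#' string is guaranteed to parse; duplicates are rejected until
#' `n_molecules` unique strings are collected.
#'
#' @param spec A [synthetic_spec()].
#' @return Character vector of `n_molecules` unique SMILES.
#' @export
generate_molecules <- function(spec) {
  mids <- synth_mid_fragments()
  caps <- synth_cap_fragments()
  with_preserved_seed(spec$seed, {
    out <- character(0)
    attempts <- 0L
    max_attempts <- 200L * spec$n_molecules
    while (length(out) < spec$n_molecules) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("fragment grammar exhausted before ", spec$n_molecules,
             " unique molecules", call. = FALSE)
      }
      k <- sample(1:3, 1)
      s <- paste(sample(mids, k, replace = TRUE), collapse = "")
      if (stats::runif(1) < 0.5) s <- paste0(s, sample(caps, 1))
      if (!s %in% out) out <- c(out, s)
    }
    out
  })
}

#' Synthetic activity labels for featurized molecules
#'
#' Applies the spec's activity model to each graph's structural counts
#' (heteroatoms, aromatic atoms, rings) with seeded Gaussian noise;
#' `sigma = 0` gives a deterministic function of structure.
#'
#' @param graphs List of `mol_graph` objects (or a tibble with a
#'   `graph` column).
#' @param spec A [synthetic_spec()].
#' @return Numeric pIC50 vector.
#' @export
generate_activity <- function(graphs, spec) {
  graphs <- as_graph_list(graphs)
  b <- spec$beta
  base <- vapply(graphs, function(g) {
    b[1] + b[2] * g$counts$n_NO + b[3] * g$counts$n_aromatic +
      b[4] * g$counts$n_rings
  }, numeric(1))
  if (spec$sigma == 0) return(base)
  noise <- with_preserved_seed(spec$seed + 1L,
                               stats::rnorm(length(base), 0, spec$sigma))
  base + noise
}

#' Generate a complete labeled synthetic dataset
#'
#' Convenience wrapper: generates the SMILES library, featurizes it and
#' attaches activity labels, yielding a table ready for [train_gnn()]
#' or [split_dataset()].
#'
#' @param spec A [synthetic_spec()].
#' @return Tibble with `id`, `smiles`, `pic50` and `graph` columns.
#' @export
make_synthetic_dataset <- function(spec) {
  smiles <- generate_molecules(spec)
  d <- featurize_compounds(tibble::tibble(
    id = sprintf("SYN%04d", seq_along(smiles)), smiles = smiles))
  d$pic50 <- generate_activity(d$graph, spec)
  for (i in seq_len(nrow(d))) d$graph[[i]]$label <- d$pic50[i]
  d
}

#' Synthetic descriptor table
#'
#' Builds a compounds-by-descriptors table from featurized molecules:
#' the informative structural counts feeding the synthetic activity
#' model (atom, heteroatom, aromatic-atom and ring counts) plus
#' `n_decoys` independent standard-normal noise columns, suitable for
#' Lasso-recovery experiments.
#'
#' @param graphs List of `mol_graph` objects or tibble with `graph`
#'   column.
#' @param n_decoys Number of noise descriptors.
#' @param seed Seed for the decoy columns.
#' @param labels Optional pIC50 labels to attach.
#' @return A [descriptor_table()].
#' @export
generate_descriptor_table <- function(graphs, n_decoys = 0L, seed = 1L,
                                      labels = NULL) {
  graphs <- as_graph_list(graphs)
  n <- length(graphs)
  df <- tibble::tibble(
    id = vapply(seq_along(graphs),
                function(i) graphs[[i]]$id %||% sprintf("SYN%04d", i),
                character(1)),
    n_atoms = vapply(graphs, function(g) as.numeric(g$counts$n_atoms), 1),
    n_NO = vapply(graphs, function(g) as.numeric(g$counts$n_NO), 1),
    n_aromatic = vapply(graphs, function(g) as.numeric(g$counts$n_aromatic), 1),
    n_rings = vapply(graphs, function(g) as.numeric(g$counts$n_rings), 1))
  if (n_decoys > 0L) {
    decoys <- with_preserved_seed(seed, {
      matrix(stats::rnorm(n * n_decoys), n, n_decoys,
             dimnames = list(NULL, sprintf("decoy%02d", seq_len(n_decoys))))
    })
    df <- dplyr::bind_cols(df, tibble::as_tibble(decoys))
  }
  descriptor_table(df, labels = labels)
}
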