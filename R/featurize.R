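#' Atom feature schema
#'
#' The fixed 46-slot per-atom encoding used by every graph model in this
#' package. Eight feature blocks are concatenated in a fixed order: atom
#' symbol (12 one-hot slots), heavy-atom degree (7), hybridization (5),
#' total valence (7), formal charge (3), ring-size membership (6,
#' multi-hot so fused-ring atoms set several slots), aromaticity (1
#' integer slot) and attached-hydrogen count (5).
#'
#' @return An object of class `atom_schema`: a tibble with one row per
#'   block (`feature`, `categories` list-column, `encoding`, `width`) and
#'   a `total_width` attribute equal to 46.
#' @examples
#' sch <- atom_feature_schema()
#' attr(sch, "total_width")
#' @export
atom_feature_schema <- function() {
  blocks <- tibble::tibble(
    feature = c("symbol", "degree", "hybridization", "valence",
                "formal_charge", "ring_size", "aromatic", "n_hydrogen"),
    categories = list(
      c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "I", "H", "other"),
      as.character(0:6),
      c("sp", "sp2", "sp3", "sp3d", "sp3d2"),
      as.character(0:6),
      as.character(-1:1),
      as.character(3:8),
      "aromatic",
      as.character(0:4)
    ),
    encoding = c("one-hot", "one-hot", "one-hot", "one-hot",
                 "one-hot", "multi-hot", "integer", "one-hot")
  )
  blocks$width <- lengths(blocks$categories)
  structure(blocks,
            total_width = sum(blocks$width),
            class = c("atom_schema", class(blocks)))
}

# clamp a numeric category to the nearest value in an integer category list
clamp_category <- function(value, categories, feature, strict) {
  cats <- as.integer(categories)
  if (value %in% cats) return(value)
  if (strict) {
    stop("encoding-domain error: ", feature, " = ", value,
         " has no category under strict mode", call. = FALSE)
  }
  cats[which.min(abs(cats - value))]
}

#' Encode one atom as a 46-slot feature vector
#'
#' @param atom A list or one-row data frame with fields `symbol`,
#'   `degree`, `hybridization` (one of `"sp"`, `"sp2"`, `"sp3"`,
#'   `"sp3d"`, `"sp3d2"`), `valence`, `formal_charge`, `ring_sizes`
#'   (integer vector, possibly empty), `aromatic` (logical) and
#'   `n_hydrogen`.
#' @param schema An [atom_feature_schema()].
#' @param mode `"tolerant"` (default) clamps out-of-range numeric
#'   categories to the nearest listed value and maps unknown symbols to
#'   `"other"`; `"strict"` signals an error for any unmappable category.
#' @return Numeric vector of length 46. Each one-hot block has exactly
#'   one slot set; the ring-size block sets one slot per ring size the
#'   atom belongs to.
#' @export
encode_atom <- function(atom, schema = atom_feature_schema(),
                        mode = c("tolerant", "strict")) {
  mode <- match.arg(mode)
  strict <- mode == "strict"
  out <- numeric(attr(schema, "total_width"))
  pos <- 0L
  for (i in seq_len(nrow(schema))) {
    cats <- schema$categories[[i]]
    w <- schema$width[i]
    feat <- schema$feature[i]
    idx <- switch(
      feat,
      symbol = {
        s <- as.character(atom$symbol)
        if (s %in% cats) match(s, cats)
        else if (strict) stop("encoding-domain error: unknown symbol '",
                              s, "' under strict mode", call. = FALSE)
        else match("other", cats)
      },
      degree = match(clamp_category(atom$degree, cats, feat, strict), as.integer(cats)),
      hybridization = {
        h <- as.character(atom$hybridization)
        if (h %in% cats) match(h, cats)
        else if (strict) stop("encoding-domain error: hybridization '",
                              h, "' under strict mode", call. = FALSE)
        else match("sp3", cats)
      },
      valence = match(clamp_category(atom$valence, cats, feat, strict), as.integer(cats)),
      formal_charge = match(clamp_category(atom$formal_charge, cats, feat, strict),
                            as.integer(cats)),
      ring_size = {
        rs <- intersect(as.integer(atom$ring_sizes[[1]] %||% atom$ring_sizes),
                        as.integer(cats))
        match(rs, as.integer(cats))
      },
      aromatic = if (isTRUE(as.logical(atom$aromatic))) 1L else integer(0),
      n_hydrogen = match(clamp_category(atom$n_hydrogen, cats, feat, strict),
                         as.integer(cats))
    )
    out[pos + idx] <- 1
    pos <- pos + w
  }
  out
}

#' Convert IC50 (nM) to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the half-maximal
#' inhibitory concentration in molar units, so an IC50 of 1000 nM maps
#' to 6 and 1 nM maps to 9.
#'
#' @param ic50_nM Positive concentration(s) in nanomolar.
#' @return Numeric vector of pIC50 values.
#' @export
pic50_from_ic50 <- function(ic50_nM) {
  if (any(!is.finite(ic50_nM)) || any(ic50_nM <= 0)) {
    stop("IC50 values must be positive and finite", call. = FALSE)
  }
  -log10(ic50_nM * 1e-9)
}

# --- SMILES parsing via ChemmineR / Open Babel ------------------------------

# Parse SMILES into per-atom descriptor tables and a heavy-atom bond list.
# Hydrogens are made explicit during conversion so attached-H counts are
# read off the molecular graph, then folded back into the heavy-atom graph.
parse_smiles <- function(smiles) {
  stopifnot(length(smiles) == 1L, is.character(smiles))
  if (is.na(smiles) || !nzchar(smiles)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " MOL\n"),
                              options = data.frame(names = c("h", "gen2D"),
                                                   args = c("", ""))),
    error = function(e) "")
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  sdf <- tryCatch(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(lines))[[1]],
    error = function(e) stop("unparseable SMILES: '", smiles, "'", call. = FALSE))

  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  syms <- sub("_.*$", "", rownames(ab))
  n_all <- length(syms)
  if (n_all == 0L) stop("molecule with zero atoms: '", smiles, "'", call. = FALSE)

  # V2000 charge codes: 1 -> +3, 2 -> +2, 3 -> +1, 5 -> -1, 6 -> -2, 7 -> -3
  code <- if ("C6" %in% colnames(ab)) as.integer(ab[, "C6"]) else integer(n_all)
  charge_map <- c(0L, 3L, 2L, 1L, 0L, -1L, -2L, -3L)
  charge <- charge_map[code + 1L]

  if (is.null(dim(bb))) {
    bb <- if (length(bb) >= 3L) matrix(bb, nrow = 1L) else
      matrix(integer(0), nrow = 0L, ncol = 3L)
  }
  b1 <- as.integer(bb[, 1]); b2 <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])

  heavy <- which(syms != "H")
  if (length(heavy) == 0L) {
    # e.g. "[H][H]": keep the explicit-H atoms as graph nodes
    heavy <- seq_len(n_all)
  }
  hmap <- integer(n_all); hmap[heavy] <- seq_along(heavy)

  is_h <- !(seq_len(n_all) %in% heavy)
  heavy_bond <- !(is_h[b1] | is_h[b2])
  hb1 <- hmap[b1[heavy_bond]]; hb2 <- hmap[b2[heavy_bond]]
  hbo <- bo[heavy_bond]

  n <- length(heavy)
  degree <- tabulate(c(hb1, hb2), nbins = n)
  n_h <- vapply(seq_len(n), function(i) {
    a <- heavy[i]
    sum((b1 == a & is_h[b2]) | (b2 == a & is_h[b1]))
  }, integer(1))
  bond_order_sum <- vapply(seq_len(n), function(i) {
    sum(hbo[hb1 == i | hb2 == i])
  }, integer(1))
  valence <- bond_order_sum + n_h

  # ring perception (smallest set of smallest rings) and aromaticity
  ring_sizes <- rep(list(integer(0)), n)
  aromatic <- logical(n)
  n_rings <- 0L
  if (length(hb1) > 0L) {
    rg <- tryCatch(ChemmineR::rings(sdf, upper = Inf, type = "all",
                                    arom = TRUE, inner = TRUE),
                   error = function(e) list(RINGS = NULL, AROMATIC = NULL))
    if (!is.null(rg$RINGS)) {
      n_rings <- length(rg$RINGS)
      for (ri in seq_along(rg$RINGS)) {
        members <- as.integer(sub("^.*_", "", rg$RINGS[[ri]]))
        members <- hmap[members]
        members <- members[members > 0L]
        sz <- length(rg$RINGS[[ri]])
        for (m in members) {
          ring_sizes[[m]] <- unique(c(ring_sizes[[m]], sz))
          if (isTRUE(rg$AROMATIC[[ri]])) aromatic[m] <- TRUE
        }
      }
    }
  }

  n_double <- vapply(seq_len(n), function(i) sum(hbo[(hb1 == i | hb2 == i)] == 2L),
                     integer(1))
  n_triple <- vapply(seq_len(n), function(i) sum(hbo[(hb1 == i | hb2 == i)] == 3L),
                     integer(1))
  steric <- degree + n_h
  hybridization <- ifelse(
    n_triple > 0L | n_double >= 2L, "sp",
    ifelse(aromatic | n_double == 1L, "sp2",
           ifelse(steric >= 6L, "sp3d2", ifelse(steric == 5L, "sp3d", "sp3"))))

  list(
    atoms = tibble::tibble(
      symbol = syms[heavy], degree = degree, hybridization = hybridization,
      valence = valence, formal_charge = charge[heavy],
      ring_sizes = ring_sizes, aromatic = aromatic, n_hydrogen = n_h),
    bonds = tibble::tibble(a1 = hb1, a2 = hb2, order = hbo),
    n_rings = n_rings
  )
}

#' Convert a SMILES string to a molecular graph
#'
#' Builds the heavy-atom graph of a molecule: a node feature matrix with
#' one 46-slot row per atom (see [atom_feature_schema()]) and a directed
#' edge list in coordinate (COO) format where each chemical bond
#' contributes both directions. Hydrogens are folded into the
#' attached-hydrogen count feature. Atom indices in `edge_index` are
#' 0-based.
#'
#' @param smiles A single SMILES string.
#' @param schema An [atom_feature_schema()].
#' @param mode Passed to [encode_atom()].
#' @param id Optional compound identifier stored on the graph.
#' @param label Optional pIC50 label stored on the graph.
#' @return An object of class `mol_graph` with elements `node_features`
#'   (n_atoms x 46 matrix), `edge_index` (2 x 2m integer matrix,
#'   0-based), `label`, `id`, `smiles` and `counts` (atom/ring tallies
#'   used by the synthetic-activity model).
#' @examples
#' g <- smiles_to_graph("CC")  # ethane: 2 nodes, one bond in both directions
#' g$edge_index
#' @export
smiles_to_graph <- function(smiles, schema = atom_feature_schema(),
                            mode = c("tolerant", "strict"),
                            id = NULL, label = NULL) {
  mode <- match.arg(mode)
  parsed <- parse_smiles(smiles)
  atoms <- parsed$atoms
  n <- nrow(atoms)
  X <- matrix(0, nrow = n, ncol = attr(schema, "total_width"))
  for (i in seq_len(n)) {
    X[i, ] <- encode_atom(atoms[i, ], schema, mode)
  }
  ei <- if (nrow(parsed$bonds) > 0L) {
    rbind(c(parsed$bonds$a1, parsed$bonds$a2),
          c(parsed$bonds$a2, parsed$bonds$a1)) - 1L
  } else {
    matrix(integer(0), nrow = 2)
  }
  storage.mode(ei) <- "integer"
  structure(
    list(node_features = X,
         edge_index = ei,
         label = label,
         id = id,
         smiles = smiles,
         counts = list(
           n_atoms = n,
           n_NO = sum(atoms$symbol %in% c("N", "O")),
           n_aromatic = sum(atoms$aromatic),
           n_rings = parsed$n_rings)),
    class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat("<mol_graph> ", x$smiles %||% "", "\n",
      "  atoms: ", nrow(x$node_features),
      "  directed edges: ", ncol(x$edge_index),
      if (!is.null(x$label)) paste0("  pIC50: ", signif(x$label, 4)) else "",
      "\n", sep = "")
  invisible(x)
}

#' Featurize a table of compounds
#'
#' Tidy entry point for the graph pipeline: takes a compounds table with
#' `id` and `smiles` columns plus either `ic50_nM` or `pic50`, and
#' returns the same table with a `pic50` column and a `graph`
#' list-column of [smiles_to_graph()] results.
#'
#' @param data A data frame with columns `id`, `smiles` and one of
#'   `ic50_nM` or `pic50` (a label column may also be absent for
#'   unlabeled screening compounds).
#' @param schema,mode Passed to [smiles_to_graph()].
#' @return A tibble with columns `id`, `smiles`, `pic50` (possibly all
#'   `NA`) and `graph`.
#' @export
featurize_compounds <- function(data, schema = atom_feature_schema(),
                                mode = c("tolerant", "strict")) {
  mode <- match.arg(mode)
  stopifnot(all(c("id", "smiles") %in% names(data)))
  pic50 <- if ("pic50" %in% names(data)) data$pic50
           else if ("ic50_nM" %in% names(data)) pic50_from_ic50(data$ic50_nM)
           else rep(NA_real_, nrow(data))
  out <- tibble::tibble(id = data$id, smiles = data$smiles, pic50 = pic50)
  out$graph <- purrr::pmap(list(out$smiles, out$id, out$pic50),
                           function(s, i, p) {
                             smiles_to_graph(s, schema, mode, id = i,
                                             label = if (is.na(p)) NULL else p)
                           })
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
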