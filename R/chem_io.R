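# Molecular and sequence I/O: SMILES -> featurized graph, protein tokenizer,
# interaction tables, batching/padding, dataset splitting.

.chem <- new.env(parent = emptyenv())
.chem$cache <- new.env(parent = emptyenv())  # SMILES -> perceived molecule

#' The 25-letter amino-acid alphabet
#'
#' The 20 standard residues plus the extended IUPAC symbols B, Z, U, O and the
#' catch-all X. Token index = position in this string (1-based). Any character
#' outside the alphabet maps to X.
#' @export
PROTEIN_ALPHABET <- "ACDEFGHIKLMNPQRSTVWYBZUOX"

# Frozen 74-dimensional atom-feature layout: 8 attribute blocks.
ATOM_SYMBOLS <- c(
  "C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na", "Ca", "Fe",
  "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb", "Sn", "Ag", "Pd", "Co",
  "Se", "Ti", "Zn", "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
  "Zr", "Cr", "Pt", "Hg", "Pb", "other"
)  # 44
HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "SP3D", "SP3D2")  # 5

#' Atom feature layout
#'
#' Returns the frozen slot table of the 74-dimensional per-atom feature vector:
#' 8 attribute blocks — atom type one-hot (44), degree one-hot 0-10 (11),
#' implicit hydrogens one-hot 0-6 (7), formal charge (1, integer-valued),
#' radical electrons (1, integer-valued), hybridization one-hot over
#' sp/sp2/sp3/sp3d/sp3d2 (5), total hydrogens one-hot 0-3 (4), aromatic flag
#' (1). Out-of-range counts clamp into the final category; non-listed
#' hybridizations fall back to sp3 so every one-hot block always carries
#' exactly one 1.
#'
#' @return data.frame with columns `block`, `width`, `start`, `end`.
#' @export
atom_feature_blocks <- function() {
  widths <- c(atom_type = 44L, degree = 11L, implicit_h = 7L,
              formal_charge = 1L, radical_electrons = 1L, hybridization = 5L,
              total_h = 4L, aromatic = 1L)
  ends <- cumsum(widths)
  data.frame(block = names(widths), width = unname(widths),
             start = unname(ends - widths + 1L), end = unname(ends),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Total atom feature width (74)
#' @export
atom_feature_dim <- function() sum(atom_feature_blocks()$width)

python_backend <- function() {
  Sys.getenv("GCADTI_PYTHON", unset = "python")
}

perceive_smiles <- function(smiles) {
  ## Batched RDKit call for all SMILES not yet cached; results memoized.
  todo <- unique(smiles[!vapply(smiles, exists, logical(1), envir = .chem$cache)])
  if (length(todo)) {
    script <- system.file("python", "mol_graph.py", package = "gcadti")
    if (script == "") script <- file.path("inst", "python", "mol_graph.py")
    inp <- tempfile(fileext = ".smi")
    writeLines(todo, inp)
    on.exit(unlink(inp))
    out <- suppressWarnings(
      system2(python_backend(), c(shQuote(script), shQuote(inp)),
              stdout = TRUE, stderr = FALSE))
    status <- attr(out, "status")
    if (!is.null(status) && status != 0)
      stop("SMILES backend failed (is python with RDKit on PATH?)")
    parsed <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
    for (i in seq_along(todo)) assign(todo[i], parsed[[i]], envir = .chem$cache)
  }
  lapply(smiles, get, envir = .chem$cache)
}

#' Parse a SMILES string into a molecular graph
#'
#' Atoms (heavy atoms only; hydrogens stay implicit) become nodes and bonds
#' undirected edges. Chemical perception — aromaticity, implicit hydrogen
#' counts — is applied before featurization by the RDKit backend. The returned
#' graph carries the raw per-atom attribute table, the 74-dim feature matrix
#' (see [atom_feature_blocks()]), and the edge list with bond orders.
#'
#' @param smiles a single non-empty SMILES string.
#' @return an object of class `mol_graph`: list with `n_real`, `atoms`
#'   (data.frame of raw attributes), `edges` (data.frame `i`, `j`, `order`,
#'   1-based, each undirected bond stored once), `atom_features`
#'   (`n_real` x 74 matrix), `node_mask` (all TRUE before padding), `smiles`.
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!nzchar(smiles)) stop("smiles_to_graph: empty SMILES string")
  mol <- perceive_smiles(smiles)[[1]]
  if (!isTRUE(mol$ok))
    stop(sprintf("smiles_to_graph: cannot parse SMILES '%s'", smiles))
  atoms <- as.data.frame(lapply(mol$atoms, unlist), stringsAsFactors = FALSE)
  edges <- if (length(mol$bonds)) {
    b <- do.call(rbind, lapply(mol$bonds, unlist))
    data.frame(i = as.integer(b[, 1]), j = as.integer(b[, 2]), order = b[, 3])
  } else {
    data.frame(i = integer(0), j = integer(0), order = numeric(0))
  }
  g <- structure(list(n_real = nrow(atoms), atoms = atoms, edges = edges,
                      atom_features = NULL, node_mask = rep(TRUE, nrow(atoms)),
                      smiles = smiles),
                 class = "mol_graph")
  g$atom_features <- featurize_atoms(g)
  g
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d atoms, %d bonds>\n",
              x$smiles, x$n_real, nrow(x$edges)))
  invisible(x)
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  k <- match(value, levels)
  if (is.na(k)) k <- length(levels)  # clamp / catch-all = last slot
  v[k] <- 1
  v
}

#' Featurize the atoms of a molecular graph
#'
#' Builds the N x 74 raw feature matrix, one row per heavy atom, following the
#' frozen 8-block layout of [atom_feature_blocks()].
#'
#' @param graph a `mol_graph` from [smiles_to_graph()].
#' @return numeric matrix `n_real` x 74.
#' @export
featurize_atoms <- function(graph) {
  stopifnot(inherits(graph, "mol_graph"))
  a <- graph$atoms
  n <- nrow(a)
  X <- matrix(0, n, atom_feature_dim())
  for (r in seq_len(n)) {
    X[r, ] <- c(
      one_hot(a$symbol[r], ATOM_SYMBOLS),
      one_hot(min(a$degree[r], 10L), 0:10),
      one_hot(min(a$implicit_h[r], 6L), 0:6),
      a$formal_charge[r],
      a$radical_electrons[r],
      one_hot(ifelse(a$hybridization[r] %in% HYBRIDIZATIONS,
                     a$hybridization[r], "SP3"), HYBRIDIZATIONS),
      one_hot(min(a$total_h[r], 3L), 0:3),
      as.numeric(a$aromatic[r]))
  }
  X
}

#' Pad and batch molecular graphs
#'
#' Every graph is padded with zero-feature dummy nodes to `max_nodes`; feature
#' rows are stacked into one matrix and edges into one block-diagonal sparse
#' symmetric adjacency (each undirected bond expanded to both directions), so
#' a single sparse product computes all neighborhood sums. Dummy nodes carry
#' no edges and all-zero features.
#'
#' @param graphs list of `mol_graph`s.
#' @param max_nodes common padded node count; defaults to the batch maximum.
#' @return a `graph_batch`: list with `features` ((B*max_nodes) x 74 matrix),
#'   `adjacency` (sparse, symmetric), `node_mask` (logical, length
#'   B*max_nodes), `real_rows` (indices of real rows), `n_real` (per-graph
#'   atom counts), `max_nodes`, `n_graphs`.
#' @export
pad_batch <- function(graphs, max_nodes = NULL) {
  stopifnot(length(graphs) >= 1L)
  n_real <- vapply(graphs, function(g) g$n_real, integer(1))
  if (is.null(max_nodes)) max_nodes <- max(n_real)
  over <- which(n_real > max_nodes)
  if (length(over))
    stop(sprintf("pad_batch: graph %d has %d atoms > max_nodes = %d",
                 over[1], n_real[over[1]], max_nodes))
  B <- length(graphs)
  feats <- matrix(0, B * max_nodes, atom_feature_dim())
  mask <- logical(B * max_nodes)
  ii <- integer(0); jj <- integer(0)
  for (b in seq_len(B)) {
    off <- (b - 1L) * max_nodes
    rows <- off + seq_len(n_real[b])
    feats[rows, ] <- graphs[[b]]$atom_features
    mask[rows] <- TRUE
    e <- graphs[[b]]$edges
    if (nrow(e)) {
      ii <- c(ii, off + e$i, off + e$j)
      jj <- c(jj, off + e$j, off + e$i)
    }
  }
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                              dims = c(B * max_nodes, B * max_nodes))
  structure(list(features = feats, adjacency = adj, node_mask = mask,
                 real_rows = which(mask), n_real = n_real,
                 max_nodes = max_nodes, n_graphs = B),
            class = "graph_batch")
}

#' Tokenize a protein sequence
#'
#' Maps each character to its 1-based position in [PROTEIN_ALPHABET]
#' (25 symbols); characters outside the alphabet (after uppercasing) map to
#' the catch-all X (index 25).
#'
#' @param sequence non-empty amino-acid string.
#' @return object of class `protein_tokens`: list with `indices` (integer in
#'   1..25) and `length`.
#' @export
tokenize_protein <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) stop("tokenize_protein: empty sequence")
  chars <- strsplit(toupper(sequence), "")[[1]]
  idx <- match(chars, strsplit(PROTEIN_ALPHABET, "")[[1]])
  idx[is.na(idx)] <- 25L
  structure(list(indices = as.integer(idx), length = length(idx)),
            class = "protein_tokens")
}

#' Read an interaction table
#'
#' Comma-separated UTF-8 file with a header row naming at least
#' `smiles,sequence,label`; labels must be exactly 0 or 1.
#'
#' @param path CSV file path.
#' @return data.frame with character `smiles`, `sequence` and integer `label`;
#'   zero rows for a header-only file.
#' @export
read_interactions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("smiles", "sequence", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("read_interactions: missing column(s) %s in %s",
                 paste(miss, collapse = ", "), path))
  if (nrow(df) == 0L)
    return(data.frame(smiles = character(0), sequence = character(0),
                      label = integer(0), stringsAsFactors = FALSE))
  lab <- suppressWarnings(as.numeric(df$label))
  bad <- which(is.na(lab) | !(lab %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("read_interactions: non-binary label '%s' at data row %d",
                 df$label[bad[1]], bad[1]))
  data.frame(smiles = df$smiles, sequence = df$sequence,
             label = as.integer(lab), stringsAsFactors = FALSE)
}

#' Write an interaction table
#' @param records data.frame with `smiles`, `sequence`, `label`.
#' @param path output CSV path.
#' @export
write_interactions <- function(records, path) {
  utils::write.csv(records[, c("smiles", "sequence", "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    return(stats::setNames(as.character(ss), names(ss)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, character(1), collapse = "")
  stats::setNames(seqs, sub("^>\\s*", "", lines[hdr]))
}

#' Split a dataset into train / validation / test partitions
#'
#' Random partition with sizes proportional to `ratios` (default 7:1:2, the
#' benchmark protocol): train and validation sizes are floors of their exact
#' shares, the test set takes the remainder. The same seed always reproduces
#' the same partition.
#'
#' @param records data.frame of interaction records (>= 10 rows).
#' @param ratios positive weights (train, val, test).
#' @param seed integer RNG seed.
#' @return list with `train`, `val`, `test` data.frames.
#' @export
split_dataset <- function(records, ratios = c(7, 1, 2), seed = 1L) {
  n <- nrow(records)
  stopifnot(n >= 10L, length(ratios) == 3L, all(ratios >= 0), sum(ratios) > 0)
  w <- ratios / sum(ratios)
  n_train <- floor(n * w[1])
  n_val <- floor(n * w[2])
  perm <- with_seed(seed, function() sample.int(n))
  list(train = records[perm[seq_len(n_train)], , drop = FALSE],
       val = records[perm[n_train + seq_len(n_val)], , drop = FALSE],
       test = records[perm[(n_train + n_val + 1L):n], , drop = FALSE])
}
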