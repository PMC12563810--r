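# Attention-based attribution: turn the protein->drug cross-attention map of
# a trained model into ranked residue-atom index pairs and atom-level
# highlight weights. Heads are averaged before selection; virtual (padding)
# rows/columns are removed; the top fraction (default 20%) of matrix entries
# is kept with deterministic tie-breaking, then projected onto drug atoms.

#' Extract the head-averaged protein-to-drug attention map for one pair
#'
#' Runs an evaluation-mode forward pass for a single record and averages the
#' per-head protein-to-drug attention weights.
#'
#' @param model a trained `dti_model` whose fusion module is active
#'   (`use_gca = TRUE`).
#' @param record one-row data.frame with `smiles` and `sequence`.
#' @param pad_to optionally pad the drug graph to this node count first
#'   (dummy columns then appear in the raw map and are removed by
#'   [remove_virtual_nodes()]).
#' @return list with `att` (residues x padded-atoms matrix), `node_mask`,
#'   `n_residues`, `prob` (predicted interaction probability), `graph`.
#' @export
extract_attention <- function(model, record, pad_to = NULL) {
  stopifnot(nrow(record) == 1L)
  if (!isTRUE(model$fusion$use_gca))
    stop("extract_attention: model was built without the cross-attention module")
  batch <- prepare_batch(record, model$config, max_nodes = pad_to)
  out <- ag_no_grad(forward_batch(model, batch, keep_attention = TRUE))
  maps <- out$attention[[1]]$att_maps$p2d
  att <- Reduce(`+`, maps) / length(maps)
  if (!is.null(pad_to) && ncol(att) < pad_to) {
    # dummy-atom keys carry exactly zero attention weight (masked softmax);
    # re-insert their columns so the map aligns with the padded graph
    full <- matrix(0, nrow(att), pad_to)
    full[, which(batch$graph_batch$node_mask)] <- att
    att <- full
  }
  list(att = att, node_mask = batch$graph_batch$node_mask,
       n_residues = batch$prot_len[1], prob = out$probs[1],
       graph = graph_cache_get(record$smiles))
}

#' Drop virtual nodes from an attention map
#'
#' Removes columns belonging to dummy (padding) atoms and rows beyond the true
#' residue count.
#'
#' @param att residues x atoms matrix.
#' @param node_mask logical vector, length = ncol(att); TRUE = real atom.
#' @param residue_length true residue count (default: all rows).
#' @return trimmed matrix (residue_length x n_real_atoms).
#' @export
remove_virtual_nodes <- function(att, node_mask, residue_length = nrow(att)) {
  if (length(node_mask) != ncol(att))
    stop(sprintf("remove_virtual_nodes: mask length %d != %d columns",
                 length(node_mask), ncol(att)))
  if (!any(node_mask)) stop("remove_virtual_nodes: no real atoms in mask")
  if (residue_length < 1L || residue_length > nrow(att))
    stop("remove_virtual_nodes: residue_length outside 1..nrow(att)")
  att[seq_len(residue_length), node_mask, drop = FALSE]
}

#' Select the top fraction of attention entries
#'
#' Keeps the `ceiling(fraction * n_entries)` largest matrix entries as
#' (residue, atom) index pairs. Ties break deterministically: higher weight
#' first, then lower row, then lower column.
#'
#' @param att numeric matrix (rows = residues, cols = atoms).
#' @param fraction selection fraction in (0, 1]; default 0.20.
#' @return data.frame with `residue`, `atom`, `weight`, ordered by the
#'   selection rule.
#' @export
top_fraction_indices <- function(att, fraction = 0.20) {
  if (length(att) == 0L) stop("top_fraction_indices: empty attention matrix")
  if (fraction <= 0 || fraction > 1)
    stop("top_fraction_indices: fraction must lie in (0, 1]")
  # tiny slack keeps exact rational multiples (e.g. 0.2 * 180) from bumping up
  # a rank through floating-point excess
  n_sel <- as.integer(ceiling(fraction * length(att) - 1e-9))
  rows <- rep(seq_len(nrow(att)), times = ncol(att))
  cols <- rep(seq_len(ncol(att)), each = nrow(att))
  w <- as.vector(att)
  ord <- order(-w, rows, cols)[seq_len(n_sel)]
  data.frame(residue = rows[ord], atom = cols[ord], weight = w[ord])
}

#' Project selected pairs onto drug atoms
#'
#' Aggregates the selected (residue, atom) pairs per atom: each atom's weight
#' is the sum of its selected entries. Emits a highlight table consumable by a
#' molecule-drawing backend.
#'
#' @param selected data.frame from [top_fraction_indices()].
#' @param graph the drug's `mol_graph` (bounds-checks atom indices and
#'   supplies element symbols).
#' @return list with `atom_ids` (sorted unique atom indices), `highlights`
#'   (data.frame `atom`, `symbol`, `weight`, `relative` in [0, 1]).
#' @export
map_to_atoms <- function(selected, graph) {
  if (nrow(selected) == 0L)
    return(list(atom_ids = integer(0),
                highlights = data.frame(atom = integer(0), symbol = character(0),
                                        weight = numeric(0), relative = numeric(0))))
  if (any(selected$atom < 1L | selected$atom > graph$n_real))
    stop("map_to_atoms: atom index outside the molecular graph")
  agg <- rowsum(selected$weight, group = selected$atom)
  atoms <- as.integer(rownames(agg))
  w <- as.numeric(agg)
  ord <- order(atoms)
  atoms <- atoms[ord]; w <- w[ord]
  list(atom_ids = atoms,
       highlights = data.frame(atom = atoms, symbol = graph$atoms$symbol[atoms],
                               weight = w, relative = w / max(w)))
}

#' End-to-end attention attribution for one drug-protein pair
#'
#' [extract_attention()] -> [remove_virtual_nodes()] ->
#' [top_fraction_indices()] -> [map_to_atoms()].
#'
#' @inheritParams extract_attention
#' @param fraction selection fraction (default 0.20).
#' @return object of class `attribution_result`: list with `pairs`,
#'   `atom_ids`, `residue_ids`, `highlights`, `fraction`, `prob`, `att`.
#' @export
attribute_interaction <- function(model, record, fraction = 0.20, pad_to = NULL) {
  ex <- extract_attention(model, record, pad_to = pad_to)
  att <- remove_virtual_nodes(ex$att, ex$node_mask, ex$n_residues)
  sel <- top_fraction_indices(att, fraction)
  mapped <- map_to_atoms(sel, ex$graph)
  structure(list(pairs = sel, atom_ids = mapped$atom_ids,
                 residue_ids = sort(unique(sel$residue)),
                 highlights = mapped$highlights, fraction = fraction,
                 prob = ex$prob, att = att),
            class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("<attribution: %d pairs (top %.0f%%), %d atoms, %d residues, p = %.3f>\n",
              nrow(x$pairs), 100 * x$fraction, length(x$atom_ids),
              length(x$residue_ids), x$prob))
  invisible(x)
}

#' Write an attribution report
#' @param result an `attribution_result`.
#' @param dir output directory; writes `pairs.csv` (residue, atom, weight),
#'   `highlights.csv` (atom, symbol, weight, relative) and `att_map.tsv`
#'   (the dense trimmed attention matrix, rows = residues, cols = atoms).
#' @export
write_attribution <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$pairs, file.path(dir, "pairs.csv"), row.names = FALSE)
  utils::write.csv(result$highlights, file.path(dir, "highlights.csv"),
                   row.names = FALSE)
  att <- result$att
  dimnames(att) <- list(paste0("res", seq_len(nrow(att))),
                        paste0("atom", seq_len(ncol(att))))
  utils::write.table(att, file.path(dir, "att_map.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(dir)
}
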