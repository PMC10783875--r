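# Distance-thresholded graph construction for a protein-ligand complex.
#
# Three graphs represent a complex: a ligand atom graph (default cutoff
# 5.0 A), a protein residue graph over CA coordinates (8.0 A) and a
# bipartite residue-atom interaction graph (12.0 A). Edges connect pairs at
# Euclidean distance strictly below the cutoff; self-loops are excluded and
# undirected edges are stored once as (i, j) with i < j, in lexicographic
# order. Indices are 1-based throughout, following R convention.

.coords_of <- function(records) {
  m <- cbind(records$x, records$y, records$z)
  .assert(all(is.finite(m)), "non-finite coordinates")
  m
}

.pairs_below <- function(coords, cutoff) {
  n <- nrow(coords)
  if (n < 2L) {
    return(list(edges = matrix(integer(0), 0L, 2L), dist = numeric(0)))
  }
  d <- .pairwise_dist(coords)
  idx <- which(upper.tri(d) & d < cutoff, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  list(edges = unname(idx), dist = d[idx])
}

#' Build the ligand atom graph
#'
#' Nodes are heavy atoms; a pair of distinct atoms is connected iff their
#' Euclidean distance is strictly below `cutoff`. Edge features combine a
#' radial-basis expansion of the distance with a bond-order one-hot when the
#' source file provided connectivity.
#'
#' @param atoms `atom_records` (from [parse_ligand()] or the generator).
#' @param cutoff distance threshold in Angstrom (default 5.0).
#' @param schema a [feature_schema()].
#' @return an object of class `ligand_graph` with nodes, node feature matrix,
#'   the (i < j) edge matrix, per-edge distances and feature matrix.
#' @export
build_ligand_graph <- function(atoms, cutoff = 5.0, schema = feature_schema()) {
  .assert(inherits(atoms, "atom_records") && nrow(atoms) >= 1L,
          "atoms must be non-empty atom_records")
  .assert(is.numeric(cutoff) && cutoff > 0, "cutoff must be positive")
  coords <- .coords_of(atoms)
  pr <- .pairs_below(coords, cutoff)
  bonds <- attr(atoms, "bonds")
  order_lab <- rep("none", nrow(pr$edges))
  if (!is.null(bonds) && nrow(bonds) > 0L && nrow(pr$edges) > 0L) {
    key <- function(i, j) paste(pmin(i, j), pmax(i, j))
    m <- match(key(pr$edges[, 1L], pr$edges[, 2L]), key(bonds$i, bonds$j))
    order_lab[!is.na(m)] <- bonds$order[m[!is.na(m)]]
  }
  structure(list(
    nodes = atoms,
    node_features = .atom_feature_matrix(atoms, schema),
    edges = pr$edges,
    distances = pr$dist,
    edge_features = featurize_ligand_edge(pr$dist, cutoff, order_lab, schema),
    cutoff = cutoff
  ), class = "ligand_graph")
}

#' Build the protein residue graph
#'
#' Nodes are residues located at their CA coordinates; edges connect residue
#' pairs strictly closer than `cutoff`.
#'
#' @param residues `residue_records`.
#' @param cutoff distance threshold in Angstrom (default 8.0).
#' @param schema a [feature_schema()].
#' @return an object of class `protein_graph`.
#' @export
build_protein_graph <- function(residues, cutoff = 8.0, schema = feature_schema()) {
  .assert(inherits(residues, "residue_records") && nrow(residues) >= 1L,
          "residues must be non-empty residue_records")
  .assert(is.numeric(cutoff) && cutoff > 0, "cutoff must be positive")
  coords <- .coords_of(residues)
  pr <- .pairs_below(coords, cutoff)
  structure(list(
    nodes = residues,
    node_features = .residue_feature_matrix(residues, schema),
    edges = pr$edges,
    distances = pr$dist,
    edge_features = featurize_protein_edge(pr$dist, cutoff, schema),
    cutoff = cutoff
  ), class = "protein_graph")
}

#' Build the bipartite protein-ligand interaction graph
#'
#' Edges connect a residue (via its CA coordinate) and a ligand atom when
#' their distance is strictly below `cutoff`. An empty edge set is permitted
#' here; downstream encoding refuses such complexes explicitly.
#'
#' @param residues `residue_records`.
#' @param atoms `atom_records`.
#' @param cutoff distance threshold in Angstrom (default 12.0).
#' @param schema a [feature_schema()].
#' @return an object of class `interaction_graph` with the (residue, atom)
#'   edge matrix, distances and RBF edge features.
#' @export
build_interaction_graph <- function(residues, atoms, cutoff = 12.0,
                                    schema = feature_schema()) {
  .assert(inherits(residues, "residue_records") && nrow(residues) >= 1L,
          "residues must be non-empty residue_records")
  .assert(inherits(atoms, "atom_records") && nrow(atoms) >= 1L,
          "atoms must be non-empty atom_records")
  .assert(is.numeric(cutoff) && cutoff > 0, "cutoff must be positive")
  d <- .pairwise_dist(.coords_of(residues), .coords_of(atoms))
  idx <- which(d < cutoff, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  dist <- d[idx]
  structure(list(
    residue_count = nrow(residues),
    atom_count = nrow(atoms),
    edges = unname(idx),
    distances = dist,
    edge_features = featurize_interaction_edge(dist, cutoff, schema),
    cutoff = cutoff
  ), class = "interaction_graph")
}

#' Restrict a protein to the binding pocket
#'
#' Keeps residues whose CA lies within `cutoff` of any ligand atom. This
#' bounds encoder cost without discarding any residue that can contribute an
#' interaction edge; pass `full_protein = TRUE` to [complex_graphs()] to keep
#' every residue instead.
#'
#' @param residues `residue_records`.
#' @param atoms `atom_records`.
#' @param cutoff pocket radius in Angstrom (default: the interaction cutoff).
#' @return the filtered, reindexed `residue_records`.
#' @export
restrict_to_pocket <- function(residues, atoms, cutoff = 12.0) {
  d <- .pairwise_dist(.coords_of(residues), .coords_of(atoms))
  keep <- apply(d, 1L, min) < cutoff
  if (!any(keep)) keep[which.min(apply(d, 1L, min))] <- TRUE
  out <- residues[keep, , drop = FALSE]
  out$index <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("residue_records", "data.frame")
  out
}

#' Build all three graphs for a complex
#'
#' @param cs a [complex_structure()].
#' @param cutoffs named list with elements `ligand`, `protein`, `interaction`
#'   (defaults 5.0, 8.0, 12.0 Angstrom).
#' @param full_protein keep all residues instead of the default pocket
#'   restriction to residues within the interaction cutoff of the ligand.
#' @param schema a [feature_schema()].
#' @return list with `ligand`, `protein` and `interaction` graphs.
#' @export
complex_graphs <- function(cs, cutoffs = list(ligand = 5.0, protein = 8.0,
                                              interaction = 12.0),
                           full_protein = FALSE, schema = feature_schema()) {
  .assert(inherits(cs, "complex_structure"), "cs must be a complex_structure")
  prot <- if (full_protein) cs$protein else
    restrict_to_pocket(cs$protein, cs$ligand, cutoffs$interaction)
  list(
    ligand = build_ligand_graph(cs$ligand, cutoffs$ligand, schema),
    protein = build_protein_graph(prot, cutoffs$protein, schema),
    interaction = build_interaction_graph(prot, cs$ligand,
                                          cutoffs$interaction, schema)
  )
}

#' @export
print.ligand_graph <- function(x, ...) {
  cat("ligand_graph:", nrow(x$nodes), "atoms,", nrow(x$edges),
      "edges (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

#' @export
print.protein_graph <- function(x, ...) {
  cat("protein_graph:", nrow(x$nodes), "residues,", nrow(x$edges),
      "edges (cutoff", x$cutoff, "A)\n")
  invisible(x)
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat("interaction_graph:", x$residue_count, "residues x", x$atom_count,
      "atoms,", nrow(x$edges), "contacts (cutoff", x$cutoff, "A)\n")
  invisible(x)
}
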