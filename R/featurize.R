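# Node and edge feature schemas for the three complex graphs.
#
# The schema is versioned so alternative featurizations can be swapped in
# without touching graph construction; the dimensions below are what the
# encoder's input layers are sized against.

.ATOM_ELEMENTS <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
.HYB_LEVELS <- c("sp", "sp2", "sp3")
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
# Kyte-Doolittle hydropathy, scaled to roughly [-1, 1]
.AA_HYDRO <- c(ALA = 1.8, ARG = -4.5, ASN = -3.5, ASP = -3.5, CYS = 2.5,
               GLN = -3.5, GLU = -3.5, GLY = -0.4, HIS = -3.2, ILE = 4.5,
               LEU = 3.8, LYS = -3.9, MET = 1.9, PHE = 2.8, PRO = -1.6,
               SER = -0.8, THR = -0.7, TRP = -0.9, TYR = -1.3, VAL = 4.2) / 4.5
# side-chain charge class at physiological pH
.AA_CHARGE <- c(ARG = 1, LYS = 1, HIS = 1, ASP = -1, GLU = -1)
# residue molecular weight (Da), scaled by 1/100
.AA_MW <- c(ALA = 89.1, ARG = 174.2, ASN = 132.1, ASP = 133.1, CYS = 121.2,
            GLN = 146.2, GLU = 147.1, GLY = 75.1, HIS = 155.2, ILE = 131.2,
            LEU = 131.2, LYS = 146.2, MET = 149.2, PHE = 165.2, PRO = 115.1,
            SER = 105.1, THR = 119.1, TRP = 204.2, TYR = 181.2,
            VAL = 117.1) / 100
.BOND_LEVELS <- c("none", "single", "double", "triple", "aromatic")

#' Feature schema for complex graphs
#'
#' Describes the fixed-length node and edge feature layouts used when
#' building ligand, protein and interaction graphs:
#' * atoms: element one-hot over C/N/O/S/P/F/Cl/Br/I/other, degree one-hot
#'   0--5, formal charge, aromaticity flag, ring flag, hybridization one-hot
#'   (sp/sp2/sp3/other);
#' * residues: 20 standard residues + UNK one-hot, hydropathy, charge class
#'   and molecular-weight scalars;
#' * edges: a Gaussian radial-basis expansion of the distance over
#'   `n_rbf` centers spanning `[0, cutoff]`, plus a bond-order one-hot
#'   (none/single/double/triple/aromatic) on ligand edges.
#'
#' @param n_rbf number of radial-basis centers for edge distances.
#' @return an object of class `affpret_schema` with the layout and dimensions.
#' @export
feature_schema <- function(n_rbf = 16L) {
  .assert(n_rbf >= 2L, "n_rbf must be >= 2")
  s <- list(
    version = "1",
    elements = .ATOM_ELEMENTS,
    max_degree = 5L,
    hybridizations = .HYB_LEVELS,
    residues = .AA3,
    bond_levels = .BOND_LEVELS,
    n_rbf = as.integer(n_rbf),
    atom_dim = length(.ATOM_ELEMENTS) + 1L + 6L + 1L + 1L + 1L +
      length(.HYB_LEVELS) + 1L,
    residue_dim = length(.AA3) + 1L + 3L,
    ligand_edge_dim = as.integer(n_rbf) + length(.BOND_LEVELS),
    protein_edge_dim = as.integer(n_rbf),
    interaction_edge_dim = as.integer(n_rbf)
  )
  class(s) <- "affpret_schema"
  s
}

.one_hot <- function(value, levels, other = TRUE) {
  v <- numeric(length(levels) + as.integer(other))
  i <- match(value, levels)
  if (is.na(i)) {
    if (other) v[length(v)] <- 1 else stop("value '", value, "' not in levels", call. = FALSE)
  } else {
    v[i] <- 1
  }
  v
}

#' Featurize a ligand atom
#'
#' @param element element symbol; anything outside the schema's element list
#'   maps to the explicit "other" slot.
#' @param degree heavy-atom degree (capped at the schema maximum).
#' @param formal_charge integer formal charge.
#' @param aromatic,in_ring logical flags.
#' @param hybridization one of "sp", "sp2", "sp3" or anything else ("other").
#' @param schema a [feature_schema()].
#' @return numeric vector of length `schema$atom_dim`.
#' @export
featurize_atom <- function(element, degree = 0L, formal_charge = 0L,
                           aromatic = FALSE, in_ring = FALSE,
                           hybridization = "sp3", schema = feature_schema()) {
  deg <- max(0L, min(as.integer(degree), schema$max_degree))
  c(.one_hot(element, schema$elements),
    .one_hot(as.character(deg), as.character(0:schema$max_degree), other = FALSE),
    as.numeric(formal_charge),
    as.numeric(aromatic),
    as.numeric(in_ring),
    .one_hot(hybridization, schema$hybridizations))
}

#' Featurize a protein residue
#'
#' @param residue_name 3-letter residue code; non-standard codes map to UNK.
#' @param schema a [feature_schema()].
#' @return numeric vector of length `schema$residue_dim`.
#' @export
featurize_residue <- function(residue_name, schema = feature_schema()) {
  known <- residue_name %in% schema$residues
  c(.one_hot(residue_name, schema$residues),
    if (known) .AA_HYDRO[[residue_name]] else 0,
    if (known && residue_name %in% names(.AA_CHARGE)) .AA_CHARGE[[residue_name]] else 0,
    if (known) .AA_MW[[residue_name]] else 1.1)
}

#' Featurize graph edges by distance (and bond order on ligand edges)
#'
#' @param distance numeric vector of edge distances in Angstrom.
#' @param cutoff the graph's distance cutoff (sets the RBF center range).
#' @param bond_order for ligand edges: vector over
#'   none/single/double/triple/aromatic; `NULL` elsewhere.
#' @param schema a [feature_schema()].
#' @return matrix with one row per edge.
#' @export
featurize_ligand_edge <- function(distance, cutoff, bond_order = NULL,
                                  schema = feature_schema()) {
  if (is.null(bond_order)) bond_order <- rep("none", length(distance))
  .assert(length(bond_order) == length(distance), "bond_order length mismatch")
  rbf <- rbf_expand(distance, cutoff, schema$n_rbf)
  oh <- t(vapply(bond_order, function(b) .one_hot(b, schema$bond_levels, other = FALSE),
                 numeric(length(schema$bond_levels))))
  if (length(distance) == 0L) oh <- matrix(0, 0L, length(schema$bond_levels))
  unname(cbind(rbf, oh))
}

#' @rdname featurize_ligand_edge
#' @export
featurize_protein_edge <- function(distance, cutoff, schema = feature_schema()) {
  rbf_expand(distance, cutoff, schema$n_rbf)
}

#' @rdname featurize_ligand_edge
#' @export
featurize_interaction_edge <- function(distance, cutoff, schema = feature_schema()) {
  rbf_expand(distance, cutoff, schema$n_rbf)
}

# Feature matrix for a set of parsed atoms (one row per atom).
.atom_feature_matrix <- function(atoms, schema) {
  t(vapply(seq_len(nrow(atoms)), function(i) {
    featurize_atom(atoms$element[i], atoms$degree[i], atoms$formal_charge[i],
                   atoms$aromatic[i], atoms$in_ring[i], atoms$hybridization[i],
                   schema)
  }, numeric(schema$atom_dim)))
}

.residue_feature_matrix <- function(residues, schema) {
  t(vapply(residues$residue_name, featurize_residue,
           numeric(schema$residue_dim), schema = schema))
}
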