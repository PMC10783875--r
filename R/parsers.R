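# Structure readers: ligands from SDF/MOL2, proteins from PDB.
#
# Parsing of the container formats is delegated to ChemmineR (SDF V2000) and
# bio3d (PDB, MOL2); this file only normalizes their output into the flat
# atom/residue record tables the graph builders consume.

.new_atom_records <- function(df, bonds) {
  rownames(df) <- NULL
  attr(df, "bonds") <- bonds
  class(df) <- c("atom_records", "data.frame")
  df
}

.bond_order_label <- function(code) {
  # SDF bond types: 1, 2, 3, 4 = aromatic; MOL2: "1","2","3","ar","am"
  code <- as.character(code)
  ifelse(code %in% c("4", "ar"), "aromatic",
         ifelse(code == "2", "double",
                ifelse(code == "3", "triple", "single")))
}

# Derived atom context (degree / aromatic / ring / hybridization) from the
# heavy-atom connectivity. `bonds` has columns i, j, order.
.atom_context <- function(n, bonds) {
  degree <- integer(n)
  aromatic <- logical(n)
  n_double <- integer(n)
  n_triple <- integer(n)
  in_ring <- logical(n)
  if (nrow(bonds) > 0L) {
    tab <- table(factor(c(bonds$i, bonds$j), levels = seq_len(n)))
    degree <- as.integer(tab)
    for (k in seq_len(nrow(bonds))) {
      ij <- c(bonds$i[k], bonds$j[k])
      if (bonds$order[k] == "aromatic") aromatic[ij] <- TRUE
      if (bonds$order[k] == "double") n_double[ij] <- n_double[ij] + 1L
      if (bonds$order[k] == "triple") n_triple[ij] <- n_triple[ij] + 1L
    }
    g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    bic <- igraph::biconnected_components(g)
    for (comp in bic$components) {
      if (length(comp) >= 3L) in_ring[as.integer(comp)] <- TRUE
    }
  }
  hyb <- ifelse(n_triple > 0L | n_double >= 2L, "sp",
                ifelse(n_double > 0L | aromatic, "sp2", "sp3"))
  list(degree = degree, aromatic = aromatic, in_ring = in_ring, hybridization = hyb)
}

.finish_ligand <- function(element, coords, bonds, charges, keep_hydrogens, path) {
  keep <- if (keep_hydrogens) rep(TRUE, length(element)) else !(element %in% c("H", "D"))
  if (!any(keep)) {
    stop("no heavy atoms found in ligand file '", path, "'", call. = FALSE)
  }
  remap <- cumsum(keep)
  bonds <- bonds[keep[bonds$i] & keep[bonds$j], , drop = FALSE]
  bonds$i <- remap[bonds$i]
  bonds$j <- remap[bonds$j]
  element <- element[keep]
  coords <- coords[keep, , drop = FALSE]
  charges <- charges[keep]
  .assert(all(is.finite(coords)), "non-finite ligand coordinates")
  ctx <- .atom_context(length(element), bonds)
  df <- data.frame(
    index = seq_along(element),
    element = element,
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    degree = ctx$degree,
    formal_charge = charges,
    aromatic = ctx$aromatic,
    in_ring = ctx$in_ring,
    hybridization = ctx$hybridization,
    stringsAsFactors = FALSE
  )
  .new_atom_records(df, bonds)
}

#' Parse a ligand structure file into atom records
#'
#' Reads the first molecule of an SDF (V2000) or MOL2 file and returns one
#' record per heavy atom: element, 3D coordinates (Angstrom), and the bond
#' context (degree, formal charge, aromaticity, ring membership and a
#' hybridization estimate) used by [featurize_atom()]. Hydrogens are dropped
#' by default since docked poses frequently omit them.
#'
#' @param path path to the structure file.
#' @param format `"sdf"` or `"mol2"`; default guesses from the extension.
#' @param keep_hydrogens keep hydrogen atoms as graph nodes.
#' @return an `atom_records` data frame; the heavy-atom bond list is attached
#'   as `attr(x, "bonds")`.
#' @export
parse_ligand <- function(path, format = c("auto", "sdf", "mol2"),
                         keep_hydrogens = FALSE) {
  format <- match.arg(format)
  .assert(file.exists(path), paste0("ligand file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.mol2$", path, ignore.case = TRUE)) "mol2" else "sdf"
  }
  if (format == "sdf") .parse_sdf(path, keep_hydrogens) else .parse_mol2(path, keep_hydrogens)
}

.parse_sdf <- function(path, keep_hydrogens) {
  sdf <- tryCatch(ChemmineR::read.SDFset(path),
                  error = function(e) stop("failed to parse SDF '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(sdf) < 1L) stop("no molecule records in SDF '", path, "'", call. = FALSE)
  mol <- sdf[[1L]]
  ab <- ChemmineR::atomblock(mol)
  if (nrow(ab) == 0L) stop("empty atom block in SDF '", path, "'", call. = FALSE)
  element <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  bb <- ChemmineR::bondblock(mol)
  bonds <- if (nrow(bb) > 0L) {
    data.frame(i = as.integer(bb[, 1L]), j = as.integer(bb[, 2L]),
               order = .bond_order_label(bb[, 3L]), stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), order = character(0))
  }
  charges <- numeric(length(element))
  # formal charges live in "M  CHG" property lines of the first record
  lines <- readLines(path, warn = FALSE)
  endrec <- which(lines == "$$$$")[1L]
  if (!is.na(endrec)) lines <- lines[seq_len(endrec)]
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1L]])
    npairs <- f[1L]
    for (k in seq_len(npairs)) {
      charges[f[2L * k]] <- f[2L * k + 1L]
    }
  }
  .finish_ligand(element, coords, bonds, charges, keep_hydrogens, path)
}

.parse_mol2 <- function(path, keep_hydrogens) {
  mol <- tryCatch(bio3d::read.mol2(path),
                  error = function(e) stop("failed to parse MOL2 '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- mol$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty atom block in MOL2 '", path, "'", call. = FALSE)
  sybyl <- as.character(at$elety)
  element <- sub("\\..*$", "", sybyl)
  coords <- cbind(as.numeric(at$x), as.numeric(at$y), as.numeric(at$z))
  bonds <- if (!is.null(mol$bond) && nrow(mol$bond) > 0L) {
    data.frame(i = as.integer(mol$bond$origin), j = as.integer(mol$bond$target),
               order = .bond_order_label(mol$bond$type), stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), order = character(0))
  }
  charges <- if (!is.null(at$charge)) round(as.numeric(at$charge)) * 0 else numeric(nrow(at))
  .finish_ligand(element, coords, bonds, charges, keep_hydrogens, path)
}

#' Parse a protein PDB file into residue records
#'
#' Keeps one record per residue possessing an alpha-carbon (CA) atom, ordered
#' by chain and residue number; residues without a CA are skipped with a
#' warning, HETATM records are ignored, and for alternate locations the first
#' occurrence in file order is kept.
#'
#' @param path path to a PDB file with ATOM records.
#' @return a `residue_records` data frame with columns index, residue_name
#'   (3-letter code, UNK for non-standard), chain, resno and the CA
#'   coordinates x/y/z in Angstrom.
#' @export
parse_protein <- function(path) {
  .assert(file.exists(path), paste0("protein file not found: ", path))
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in PDB '", path, "'", call. = FALSE)
  ins <- ifelse(is.na(at$insert), "", at$insert)
  res_key <- paste(at$chain, at$resno, ins, sep = "|")
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("no CA atoms in PDB '", path, "'", call. = FALSE)
  ca_key <- paste(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert), sep = "|")
  first <- !duplicated(ca_key) # first altloc kept
  ca <- ca[first, , drop = FALSE]
  ca_key <- ca_key[first]
  missing_ca <- setdiff(unique(res_key), ca_key)
  if (length(missing_ca) > 0L) {
    warning(length(missing_ca), " residue(s) without a CA atom skipped",
            call. = FALSE)
  }
  ord <- order(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  ca <- ca[ord, , drop = FALSE]
  name <- toupper(ca$resid)
  name[!(name %in% .AA3)] <- "UNK"
  df <- data.frame(
    index = seq_len(nrow(ca)),
    residue_name = name,
    chain = ca$chain,
    resno = ca$resno,
    x = ca$x, y = ca$y, z = ca$z,
    stringsAsFactors = FALSE
  )
  .assert(all(is.finite(df$x + df$y + df$z)), "non-finite CA coordinates")
  rownames(df) <- NULL
  class(df) <- c("residue_records", "data.frame")
  df
}

#' Bundle parsed protein and ligand records into a complex
#'
#' @param protein `residue_records` from [parse_protein()] or the synthetic
#'   generator.
#' @param ligand `atom_records` from [parse_ligand()] or the generator.
#' @param protein_id,ligand_id identifiers carried through to predictions.
#' @param pose_rank optional docked-pose rank.
#' @return an object of class `complex_structure`.
#' @export
complex_structure <- function(protein, ligand, protein_id = "protein",
                              ligand_id = "ligand", pose_rank = NA_integer_) {
  .assert(inherits(protein, "residue_records") && nrow(protein) > 0L,
          "protein must be non-empty residue_records")
  .assert(inherits(ligand, "atom_records") && nrow(ligand) > 0L,
          "ligand must be non-empty atom_records")
  structure(list(protein = protein, ligand = ligand,
                 protein_id = protein_id, ligand_id = ligand_id,
                 pose_rank = pose_rank),
            class = "complex_structure")
}

#' @export
print.complex_structure <- function(x, ...) {
  cat("complex_structure:", x$protein_id, "/", x$ligand_id, "\n")
  cat("  ", nrow(x$protein), "residues,", nrow(x$ligand), "heavy atoms\n")
  invisible(x)
}
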