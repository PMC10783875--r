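# Synthetic complex / bioassay generator.
#
# Emulates the statistical structure the pre-training framework assumes,
# with a fully known ground truth: toy protein pockets and chain-like
# ligands in 3D, and assay collections whose true pAff is a planted linear
# function of the residue-atom contact count, plus a per-assay systematic
# offset (label noise across assays), a systematic IC50-vs-K shift (label
# variety) and iid measurement noise. Within an assay the offset is shared,
# so within-assay rankings are exactly the rankings of the noiseless
# signal -- the property that makes assay-specific ranking informative.

#' Configuration of the synthetic generator
#'
#' @param n_assays number of bioassays.
#' @param size_range min/max ligands per assay (min >= 2).
#' @param n_residues min/max residues per pocket.
#' @param n_atoms min/max heavy atoms per ligand.
#' @param alpha planted affinity slope, pAff per contact.
#' @param intercept baseline pAff at zero contacts.
#' @param sigma_assay standard deviation of the per-assay systematic offset
#'   (pAff units).
#' @param delta_type systematic shift added to IC50-type assays (pAff
#'   units); models the non-comparability of IC50 and K values.
#' @param sigma_eps iid measurement noise (pAff units).
#' @param pose_jitter per-coordinate Gaussian jitter (Angstrom) applied to
#'   ligand poses, a proxy for docked rather than crystallographic
#'   conformations.
#' @param p_ic50,p_ki probabilities that an assay measures IC50 / Ki (the
#'   remainder are Kd).
#' @param seed generator seed; the whole collection is reproducible from it.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_assays = 40L, size_range = c(4L, 16L),
                             n_residues = c(8L, 18L), n_atoms = c(5L, 14L),
                             alpha = 0.05, intercept = 3.0,
                             sigma_assay = 0.4, delta_type = 0.5,
                             sigma_eps = 0.1, pose_jitter = 0.3,
                             p_ic50 = 0.55, p_ki = 0.3, seed = 1L) {
  .assert(size_range[1L] >= 2L, "assay sizes must be >= 2")
  .assert(all(c(sigma_assay, sigma_eps, pose_jitter) >= 0), "spreads must be >= 0")
  .assert(p_ic50 >= 0 && p_ki >= 0 && p_ic50 + p_ki <= 1, "invalid type probabilities")
  structure(list(n_assays = as.integer(n_assays),
                 size_range = as.integer(size_range),
                 n_residues = as.integer(n_residues),
                 n_atoms = as.integer(n_atoms),
                 alpha = alpha, intercept = intercept,
                 sigma_assay = sigma_assay, delta_type = delta_type,
                 sigma_eps = sigma_eps, pose_jitter = pose_jitter,
                 p_ic50 = p_ic50, p_ki = p_ki, seed = as.integer(seed)),
            class = "synthetic_config")
}


# sample() treats a length-1 vector as 1:n; guard degenerate ranges
.sample_range <- function(lo, hi) {
  if (lo >= hi) return(as.integer(lo))
  sample(lo:hi, 1L)
}

# Toy pocket: CA positions on a jittered cubic lattice (5.5 A spacing).
.make_pocket <- function(n_res) {
  side <- ceiling(n_res^(1 / 3))
  grid <- as.matrix(expand.grid(x = seq_len(side), y = seq_len(side),
                                z = seq_len(side))) * 5.5
  pick <- sample(nrow(grid), n_res)
  coords <- grid[pick, , drop = FALSE] + matrix(stats::rnorm(3 * n_res, 0, 0.5), n_res)
  df <- data.frame(
    index = seq_len(n_res),
    residue_name = sample(.AA3, n_res, replace = TRUE),
    chain = "A",
    resno = seq_len(n_res),
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    stringsAsFactors = FALSE
  )
  class(df) <- c("residue_records", "data.frame")
  df
}

# Chain-like ligand grown with 1.5 A bonds around a center point.
.make_ligand <- function(n_atoms, center, pose_jitter) {
  elements <- sample(c("C", "C", "C", "N", "O", "S"), n_atoms, replace = TRUE)
  coords <- matrix(0, n_atoms, 3L)
  coords[1L, ] <- center
  for (k in seq_len(n_atoms)[-1L]) {
    dir <- stats::rnorm(3L)
    dir <- dir / sqrt(sum(dir^2))
    coords[k, ] <- coords[k - 1L, ] + dir * 1.5
  }
  if (pose_jitter > 0) {
    coords <- coords + matrix(stats::rnorm(3L * n_atoms, 0, pose_jitter), n_atoms)
  }
  bonds <- if (n_atoms > 1L) {
    data.frame(i = seq_len(n_atoms - 1L), j = 2:n_atoms,
               order = sample(c("single", "single", "single", "double"),
                              n_atoms - 1L, replace = TRUE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(i = integer(0), j = integer(0), order = character(0))
  }
  ctx <- .atom_context(n_atoms, bonds)
  df <- data.frame(
    index = seq_len(n_atoms),
    element = elements,
    x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
    degree = ctx$degree,
    formal_charge = 0,
    aromatic = ctx$aromatic,
    in_ring = ctx$in_ring,
    hybridization = ctx$hybridization,
    stringsAsFactors = FALSE
  )
  .new_atom_records(df, bonds)
}

#' Generate one synthetic protein-ligand complex
#'
#' Places a toy pocket (optionally reusing a supplied one) and grows a
#' chain ligand near a randomly chosen anchor residue, guaranteeing at
#' least one residue-atom contact within 12 Angstrom. The returned contact
#' count is the interaction-edge count of the emitted structure (the
#' quantity the planted affinity is a function of).
#'
#' @param config a [synthetic_config()].
#' @param protein optional `residue_records` pocket to reuse.
#' @param protein_id,ligand_id identifiers for the complex.
#' @param seed optional seed; default continues the caller's RNG stream.
#' @return list with `cs` (a [complex_structure()]) and `contacts`.
#' @export
make_complex <- function(config = synthetic_config(), protein = NULL,
                         protein_id = "T001", ligand_id = "L0001",
                         seed = NULL) {
  run <- function() {
    if (is.null(protein)) {
      n_res <- .sample_range(config$n_residues[1L], config$n_residues[2L])
      protein <- .make_pocket(n_res)
    }
    n_at <- .sample_range(config$n_atoms[1L], config$n_atoms[2L])
    for (attempt in 1:25) {
      anchor <- as.numeric(protein[sample(nrow(protein), 1L), c("x", "y", "z")])
      dir <- stats::rnorm(3L)
      dir <- dir / sqrt(sum(dir^2))
      center <- anchor + dir * stats::runif(1L, 1.5, 9)
      ligand <- .make_ligand(n_at, center, config$pose_jitter)
      d <- .pairwise_dist(cbind(protein$x, protein$y, protein$z),
                          cbind(ligand$x, ligand$y, ligand$z))
      contacts <- sum(d < 12)
      if (contacts >= 1L) {
        return(list(cs = complex_structure(protein, ligand, protein_id, ligand_id),
                    contacts = contacts))
      }
    }
    stop("could not place ligand in contact with the pocket", call. = FALSE)
  }
  if (is.null(seed)) run() else .with_seed(seed, run())
}

#' Planted affinity from a contact count
#'
#' pAff = intercept + alpha * contacts + assay offset + type shift + noise;
#' the stored nM value is `10^(9 - pAff)`.
#'
#' @param contacts residue-atom contact count (>= 0).
#' @param assay_offset per-assay systematic offset (pAff units).
#' @param type_shift measurement-type shift (pAff units).
#' @param noise measurement noise draw (pAff units).
#' @param config a [synthetic_config()] providing alpha and intercept.
#' @return list with `paff` and `value_nM`.
#' @export
planted_affinity <- function(contacts, assay_offset = 0, type_shift = 0,
                             noise = 0, config = synthetic_config()) {
  .assert(all(contacts >= 0), "contacts must be >= 0")
  paff <- config$intercept + config$alpha * contacts + assay_offset +
    type_shift + noise
  list(paff = paff, value_nM = from_paffinity(paff))
}

#' Generate a synthetic bioassay collection
#'
#' One pocket per assay; each record is a fresh ligand pose against that
#' pocket with a planted affinity. The emitted assay table carries the
#' eight ChEMBL-style curation fields with compliant values, so curation
#' removes nothing by construction.
#'
#' @param config a [synthetic_config()].
#' @return a `synthetic_collection`: `records` (the raw assay table),
#'   `complexes` (named list of [complex_structure()] keyed by ligand id),
#'   `truth` (per-record contact counts, true pAff and noise decomposition)
#'   and `config`.
#' @export
make_assay_collection <- function(config = synthetic_config()) {
  .with_seed(config$seed, {
    recs <- list()
    truth <- list()
    complexes <- list()
    lig_counter <- 0L
    for (i in seq_len(config$n_assays)) {
      assay_id <- sprintf("A%04d", i)
      target_id <- sprintf("T%03d", i)
      u <- stats::runif(1L)
      mtype <- if (u < config$p_ic50) "IC50" else if (u < config$p_ic50 + config$p_ki) "Ki" else "Kd"
      n_res <- .sample_range(config$n_residues[1L], config$n_residues[2L])
      pocket <- .make_pocket(n_res)
      b_assay <- stats::rnorm(1L, 0, config$sigma_assay)
      shift <- if (mtype == "IC50") config$delta_type else 0
      size <- .sample_range(config$size_range[1L], config$size_range[2L])
      for (j in seq_len(size)) {
        lig_counter <- lig_counter + 1L
        ligand_id <- sprintf("L%05d", lig_counter)
        cx <- make_complex(config, protein = pocket, protein_id = target_id,
                           ligand_id = ligand_id)
        eps <- stats::rnorm(1L, 0, config$sigma_eps)
        pa <- planted_affinity(cx$contacts, b_assay, shift, eps, config)
        complexes[[ligand_id]] <- cx$cs
        recs[[length(recs) + 1L]] <- data.frame(
          assay_id = assay_id, target_id = target_id, ligand_id = ligand_id,
          standard_type = mtype, standard_relation = "=",
          standard_value = pa$value_nM, standard_units = "nM",
          assay_type = "B", target_type = "SINGLE PROTEIN",
          component_type = "PROTEIN", molecule_type = "Small molecule",
          bao_format = "BAO_0000357", stringsAsFactors = FALSE
        )
        truth[[length(truth) + 1L]] <- data.frame(
          ligand_id = ligand_id, assay_id = assay_id, target_id = target_id,
          measure_type = mtype, contacts = cx$contacts, paff = pa$paff,
          value_nM = pa$value_nM, assay_offset = b_assay, type_shift = shift,
          noise = eps, stringsAsFactors = FALSE
        )
      }
    }
    structure(list(records = do.call(rbind, recs),
                   complexes = complexes,
                   truth = do.call(rbind, truth),
                   config = config),
              class = "synthetic_collection")
  })
}

#' @export
print.synthetic_collection <- function(x, ...) {
  cat("synthetic_collection:", length(unique(x$records$assay_id)), "assays,",
      nrow(x$records), "records,", length(x$complexes), "complexes\n")
  invisible(x)
}

# ---- plain-text structure writers ------------------------------------------

#' Write a pocket as a minimal PDB file
#'
#' One CA ATOM record per residue (fixed-column PDB format), terminated by
#' TER/END; round-trips through [parse_protein()].
#'
#' @param residues `residue_records` (or a [complex_structure()], whose
#'   protein is used).
#' @param path output path.
#' @export
write_complex_pdb <- function(residues, path) {
  if (inherits(residues, "complex_structure")) residues <- residues$protein
  lines <- vapply(seq_len(nrow(residues)), function(i) {
    sprintf("ATOM  %5d  CA  %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            i, residues$residue_name[i], substr(residues$chain[i], 1, 1),
            residues$resno[i], residues$x[i], residues$y[i], residues$z[i])
  }, character(1))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write a ligand as a minimal SDF (V2000) file
#'
#' Atom block with 3D coordinates and the bond block from the records'
#' attached bond list; round-trips through [parse_ligand()].
#'
#' @param atoms `atom_records` (or a [complex_structure()], whose ligand is
#'   used).
#' @param path output path.
#' @param title molecule title line.
#' @export
write_ligand_sdf <- function(atoms, path, title = "ligand") {
  if (inherits(atoms, "complex_structure")) atoms <- atoms$ligand
  bonds <- attr(atoms, "bonds")
  if (is.null(bonds)) bonds <- data.frame(i = integer(0), j = integer(0),
                                          order = character(0))
  order_code <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L,
                  none = 1L)
  header <- c(title, "  affpret", "")
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                    nrow(atoms), nrow(bonds))
  atom_lines <- vapply(seq_len(nrow(atoms)), function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            atoms$x[i], atoms$y[i], atoms$z[i], atoms$element[i])
  }, character(1))
  bond_lines <- if (nrow(bonds) > 0L) {
    vapply(seq_len(nrow(bonds)), function(k) {
      sprintf("%3d%3d%3d  0", bonds$i[k], bonds$j[k],
              order_code[[bonds$order[k]]])
    }, character(1))
  } else character(0)
  writeLines(c(header, counts, atom_lines, bond_lines, "M  END", "$$$$"), path)
  invisible(path)
}

#' Write a synthetic collection to disk
#'
#' Emits `assays.tsv` (the raw assay table), `truth.json`, and a
#' `complexes/` directory with one PDB per target pocket and one SDF per
#' ligand.
#'
#' @param collection a `synthetic_collection`.
#' @param dir output directory (created if needed).
#' @export
write_synthetic_dir <- function(collection, dir) {
  .assert(inherits(collection, "synthetic_collection"), "not a synthetic_collection")
  dir.create(file.path(dir, "complexes"), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(collection$records, file.path(dir, "assays.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(collection$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", digits = NA)
  done_targets <- character(0)
  for (lig in names(collection$complexes)) {
    cs <- collection$complexes[[lig]]
    if (!(cs$protein_id %in% done_targets)) {
      write_complex_pdb(cs, file.path(dir, "complexes",
                                      paste0(cs$protein_id, ".pdb")))
      done_targets <- c(done_targets, cs$protein_id)
    }
    write_ligand_sdf(cs, file.path(dir, "complexes", paste0(lig, ".sdf")),
                     title = lig)
  }
  invisible(dir)
}
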